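# Small shared fixtures; everything is generated in code.

default_drive <- function(...) drive_config(...)

# tiny density-preserving arena for fast end-to-end runs
tiny_config <- function(scenario = "mixed", scale = 0.01, drive = drive_config(),
                        ...) {
  make_fixture(run_config(drive = drive,
                          scenario = scenario_config(scenario, ...)), scale)
}

# random colony table on a custom arena (for spatial kernel tests)
random_colonies <- function(n, side, seed = 1, species_prob = c(1, 0)) {
  set.seed(seed)
  pop <- firedrive:::new_population(n)
  pop$id <- seq_len(n)
  pop$x <- runif(n, 0, side)
  pop$y <- runif(n, 0, side)
  pop$age <- sample(1:7, n, replace = TRUE)
  pop$form <- sample(1:2, n, replace = TRUE)
  pop$species <- sample(1:2, n, replace = TRUE, prob = species_prob)
  pop$f1 <- 0L; pop$f2 <- 0L; pop$s1 <- 0L; pop$s2 <- 0L
  pop$d1 <- NA_integer_; pop$d2 <- NA_integer_
  pop$mf <- 0L; pop$ms <- 0L; pop$md <- NA_integer_
  pop
}

# independent exact enumeration of the maternal gamete distribution at the
# fertility locus for a standard-type homing drive (oracle for the sampler)
oracle_fert_gamete <- function(a1, a2, c0, rg_net, res = "R") {
  states <- c("W", "D", "R", "RD")
  p <- setNames(numeric(4), states)
  pair <- sort(c(a1, a2))
  if (identical(pair, c("D", "W"))) {
    p["D"] <- (1 + c0) / 2
    p[res] <- p[res] + rg_net / 2
    p["W"] <- (1 - c0 - rg_net) / 2
  } else {
    p[a1] <- p[a1] + 0.5
    p[a2] <- p[a2] + 0.5
  }
  p
}
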