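test_that("all-wild population is a fixed point of the recursion", {
  cfg <- drive_config()
  st <- panmictic_init(cfg, drive_intro = 0)
  st2 <- next_generation(st, cfg)
  expect_equal(st2$female, st$female, tolerance = 1e-12)
  expect_equal(st2$male, st$male, tolerance = 1e-12)
})

test_that("perfect conversion heterozygote cross gives all-carrier offspring", {
  cfg <- drive_config(conversion = 1, embryo_resistance = 0)
  st <- panmictic_init(cfg)
  mach <- attr(st, "machinery")
  f <- mach$females
  # craft a population of D/W mothers and W males
  st$female[] <- 0
  st$female[f$f1 == 0 & f$f2 == 1 & f$s1 == 0 & f$s2 == 0] <- 1
  st$male[] <- 0
  st$male[mach$males$f == 0 & mach$males$s == 0] <- 1
  st2 <- next_generation(st, cfg)
  # daughters: maternal gamete is always D, paternal allele W -> all D/W
  dw <- st2$female[f$f1 == 0 & f$f2 == 1 & f$s1 == 0 & f$s2 == 0]
  expect_equal(sum(dw), 1, tolerance = 1e-12)
  # sons are all drive
  expect_equal(sum(st2$male[mach$males$f == 1]), 1, tolerance = 1e-12)
})

test_that("frequencies stay normalised and nonnegative over 1000 generations", {
  cfg <- drive_config()
  st <- panmictic_init(cfg)
  for (i in 1:1000) st <- next_generation(st, cfg)
  expect_equal(sum(st$female), 1, tolerance = 1e-9)
  expect_equal(sum(st$male), 1, tolerance = 1e-9)
  expect_true(all(st$female >= 0) && all(st$male >= 0))
})

test_that("deterministic elimination threshold is 1 - 1/g", {
  expect_equal(required_genetic_load(6), 1 - 1 / 6)
  expect_equal(round(required_genetic_load(6), 4), 0.8333)
  expect_equal(required_genetic_load(2), 0.5)
  expect_equal(required_genetic_load(10), 0.9)
  expect_error(required_genetic_load(1), "exceed 1")
})

test_that("null drive yields zero genetic load", {
  res <- equilibrium_genetic_load(drive_config(conversion = 0,
                                               germline_resistance = 0,
                                               embryo_resistance = 0,
                                               somatic_fitness = 1))
  expect_lt(res$load, 0.01)
})

test_that("genetic load is monotone non-decreasing in conversion", {
  loads <- vapply(c(0.8, 0.85, 0.9, 0.95, 1), function(cc)
    equilibrium_genetic_load(drive_config(conversion = cc))$load, numeric(1))
  expect_true(all(diff(loads) > -1e-9))
})

test_that("dominant-sterile resistance outperforms the standard drive at low conversion", {
  p <- list(conversion = 0.8, germline_resistance = 0.2,
            germline_res_absolute = TRUE)
  std <- equilibrium_genetic_load(do.call(drive_config, c(p, variant = "standard")))
  dom <- equilibrium_genetic_load(do.call(drive_config, c(p, variant = "dominant_sterile")))
  expect_gt(dom$load, std$load)
})

test_that("haplolethal two-target load equals dominant-sterile load at 100% cutting", {
  p <- list(conversion = 0.8, germline_resistance = 0.2,
            germline_res_absolute = TRUE)  # total cut rate 1
  tt <- equilibrium_genetic_load(do.call(drive_config,
                                         c(p, variant = "two_target_haplolethal")))
  dom <- equilibrium_genetic_load(do.call(drive_config,
                                          c(p, variant = "dominant_sterile")))
  expect_equal(tt$load, dom$load, tolerance = 1e-6)
})

test_that("recursion agrees with a stochastic Wright-Fisher haplodiploid simulation", {
  cfg <- drive_config()
  # deterministic trajectory
  st <- panmictic_init(cfg, drive_intro = 0.05)
  mach <- attr(st, "machinery")
  freq_det <- numeric(25)
  for (g in 1:25) {
    st <- next_generation(st, cfg)
    freq_det[g] <- firedrive:::panmictic_drive_freq(st)
  }
  # independent stochastic simulation: explicit individuals, one locus
  set.seed(99)
  N <- 1e5
  fem <- cbind(rep(0L, N), rep(0L, N))                   # W/W females
  mal <- c(rep(1L, round(0.05 * N)), rep(0L, N - round(0.05 * N)))
  c0 <- 0.95; rg <- 0.5 * 0.05; re <- 0.05; fs <- 0.98
  gam_draw <- function(f) {
    het <- (f[, 1] == 1L & f[, 2] == 0L) | (f[, 1] == 0L & f[, 2] == 1L)
    pick <- ifelse(runif(nrow(f)) < 0.5, f[, 1], f[, 2])
    u <- runif(nrow(f))
    cutres <- ifelse(u < c0, 1L, ifelse(u < c0 + rg, 2L, 0L))
    pool <- ifelse(runif(nrow(f)) < 0.5, 1L, cutres)
    ifelse(het, pool, pick)
  }
  freq_sto <- numeric(25)
  for (g in 1:25) {
    fert <- fem[, 1] == 0L | fem[, 2] == 0L
    het <- (fem[, 1] == 1L & fem[, 2] == 0L) | (fem[, 1] == 0L & fem[, 2] == 1L)
    w <- ifelse(fert, ifelse(het, fs, 1), 0)
    moms <- sample.int(N, N, replace = TRUE, prob = w)
    momg <- fem[moms, , drop = FALSE]
    hasD <- momg[, 1] == 1L | momg[, 2] == 1L
    eggs <- gam_draw(momg)
    eggs[hasD & eggs == 0L & runif(N) < re] <- 2L
    dads <- sample(mal, N, replace = TRUE)
    dads[hasD & dads == 0L & runif(N) < re] <- 2L
    sons <- gam_draw(momg)
    sons[hasD & sons == 0L & runif(N) < re] <- 2L
    fem <- cbind(eggs, dads)
    mal <- sons
    freq_sto[g] <- (sum(fem == 1L) + sum(mal == 1L)) / (2 * N + N)
  }
  # compare where drift noise is quantifiable: 3 SE on allele counts
  se <- sqrt(freq_det * (1 - freq_det) / N)
  expect_true(all(abs(freq_sto - freq_det) < 3 * se + 0.01))
})
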