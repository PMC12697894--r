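# The colony table: one row per colony (the simulation agent), with the
# queen's diploid genome (f1,f2 fertility; s1,s2 social; d1,d2 drive site)
# and her stored mate's haploid genome (mf, ms, md; NA while unmated).

new_population <- function(n = 0L) {
  data.frame(id = integer(n), x = numeric(n), y = numeric(n),
             age = integer(n), form = integer(n), species = integer(n),
             f1 = integer(n), f2 = integer(n),
             s1 = integer(n), s2 = integer(n),
             d1 = integer(n), d2 = integer(n),
             mf = integer(n), ms = integer(n), md = integer(n))
}

# Census age distribution (post-survival ages 0..max-1): the within-year
# stationary distribution shifted by one year.
census_age_probs <- function(form, params) {
  q <- stationary_age_distribution(form, params)
  p <- unname(q) # p[a + 1] corresponds to census age a = 0..max-1
  p / sum(p)
}

wild_block <- function(n, form, species, scenario, drive, ecology, xlim, id0) {
  if (n <= 0) return(new_population(0L))
  side <- ecology$arena_side
  pform <- if (form == FORM_POLYGYNE) "polygyne" else "monogyne"
  ages <- sample(seq_along(census_age_probs(pform, ecology)) - 1L, n,
                 replace = TRUE, prob = census_age_probs(pform, ecology))
  pop <- new_population(n)
  pop$id <- as.integer(id0) + seq_len(n)
  pop$x <- runif(n, xlim[1] * side, xlim[2] * side)
  pop$y <- runif(n, 0, side)
  pop$age <- as.integer(ages)
  pop$form <- form
  pop$species <- species
  pop$f1 <- FERT_W; pop$f2 <- FERT_W
  if (form == FORM_POLYGYNE) {
    pop$s1 <- SOC_SB; pop$s2 <- SOC_Sb
  } else {
    pop$s1 <- SOC_SB; pop$s2 <- SOC_SB
  }
  if (uses_drive_site(drive)) {
    pop$d1 <- DS_W; pop$d2 <- DS_W
  } else {
    pop$d1 <- NA_integer_; pop$d2 <- NA_integer_
  }
  mated <- pop$age >= 1L
  pop$mf <- ifelse(mated, FERT_W, NA_integer_)
  # polygyne queens take mates from the local (half-Sb) male pool
  ms <- if (form == FORM_POLYGYNE) {
    ifelse(runif(n) < 0.5, SOC_Sb, SOC_SB)
  } else rep(SOC_SB, n)
  pop$ms <- ifelse(mated, ms, NA_integer_)
  pop$md <- if (uses_drive_site(drive)) ifelse(mated, DS_W, NA_integer_)
            else NA_integer_
  pop
}

#' Initialise a population for a scenario
#'
#' Places wild-type colonies uniformly at random in their allotted regions
#' with ages drawn from the stationary age distribution: mixed and
#' single-form scenarios use the whole arena; the invasion scenario confines
#' polygyne fire ants to the leftmost 20% of the arena, monogyne fire ants to
#' the next 20%, and native ants to the right 60%.  Monogyne queens are SB/SB,
#' polygyne queens SB/Sb; colonies of age >= 1 carry a wild-type mate.
#'
#' @param config a [run_config()].
#' @return A colony data frame (one row per colony).
#' @examples
#' pop <- initialize_population(make_fixture(run_config(), 0.01))
#' nrow(pop)
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$scenario; eco <- config$ecology; drv <- config$drive
  if (sc$scenario == "invasion") {
    blocks <- list(
      wild_block(sc$n_polygyne, FORM_POLYGYNE, SP_FIRE, sc, drv, eco, c(0, 0.2), 0L),
      wild_block(sc$n_monogyne, FORM_MONOGYNE, SP_FIRE, sc, drv, eco, c(0.2, 0.4),
                 sc$n_polygyne),
      wild_block(sc$n_native, FORM_MONOGYNE, SP_NATIVE, sc, drv, eco, c(0.4, 1),
                 sc$n_polygyne + sc$n_monogyne))
  } else {
    blocks <- list(
      wild_block(sc$n_monogyne, FORM_MONOGYNE, SP_FIRE, sc, drv, eco, c(0, 1), 0L),
      wild_block(sc$n_polygyne, FORM_POLYGYNE, SP_FIRE, sc, drv, eco, c(0, 1),
                 sc$n_monogyne),
      wild_block(sc$n_native, FORM_MONOGYNE, SP_NATIVE, sc, drv, eco, c(0, 1),
                 sc$n_monogyne + sc$n_polygyne))
  }
  do.call(rbind, blocks)
}
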