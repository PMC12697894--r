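# Yearly-cycle orchestration: reproduction, polygyne queen replacement,
# mating (with drive-male releases), competition, and survival.

# ---- offspring production ---------------------------------------------------

# Haploid genome of released drive males; Sb with probability
# release_Sb_fraction.
release_male_genomes <- function(n, drive, scenario) {
  if (uses_drive_site(drive)) {
    list(f = rep(FERT_W, n), d = rep(DS_D, n),
         s = ifelse(runif(n) < scenario$release_Sb_fraction, SOC_Sb, SOC_SB))
  } else {
    list(f = rep(FERT_D, n), d = rep(NA_integer_, n),
         s = ifelse(runif(n) < scenario$release_Sb_fraction, SOC_Sb, SOC_SB))
  }
}

# Male gamete of a father colony: the colony queen's germline gamete with her
# embryo resistance applied (sons develop from her unfertilised eggs).
father_son_genomes <- function(pop, fidx, drive) {
  g <- sample_gametes(pop$f1[fidx], pop$f2[fidx], pop$s1[fidx], pop$s2[fidx],
                      pop$d1[fidx], pop$d2[fidx], drive)
  active <- vec_mother_has_drive(pop$f1[fidx], pop$f2[fidx],
                                 pop$d1[fidx], pop$d2[fidx], drive)
  r <- drive$embryo_resistance
  g$f <- embryo_cut(g$f, active, r, fert_res_code(drive))
  if (uses_drive_site(drive)) g$d <- embryo_cut(g$d, active, r, DS_R)
  g
}

# Reproduction by colonies of age >= 2: queen counts, daughter genome
# formation, viability/greenbeard filters and dispersal.  Returns the
# offspring block (age 0, unmated) and indices of colonies dying from the
# cleave-SB nonviability rule.
reproduce_step <- function(pop, config, next_id) {
  drv <- config$drive; eco <- config$ecology; sc <- config$scenario
  kill <- rep(FALSE, nrow(pop))
  if (drv$variant == "cleave_SB") {
    # a drive SB/Sb queen's germline is all Sb; mated to an Sb male her
    # workers are Sb/Sb, so the colony fails
    kill <- (pop$f1 == FERT_D | pop$f2 == FERT_D) & (pop$s1 != pop$s2) &
      !is.na(pop$ms) & pop$ms == SOC_Sb
  }
  mothers <- which(pop$age >= 2L & !is.na(pop$mf) & !kill)
  if (length(mothers) == 0)
    return(list(offspring = new_population(0L), kill = which(kill)))
  fec <- vec_fecundity(pop$f1[mothers], pop$f2[mothers],
                       pop$d1[mothers], pop$d2[mothers], drv)
  mu <- expected_queen_mean(pop$age[mothers], fec, eco)
  noff <- rpois(length(mothers), mu)
  midx <- rep(mothers, noff)
  n <- length(midx)
  if (n == 0) return(list(offspring = new_population(0L), kill = which(kill)))

  gam <- sample_gametes(pop$f1[midx], pop$f2[midx], pop$s1[midx], pop$s2[midx],
                        pop$d1[midx], pop$d2[midx], drv)
  f1 <- gam$f; f2 <- pop$mf[midx]
  s1 <- gam$s; s2 <- pop$ms[midx]
  d1 <- gam$d; d2 <- pop$md[midx]
  active <- vec_mother_has_drive(pop$f1[midx], pop$f2[midx],
                                 pop$d1[midx], pop$d2[midx], drv)
  r <- drv$embryo_resistance
  f1 <- embryo_cut(f1, active, r, fert_res_code(drv))
  f2 <- embryo_cut(f2, active, r, fert_res_code(drv))
  if (uses_drive_site(drv)) {
    d1 <- embryo_cut(d1, active, r, DS_R)
    d2 <- embryo_cut(d2, active, r, DS_R)
  }
  # sterile females cannot produce workers and are unable to found a colony
  keep <- vec_female_viable(s1, s2, d1, d2, drv) &
    vec_female_fertile(f1, f2, drv) &
    !vec_greenbeard_culled(pop$form[midx], f1, f2, s1, s2, drv)
  if (!any(keep)) return(list(offspring = new_population(0L), kill = which(kill)))

  midx <- midx[keep]
  f1 <- f1[keep]; f2 <- f2[keep]; s1 <- s1[keep]; s2 <- s2[keep]
  d1 <- d1[keep]; d2 <- d2[keep]
  n <- length(midx)
  form <- as.integer(vec_social_form(f1, f2, s1, s2, drv))
  species <- pop$species[midx]
  disp <- dispersal_mean(form, eco, sc)
  pos <- dispersal_draw(pop$x[midx], pop$y[midx], disp, eco$arena_side)

  off <- new_population(n)
  off$id <- as.integer(next_id + seq_len(n) - 1L)
  off$x <- pos$x; off$y <- pos$y
  off$age <- 0L
  off$form <- form; off$species <- species
  off$f1 <- f1; off$f2 <- f2; off$s1 <- s1; off$s2 <- s2
  off$d1 <- d1; off$d2 <- d2
  off$mf <- NA_integer_; off$ms <- NA_integer_; off$md <- NA_integer_
  list(offspring = off, kill = which(kill))
}

# ---- mating -----------------------------------------------------------------

# Father-colony pool for a species: colonies capable of producing offspring,
# weighted by biomass x queen fecundity x polygyne male rate.
father_pool <- function(pop, species, config) {
  drv <- config$drive; eco <- config$ecology
  idx <- which(pop$species == species & pop$age >= 2L & !is.na(pop$mf))
  if (length(idx) == 0) return(list(idx = integer(0), w = numeric(0)))
  fec <- vec_fecundity(pop$f1[idx], pop$f2[idx], pop$d1[idx], pop$d2[idx], drv)
  w <- size_monogyne(pop$age[idx], eco) *
    ifelse(pop$form[idx] == FORM_POLYGYNE,
           eco$polygyne_exert * eco$polygyne_male_rate, 1) * fec
  keep <- w > 0
  list(idx = idx[keep], w = w[keep])
}

# Assign mates to queens at positions (qx, qy) of given form/species.
# Implements up-to-`mate_attempts` weighted sampling with per-attempt release
# overrides, monogyne rejection of Sb-bearing males, and nonviable-male
# rejection.  Returns mf/ms/md vectors (NA where mating failed).
mate_queens <- function(pop, qx, qy, qform, qspecies, config, release_active) {
  drv <- config$drive; eco <- config$ecology; sc <- config$scenario
  nq <- length(qx)
  out <- list(mf = rep(NA_integer_, nq), ms = rep(NA_integer_, nq),
              md = rep(NA_integer_, nq))
  if (nq == 0) return(out)
  rho <- sc$release_fraction / (1 + sc$release_fraction)
  for (sp in unique(qspecies)) {
    qs <- which(qspecies == sp)
    fp <- father_pool(pop, sp, config)
    rel_here <- release_active && sp == SP_FIRE && sc$release_fraction > 0
    if (length(fp$idx) == 0 && !rel_here) next
    sigma <- dispersal_mean(qform[qs], eco, sc) * sqrt(2 / pi)
    radius <- eco$mate_radius_factor * sigma
    samp <- if (length(fp$idx) > 0) {
      cpp_mate_sample(qx[qs], qy[qs], radius, pop$x[fp$idx], pop$y[fp$idx],
                      fp$w, eco$mate_attempts, eco$mate_fallback_k)
    } else matrix(0L, length(qs), eco$mate_attempts)
    unmated <- seq_along(qs)
    for (a in seq_len(eco$mate_attempts)) {
      if (length(unmated) == 0) break
      rows <- unmated
      m <- length(rows)
      use_rel <- if (rel_here) runif(m) < rho else rep(FALSE, m)
      fath <- samp[rows, a]
      gen <- list(f = rep(NA_integer_, m), s = rep(NA_integer_, m),
                  d = rep(NA_integer_, m))
      src <- !use_rel & fath > 0L
      if (any(src)) {
        fidx <- fp$idx[fath[src]]
        g <- father_son_genomes(pop, fidx, drv)
        gen$f[src] <- g$f; gen$s[src] <- g$s; gen$d[src] <- g$d
      }
      if (any(use_rel)) {
        g <- release_male_genomes(sum(use_rel), drv, sc)
        gen$f[use_rel] <- g$f; gen$s[use_rel] <- g$s; gen$d[use_rel] <- g$d
      }
      ok <- !is.na(gen$s) & vec_male_viable(gen$d, drv) &
        !(qform[qs][rows] == FORM_MONOGYNE & gen$s == SOC_Sb)
      if (any(ok)) {
        hit <- qs[rows[ok]]
        out$mf[hit] <- gen$f[ok]
        out$ms[hit] <- gen$s[ok]
        out$md[hit] <- gen$d[ok]
        unmated <- rows[!ok]
      }
    }
  }
  out
}

# Mating of age-1 unmated queens; queens failing all attempts are removed.
mating_step <- function(pop, config, release_active) {
  queens <- which(pop$age == 1L & is.na(pop$mf))
  if (length(queens) == 0) return(pop)
  res <- mate_queens(pop, pop$x[queens], pop$y[queens], pop$form[queens],
                     pop$species[queens], config, release_active)
  pop$mf[queens] <- res$mf
  pop$ms[queens] <- res$ms
  pop$md[queens] <- res$md
  failed <- queens[is.na(res$mf)]
  if (length(failed) > 0) pop <- pop[-failed, , drop = FALSE]
  pop
}

# ---- polygyne representative-queen replacement ------------------------------

# Polygyne representative-queen replacement.  Each year every polygyne colony
# seeks a replacement queen with probability queen_replacement_prob; a seeker
# that finds a viable newly mated polygyne queen swaps its queen and mate
# genotypes (age retained), while a seeker that cannot (no reproducing
# polygyne colony in range, or the candidate is nonviable, culled or fails to
# mate) dies with probability replacement_fail_death.  Non-seeking colonies
# simply retain the previous queen's genotype.  In a healthy population
# failures are rare; under drive suppression candidates become scarce and
# sterile, which is what shortens polygyne colony lifespan.
replacement_step <- function(pop, config, release_active) {
  drv <- config$drive; eco <- config$ecology; sc <- config$scenario
  poly <- which(pop$form == FORM_POLYGYNE & pop$species == SP_FIRE & pop$age >= 1L)
  if (length(poly) == 0) return(pop)
  n <- length(poly)
  seek <- runif(n) < eco$queen_replacement_prob
  replaced <- rep(FALSE, n)

  if (any(seek)) {
    # candidate mother: a reproducing polygyne colony within the polygyne
    # dispersal range, weighted by its expected queen output
    mom_idx <- which(pop$form == FORM_POLYGYNE & pop$species == SP_FIRE &
                       pop$age >= 2L & !is.na(pop$mf))
    if (drv$variant == "cleave_SB") {
      blocked <- (pop$f1[mom_idx] == FERT_D | pop$f2[mom_idx] == FERT_D) &
        (pop$s1[mom_idx] != pop$s2[mom_idx]) & pop$ms[mom_idx] == SOC_Sb
      mom_idx <- mom_idx[!blocked]
    }
    if (length(mom_idx) > 0) {
      fec <- vec_fecundity(pop$f1[mom_idx], pop$f2[mom_idx],
                           pop$d1[mom_idx], pop$d2[mom_idx], drv)
      w <- expected_queen_mean(pop$age[mom_idx], fec, eco)
      keep <- w > 0
      mom_idx <- mom_idx[keep]; w <- w[keep]
    }
    sk <- which(seek)
    if (length(mom_idx) > 0) {
      sigma <- eco$dispersal * eco$polygyne_dispersal_factor * sqrt(2 / pi)
      if (!is.null(sc$dispersal_override))
        sigma <- sc$dispersal_override * eco$polygyne_dispersal_factor * sqrt(2 / pi)
      radius <- rep(eco$mate_radius_factor * sigma, length(sk))
      samp <- cpp_mate_sample(pop$x[poly[sk]], pop$y[poly[sk]], radius,
                              pop$x[mom_idx], pop$y[mom_idx], w, 1L, 0L)
      has_mom <- samp[, 1] > 0L
      if (any(has_mom)) {
        rows <- sk[has_mom]
        momg <- mom_idx[samp[has_mom, 1]]
        # the colony adopts one of the mother's *surviving* daughters: draw
        # daughters until one passes the viability/greenbeard/social-form
        # filters (a mother whose daughters are systematically culled or
        # nonviable - e.g. under the drive - yields no candidate)
        nr <- length(momg)
        f1 <- f2 <- s1 <- s2 <- d1 <- d2 <- rep(NA_integer_, nr)
        valid <- rep(FALSE, nr)
        active <- vec_mother_has_drive(pop$f1[momg], pop$f2[momg],
                                       pop$d1[momg], pop$d2[momg], drv)
        r <- drv$embryo_resistance
        for (try in seq_len(10L)) {
          todo <- which(!valid)
          if (length(todo) == 0) break
          mg <- momg[todo]
          gam <- sample_gametes(pop$f1[mg], pop$f2[mg], pop$s1[mg],
                                pop$s2[mg], pop$d1[mg], pop$d2[mg], drv)
          tf1 <- embryo_cut(gam$f, active[todo], r, fert_res_code(drv))
          tf2 <- embryo_cut(pop$mf[mg], active[todo], r, fert_res_code(drv))
          ts1 <- gam$s; ts2 <- pop$ms[mg]
          td1 <- gam$d; td2 <- pop$md[mg]
          if (uses_drive_site(drv)) {
            td1 <- embryo_cut(td1, active[todo], r, DS_R)
            td2 <- embryo_cut(td2, active[todo], r, DS_R)
          }
          ok <- vec_female_viable(ts1, ts2, td1, td2, drv) &
            vec_female_fertile(tf1, tf2, drv) &
            !vec_greenbeard_culled(FORM_POLYGYNE, tf1, tf2, ts1, ts2, drv) &
            vec_social_form(tf1, tf2, ts1, ts2, drv) == FORM_POLYGYNE
          f1[todo] <- tf1; f2[todo] <- tf2
          s1[todo] <- ts1; s2[todo] <- ts2
          d1[todo] <- td1; d2[todo] <- td2
          valid[todo] <- ok
        }
        if (any(valid)) {
          v <- which(valid)
          tgt <- poly[rows[v]] # colonies receiving a candidate queen
          mt <- mate_queens(pop, pop$x[tgt], pop$y[tgt],
                            rep(FORM_POLYGYNE, length(tgt)),
                            rep(SP_FIRE, length(tgt)), config, release_active)
          okm <- !is.na(mt$mf)
          if (drv$variant == "cleave_Sb") {
            # a drive SB/Sb queen mated to an SB male cannot represent the
            # colony (all her SB/SB daughters are culled by workers)
            bad <- (f1[v] == FERT_D | f2[v] == FERT_D) & (s1[v] != s2[v]) &
              !is.na(mt$ms) & mt$ms == SOC_SB
            okm <- okm & !bad
          }
          if (any(okm)) {
            dst <- tgt[okm]; srcv <- v[okm]
            pop$f1[dst] <- f1[srcv]; pop$f2[dst] <- f2[srcv]
            pop$s1[dst] <- s1[srcv]; pop$s2[dst] <- s2[srcv]
            pop$d1[dst] <- d1[srcv]; pop$d2[dst] <- d2[srcv]
            pop$mf[dst] <- mt$mf[okm]; pop$ms[dst] <- mt$ms[okm]
            pop$md[dst] <- mt$md[okm]
            replaced[rows[v][okm]] <- TRUE
          }
        }
      }
    }
  }
  # seekers that could not complete a replacement die with probability
  # replacement_fail_death; non-seekers retain their queen
  fail <- which(seek & !replaced)
  die <- fail[runif(length(fail)) < eco$replacement_fail_death]
  if (length(die) > 0) pop <- pop[-poly[die], , drop = FALSE]
  pop
}

# ---- survival ---------------------------------------------------------------

survival_step <- function(pop, config, expected) {
  eco <- config$ecology; sc <- config$scenario
  if (nrow(pop) == 0) return(pop)
  src <- pop[pop$age >= 1L, , drop = FALSE]
  actual <- actual_competition(src, pop, sc, eco)
  expct <- ifelse(pop$species == SP_FIRE, expected$fire, expected$native)
  R <- (actual / expct) * eco$competition_calibration

  surv <- numeric(nrow(pop))
  a0 <- pop$age == 0L
  # recruitment is regulated by the population-level competition ratio per
  # species (the mean over established colonies), the scale on which the
  # low-density growth rate is defined; established-colony survival below
  # responds to the local ratio
  for (sp in unique(pop$species[a0])) {
    est <- pop$age >= 1L & pop$species == sp
    Rg <- if (any(est)) mean(R[est]) else 0
    sel <- a0 & pop$species == sp
    surv[sel] <- age0_survival(Rg, eco$low_density_growth)
  }
  if (any(!a0)) {
    L <- ifelse(pop$form[!a0] == FORM_POLYGYNE,
                eco$survival_base_polygyne, eco$survival_base)
    S <- size_monogyne(pop$age[!a0], eco)
    Rv <- pmax(R[!a0], 1e-12)
    surv[!a0] <- pmin(1, pmax(0, L - eco$survival_amplitude *
                                exp(-eco$survival_constant * S / Rv)))
  }
  alive <- runif(nrow(pop)) < surv
  # age-related death
  mono <- pop$form == FORM_MONOGYNE
  alive <- alive & !(mono & pop$age >= eco$max_age_monogyne)
  at6 <- mono & pop$age == 6L
  alive[at6] <- alive[at6] & (runif(sum(at6)) >= eco$age6_death_rate)
  alive <- alive & !(!mono & pop$age >= eco$max_age_polygyne)
  pop[alive, , drop = FALSE]
}

# ---- release trigger for the invasion scenario ------------------------------

invasion_triggered <- function(pop, eco) {
  # fire ants make up >= 50% of the biomass in the left half of slice 7
  side <- eco$arena_side
  sel <- pop$x >= 0.60 * side & pop$x < 0.65 * side & pop$age >= 1L
  if (!any(sel)) return(FALSE)
  bm <- colony_biomass(pop[sel, , drop = FALSE], eco)
  fire <- pop$species[sel] == SP_FIRE
  tot <- sum(bm)
  tot > 0 && sum(bm[fire]) / tot >= 0.5
}

# ---- main loop --------------------------------------------------------------

#' Run the spatial fire ant gene drive simulation
#'
#' Executes the yearly cycle for up to `years` years: age increment;
#' reproduction by colonies of age >= 2 (queen production, inheritance with
#' drive conversion and embryo resistance, viability and greenbeard filters,
#' dispersal); polygyne representative-queen replacement; mating of age-1
#' queens including released drive males; competition-ratio computation;
#' survival (age-0 low-density rule, density-dependent survival, age-related
#' death); metrics recording.
#'
#' @param config a [run_config()]; use [make_fixture()] for fast
#'   density-preserving scaled runs.
#' @param seed random seed for this replicate (defaults to `config$seed`).
#' @param years simulation horizon (defaults to the scenario's).
#' @param stop_when_suppressed optional fraction: stop once total fire
#'   biomass falls below this fraction of its initial value (for
#'   time-to-suppression runs).
#' @param record_slices record 10-slice biomass vectors each year (default
#'   in the invasion scenario).
#' @return An object of class `firedrive_sim`: a list with `records` (one
#'   row per year, year 0 = initial state), `final_pop`, `termination`
#'   (`"years"`, `"eliminated"`, `"drive_lost"` or `"suppressed"`), `seed`,
#'   `config`, and optionally `slices`.
#' @examples
#' \donttest{
#' cfg <- make_fixture(run_config(scenario = scenario_config("mixed")), 0.01)
#' sim <- simulate_drive(cfg, seed = 1, years = 10)
#' tail(sim$records[, c("year", "n_fire", "biomass_fire", "freq_drive")])
#' }
#' @export
simulate_drive <- function(config = run_config(), seed = config$seed,
                           years = config$scenario$years,
                           stop_when_suppressed = NULL,
                           record_slices = config$scenario$scenario == "invasion") {
  stopifnot(inherits(config, "run_config"))
  set.seed(seed)
  sc <- config$scenario; eco <- config$ecology
  pop <- initialize_population(config)
  next_id <- if (nrow(pop)) max(pop$id) + 1L else 1L
  expected <- expected_competition(sc, eco)

  records <- vector("list", years + 1)
  slices <- if (record_slices) vector("list", years + 1) else NULL
  records[[1]] <- year_record(0, pop, config)
  if (record_slices) slices[[1]] <- slice_biomass(pop, eco)
  init_biomass <- records[[1]]$biomass_fire
  termination <- "years"
  release_started <- sc$scenario != "invasion"
  release_until <- if (release_started) sc$release_years else NA_integer_
  last_year <- years

  for (yr in seq_len(years)) {
    if (nrow(pop) == 0) { termination <- "eliminated"; last_year <- yr - 1; break }
    # invasion: trigger releases on the slice-7 criterion
    if (!release_started && sc$release_fraction > 0 && invasion_triggered(pop, eco)) {
      release_started <- TRUE
      release_until <- yr + sc$release_years - 1L
    }
    release_active <- release_started && sc$release_fraction > 0 &&
      yr <= release_until

    pop$age <- pop$age + 1L
    rep_out <- reproduce_step(pop, config, next_id)
    if (length(rep_out$kill) > 0) {
      keep_ids <- setdiff(seq_len(nrow(pop)), rep_out$kill)
      pop <- pop[keep_ids, , drop = FALSE]
    }
    off <- rep_out$offspring
    if (nrow(off) > 0) next_id <- max(off$id) + 1L
    pop <- replacement_step(pop, config, release_active)
    pop <- mating_step(pop, config, release_active)
    pop <- rbind(pop, off)
    pop <- survival_step(pop, config, expected)

    rec <- year_record(yr, pop, config)
    records[[yr + 1]] <- rec
    if (record_slices) slices[[yr + 1]] <- slice_biomass(pop, eco)

    fire_alive <- rec$n_fire > 0
    if (!fire_alive && sc$n_native == 0) {
      termination <- "eliminated"; last_year <- yr; break
    }
    if (!is.null(stop_when_suppressed) && init_biomass > 0 &&
        rec$biomass_fire < stop_when_suppressed * init_biomass) {
      termination <- "suppressed"; last_year <- yr; break
    }
    if (sc$release_fraction > 0 && release_started && yr > release_until &&
        fire_alive && !is.na(rec$freq_drive) && rec$freq_drive == 0) {
      termination <- "drive_lost"; last_year <- yr; break
    }
  }
  records <- do.call(rbind, records[!vapply(records, is.null, logical(1))])
  out <- list(records = records, final_pop = pop, termination = termination,
              last_year = last_year, seed = seed, config = config)
  if (record_slices)
    out$slices <- slices[!vapply(slices, is.null, logical(1))]
  class(out) <- "firedrive_sim"
  out
}

#' @export
print.firedrive_sim <- function(x, ...) {
  r <- x$records[nrow(x$records), ]
  cat(sprintf(
    "<firedrive_sim> %s, %d years (%s): %d colonies, fire biomass %.3g, drive freq %.3g\n",
    x$config$scenario$scenario, x$last_year, x$termination,
    r$n_colonies, r$biomass_fire,
    if (is.na(r$freq_drive)) 0 else r$freq_drive))
  invisible(x)
}

#' Run several replicates with derived seeds
#'
#' Draws one sub-seed per replicate from the base seed and runs
#' [simulate_drive()] for each, so replicates are independent and
#' reproducible.
#'
#' @param config a [run_config()].
#' @param n number of replicates (defaults to `config$replicates`).
#' @param base_seed base seed (defaults to `config$seed`).
#' @param ... passed to [simulate_drive()].
#' @return A list of `firedrive_sim` objects.
#' @export
simulate_replicates <- function(config, n = config$replicates,
                                base_seed = config$seed, ...) {
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seeds, function(s) simulate_drive(config, seed = s, ...))
}
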