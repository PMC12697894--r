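# Discrete-generation, non-spatial haplodiploid genotype-frequency model:
# genetic load surfaces, suppression thresholds and generation times.

# ---- genotype machinery -----------------------------------------------------

# Enumerate haploid male states and diploid female genotypes for a variant,
# and precompute the gamete matrix, embryo operator, and genotype-level
# weights.  All per-config; cached on the state object.
panmictic_machinery <- function(config) {
  ds_states <- if (uses_drive_site(config)) c(DS_W, DS_D, DS_R) else NA_integer_
  males <- expand.grid(f = c(FERT_W, FERT_D, FERT_R, FERT_RD),
                       s = c(SOC_SB, SOC_Sb), d = ds_states,
                       KEEP.OUT.ATTRS = FALSE)
  nm <- nrow(males)

  pair_idx <- function(vals) {
    g <- expand.grid(a1 = vals, a2 = vals, KEEP.OUT.ATTRS = FALSE)
    g[which(is.na(g$a1) | g$a1 <= g$a2), , drop = FALSE]
  }
  fp <- pair_idx(c(FERT_W, FERT_D, FERT_R, FERT_RD))
  sp <- pair_idx(c(SOC_SB, SOC_Sb))
  dp <- pair_idx(ds_states)
  females <- expand.grid(fi = seq_len(nrow(fp)), si = seq_len(nrow(sp)),
                         di = seq_len(nrow(dp)), KEEP.OUT.ATTRS = FALSE)
  females <- data.frame(f1 = fp$a1[females$fi], f2 = fp$a2[females$fi],
                        s1 = sp$a1[females$si], s2 = sp$a2[females$si],
                        d1 = dp$a1[females$di], d2 = dp$a2[females$di])
  nf <- nrow(females)

  # lookup from an ordered haploid pair to the female genotype row
  key_f <- function(f1, f2, s1, s2, d1, d2) {
    a <- pmin(f1, f2); b <- pmax(f1, f2)
    c1 <- pmin(s1, s2); c2 <- pmax(s1, s2)
    e1 <- pmin(d1, d2); e2 <- pmax(d1, d2)
    e1[is.na(e1)] <- 9L; e2[is.na(e2)] <- 9L
    ((a * 4L + b) * 2L + c1) * 2L + c2 + 1000L * (e1 * 10L + e2)
  }
  fem_key <- key_f(females$f1, females$f2, females$s1, females$s2,
                   females$d1, females$d2)

  # gamete matrix: G[i, j] = P(gamete state j | mother genotype i)
  G <- matrix(0, nf, nm)
  for (i in seq_len(nf)) {
    mom <- structure(list(ploidy = "diploid",
                          fertility = c(females$f1[i], females$f2[i]),
                          social = c(females$s1[i], females$s2[i]),
                          drive_site = if (uses_drive_site(config))
                            c(females$d1[i], females$d2[i]) else NULL),
                     class = "ant_genome")
    pr <- gamete_probabilities(mom, config)
    pf <- pr$fertility; ps <- pr$social
    pd <- if (uses_drive_site(config)) pr$drive_site else NULL
    G[i, ] <- pf[males$f + 1L] * ps[males$s + 1L] *
      (if (is.null(pd)) 1 else pd[males$d + 1L])
  }

  # embryo operator on haploids: each W allele at a drive-targeted locus
  # becomes the resistance state with probability r_e (drive mothers only)
  re <- config$embryo_resistance
  res_f <- fert_res_code(config)
  E <- matrix(0, nm, nm)
  for (j in seq_len(nm)) {
    pf <- numeric(4); pf[males$f[j] + 1L] <- 1
    if (males$f[j] == FERT_W) {
      pf[FERT_W + 1L] <- 1 - re; pf[res_f + 1L] <- pf[res_f + 1L] + re
    }
    pd <- NULL
    if (uses_drive_site(config)) {
      pd <- numeric(3); pd[males$d[j] + 1L] <- 1
      if (males$d[j] == DS_W) {
        pd[DS_W + 1L] <- 1 - re; pd[DS_R + 1L] <- pd[DS_R + 1L] + re
      }
    }
    for (k in seq_len(nm)) {
      if (males$s[k] != males$s[j]) next
      pdk <- if (is.null(pd)) 1 else pd[males$d[k] + 1L]
      E[k, j] <- pf[males$f[k] + 1L] * pdk
    }
  }

  # map a (maternal state, paternal state) pair to a female genotype row
  pair_map <- matrix(0L, nm, nm)
  for (a in seq_len(nm)) for (b in seq_len(nm)) {
    k <- key_f(males$f[a], males$f[b], males$s[a], males$s[b],
               males$d[a], males$d[b])
    pair_map[a, b] <- match(k, fem_key)
  }

  list(males = males, females = females, G = G, E = E, pair_map = pair_map,
       fertile = vec_female_fertile(females$f1, females$f2, config),
       viable_f = vec_female_viable(females$s1, females$s2,
                                    females$d1, females$d2, config),
       fec = vec_fecundity(females$f1, females$f2,
                           females$d1, females$d2, config),
       has_drive = vec_mother_has_drive(females$f1, females$f2,
                                        females$d1, females$d2, config),
       viable_m = vec_male_viable(males$d, config),
       drive_m = if (uses_drive_site(config)) males$d == DS_D
                 else males$f == FERT_D)
}

#' Initialise panmictic genotype frequencies
#'
#' All-wild females; males all wild except a fraction `drive_intro` of drive
#' males (the release).
#'
#' @param config a [drive_config()].
#' @param drive_intro introduced drive-male frequency.
#' @return An object of class `genotype_freqs` holding normalised female and
#'   male genotype frequency vectors.
#' @export
panmictic_init <- function(config = drive_config(), drive_intro = 0.01) {
  mach <- panmictic_machinery(config)
  males <- mach$males; females <- mach$females
  fm <- numeric(nrow(males))
  wild_m <- which(males$f == FERT_W & males$s == SOC_SB &
                    (is.na(males$d) | males$d == DS_W))
  if (uses_drive_site(config)) {
    drv_m <- which(males$f == FERT_W & males$s == SOC_SB & males$d == DS_D)
  } else {
    drv_m <- which(males$f == FERT_D & males$s == SOC_SB)
  }
  fm[wild_m] <- 1 - drive_intro
  fm[drv_m] <- drive_intro
  ff <- numeric(nrow(females))
  wild_f <- which(females$f1 == FERT_W & females$f2 == FERT_W &
                    females$s1 == SOC_SB & females$s2 == SOC_SB &
                    (is.na(females$d1) | (females$d1 == DS_W & females$d2 == DS_W)))
  ff[wild_f] <- 1
  structure(list(female = ff, male = fm, variant = config$variant),
            class = "genotype_freqs", machinery = mach)
}

# Advance one generation; internal core shared by next_generation() and
# equilibrium_genetic_load().  Returns the new state plus the generation's
# genetic load (1 - relative fertile reproductive output of daughters).
panmictic_advance <- function(state, config, mach) {
  ff <- state$female; fm <- state$male
  w <- ff * mach$fertile * mach$fec
  wt <- sum(w)
  if (wt <= 0) {
    attr(state, "extinct") <- TRUE
    return(list(state = state, load = 1))
  }
  w <- w / wt
  md <- w * mach$has_drive
  mn <- w * !mach$has_drive
  g_d <- drop(crossprod(mach$G, md))   # gametes from drive mothers
  g_n <- drop(crossprod(mach$G, mn))
  g_de <- drop(mach$E %*% g_d)         # embryo resistance applied

  fmv <- fm / sum(fm)
  fp_d <- drop(mach$E %*% fmv)         # paternal allele also exposed
  # daughter distribution over (maternal, paternal) haploid pairs
  D <- outer(g_de, fp_d) + outer(g_n, fmv)
  dv <- as.vector(D)
  idx <- as.vector(mach$pair_map)
  dd <- numeric(length(ff))
  agg <- tapply(dv, idx, sum)
  dd[as.integer(names(agg))] <- agg
  daughters <- dd / sum(dd)

  sons <- g_de + g_n
  sons <- sons / sum(sons)

  load <- 1 - sum(daughters * mach$viable_f * mach$fertile * mach$fec)

  fem_new <- daughters * mach$viable_f
  if (sum(fem_new) <= 0) {
    attr(state, "extinct") <- TRUE
    return(list(state = state, load = load))
  }
  fem_new <- fem_new / sum(fem_new)
  male_new <- sons * mach$viable_m
  male_new <- male_new / sum(male_new)
  out <- structure(list(female = fem_new, male = male_new,
                        variant = state$variant),
                   class = "genotype_freqs", machinery = mach)
  list(state = out, load = load)
}

#' Advance the panmictic recursion one generation
#'
#' Deterministic recursion: fertile females (fecundity-weighted) are crossed
#' with the male pool; daughters receive a maternal germline gamete (drive
#' conversion/resistance) plus the paternal haploid genome, sons a maternal
#' gamete alone; embryo resistance applies to offspring of drive mothers;
#' nonviable genotypes are removed and frequencies renormalised per sex.
#'
#' @param freqs a `genotype_freqs` state from [panmictic_init()].
#' @param config the [drive_config()] used to build the state.
#' @return The next `genotype_freqs` state; the attribute `"extinct"` is set
#'   when no fertile females remain.
#' @export
next_generation <- function(freqs, config) {
  stopifnot(inherits(freqs, "genotype_freqs"))
  if (!identical(freqs$variant, config$variant))
    stop("state was built for variant ", freqs$variant)
  mach <- attr(freqs, "machinery")
  if (is.null(mach)) mach <- panmictic_machinery(config)
  res <- panmictic_advance(freqs, config, mach)
  out <- res$state
  attr(out, "load") <- res$load
  out
}

# Drive allele frequency of a state (carrier locus), pooled over sexes.
panmictic_drive_freq <- function(state) {
  mach <- attr(state, "machinery")
  fem <- state$female; males <- state$male
  f <- mach$females; m <- mach$males
  if (any(!is.na(m$d))) {
    fcount <- (f$d1 == DS_D) + (f$d2 == DS_D)
    mcount <- as.numeric(m$d == DS_D)
  } else {
    fcount <- (f$f1 == FERT_D) + (f$f2 == FERT_D)
    mcount <- as.numeric(m$f == FERT_D)
  }
  (sum(fem * fcount) + sum(males * mcount)) / 3
}

#' Equilibrium genetic load of a drive
#'
#' Iterates the panmictic recursion from a drive-male introduction until the
#' genotype frequencies converge (or a period-2 oscillation is detected) and
#' returns the genetic load: the fractional reduction in fertile,
#' fecundity-weighted female reproductive output relative to an all-wild
#' population.
#'
#' @param config a [drive_config()].
#' @param drive_intro introduced drive-male frequency.
#' @param tol convergence tolerance on genotype frequencies.
#' @param max_generations iteration cap; non-convergence is reported with the
#'   last value.
#' @return An object of class `load_result`: list with `load`,
#'   `generations`, `converged`, `drive_lost` (the load is then reported at
#'   the peak-drive generation) and `extinct`.
#' @examples
#' required_genetic_load(6)                  # elimination threshold, 0.833
#' \donttest{
#' equilibrium_genetic_load(drive_config())  # defaults: load ~ 0.87
#' }
#' @export
equilibrium_genetic_load <- function(config = drive_config(),
                                     drive_intro = 0.01, tol = 1e-9,
                                     max_generations = 1e5) {
  state <- panmictic_init(config, drive_intro)
  mach <- attr(state, "machinery")
  prev <- NULL; prev2 <- NULL
  load <- 0; peak_load <- 0; peak_freq <- 0
  converged <- FALSE; extinct <- FALSE
  gen <- 0L
  repeat {
    gen <- gen + 1L
    res <- panmictic_advance(state, config, mach)
    load <- res$load
    if (isTRUE(attr(res$state, "extinct"))) { extinct <- TRUE; break }
    state <- res$state
    dfreq <- panmictic_drive_freq(state)
    if (dfreq >= peak_freq) { peak_freq <- dfreq; peak_load <- load }
    vec <- c(state$female, state$male)
    if (!is.null(prev) && max(abs(vec - prev)) < tol) { converged <- TRUE; break }
    if (!is.null(prev2) && max(abs(vec - prev2)) < tol) { converged <- TRUE; break }
    if (gen >= max_generations) break
    prev2 <- prev; prev <- vec
  }
  drive_lost <- !extinct && panmictic_drive_freq(state) < 1e-9
  structure(list(load = if (drive_lost) peak_load else load,
                 generations = gen, converged = converged || extinct,
                 drive_lost = drive_lost, extinct = extinct),
            class = "load_result")
}

#' @export
print.load_result <- function(x, ...) {
  cat(sprintf("<load_result> genetic load %.4f after %d generations (%s%s%s)\n",
              x$load, x$generations,
              if (x$converged) "converged" else "not converged",
              if (x$drive_lost) ", drive lost" else "",
              if (x$extinct) ", extinct" else ""))
  invisible(x)
}

#' Genetic load required for deterministic elimination
#'
#' A population with low-density growth rate `g` declines deterministically
#' once the genetic load exceeds `1 - 1/g`.
#'
#' @param g low-density growth rate, `> 1`.
#' @return The threshold load.
#' @examples
#' required_genetic_load(6)   # 0.8333
#' @export
required_genetic_load <- function(g) {
  if (any(g <= 1)) stop("low-density growth rate must exceed 1")
  1 - 1 / g
}

#' Genetic load sweep over drive conversion and germline resistance
#'
#' Computes the equilibrium genetic load on a conversion x germline-resistance
#' grid for a drive variant, mirroring load-surface analyses.  Germline
#' resistance is treated as an absolute rate by default (the total cut rate is
#' conversion + resistance, capped at 1).
#'
#' @param conversion,germline_resistance grid axis values.
#' @param variant drive variant.
#' @param embryo_resistance,somatic_fitness held-fixed drive parameters.
#' @param germline_res_absolute interpretation of the resistance axis.
#' @return A data frame with columns `conversion`, `germline_resistance`,
#'   `load`, `generations`, `drive_lost`.
#' @export
genetic_load_sweep <- function(conversion = seq(0.5, 1, by = 0.05),
                               germline_resistance = seq(0, 0.5, by = 0.05),
                               variant = "standard",
                               embryo_resistance = 0.05,
                               somatic_fitness = 0.98,
                               germline_res_absolute = TRUE) {
  grid <- expand.grid(conversion = conversion,
                      germline_resistance = germline_resistance,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- drive_config(conversion = grid$conversion[i],
                        germline_resistance = grid$germline_resistance[i],
                        embryo_resistance = embryo_resistance,
                        somatic_fitness = somatic_fitness,
                        variant = variant,
                        germline_res_absolute = germline_res_absolute)
    equilibrium_genetic_load(cfg)
  })
  grid$load <- vapply(res, `[[`, numeric(1), "load")
  grid$generations <- vapply(res, `[[`, numeric(1), "generations")
  grid$drive_lost <- vapply(res, `[[`, logical(1), "drive_lost")
  grid
}

# ---- generation times -------------------------------------------------------

#' Monogyne equilibrium life table
#'
#' Survivorship and queen production of a monogyne colony cohort at
#' competition ratio 1: age-0 survival from the low-density rule,
#' density-dependent survival afterwards, the 50% age-6 death and the age-7
#' cap; fecundity `(S(t) - maintenance) / workers_per_queen` scaled by the
#' offspring calibration.
#'
#' @param params an [ecology_params()].
#' @return A data frame with `age`, `survivorship` (to reproduction at that
#'   age, from the egg), and `fecundity` (mean queens produced).
#' @export
monogyne_life_table <- function(params = ecology_params()) {
  max_age <- params$max_age_monogyne
  ages <- seq_len(max_age)
  s <- density_survival(ages, "monogyne", R = 1, params = params)
  s[ages == 6] <- s[ages == 6] * (1 - params$age6_death_rate)
  l <- numeric(max_age)
  l[1] <- age0_survival(1, params$low_density_growth)
  for (t in 2:max_age) l[t] <- l[t - 1] * s[t - 1]
  m <- ifelse(ages >= 2, expected_queen_mean(ages, 1, params), 0)
  data.frame(age = ages, survivorship = l, fecundity = m)
}

#' Generation time of monogyne colonies
#'
#' Mean mother (colony) age at daughter production in a panmictic population
#' at equilibrium: `sum(t * l_t * m_t) / sum(l_t * m_t)` over the
#' [monogyne_life_table()].
#'
#' @param params an [ecology_params()].
#' @return Years.
#' @export
monogyne_generation_time <- function(params = ecology_params()) {
  lt <- monogyne_life_table(params)
  w <- lt$survivorship * lt$fecundity
  sum(lt$age * w) / sum(w)
}

#' Effective generation time of polygyne colonies
#'
#' With yearly representative-queen replacement, a queen genotype installed at
#' (queen) age 1 produces daughters from age 2 on, and persists only while the
#' colony neither replaces it (probability `queen_replacement_prob` per year)
#' nor dies; yearly genotype retention is
#' `(1 - replacement_prob) * density_survival` and the mean mother age is
#' `2 + ret / (1 - ret)`.
#'
#' @param params an [ecology_params()].
#' @return Years (between 2 and 3 at the default 50% replacement rate).
#' @export
polygyne_generation_time <- function(params = ecology_params()) {
  s <- density_survival(25, "polygyne", R = 1, params = params) # mature colony
  ret <- (1 - params$queen_replacement_prob) * s
  2 + ret / (1 - ret)
}
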