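#' Ecological and life-history parameters
#'
#' Defaults describe the fire ant system: yearly time steps, logistic colony
#' growth to 170 000 workers (monogyne; polygyne colonies hold twice as many
#' but smaller workers), queen production of one new queen per 10 800 workers
#' above a 10 000-worker maintenance threshold, density-dependent survival
#' driven by the ratio of actual to expected competition, a 1.85 km square
#' arena that supports about 100 000 monogyne colonies at equilibrium, and
#' nuptial-flight dispersal averaging 100 m (half for polygyne budding).
#'
#' @param s_max_monogyne,s_max_polygyne asymptotic worker numbers of the
#'   logistic growth curve (natives share the monogyne curve).
#' @param growth_shape,growth_rate logistic parameters: size at age `t` years
#'   is `s_max / (1 + growth_shape * exp(-growth_rate * t))`.
#' @param maintenance workers needed for basic colony maintenance.
#' @param workers_per_queen additional workers per new queen produced.
#' @param offspring_calibration multiplier on queen production compensating
#'   for the overdispersed spatial pattern competition produces.
#' @param queen_replacement_prob yearly probability a polygyne colony replaces
#'   its representative queen genotype.
#' @param replacement_fail_death colony death probability after a failed
#'   replacement.
#' @param max_age_monogyne,age6_death_rate,max_age_polygyne age-related
#'   mortality: monogyne colonies suffer `age6_death_rate` mortality at age 6
#'   and none survive past `max_age_monogyne`; polygyne colonies are capped at
#'   `max_age_polygyne` years.
#' @param low_density_growth low-density growth rate (age-0 survival is
#'   `0.1 * g / ((g - 1) * R + 1)` at competition ratio `R`).
#' @param dispersal average nuptial-flight dispersal distance in meters; the
#'   per-axis Gaussian displacement uses sigma = `dispersal * sqrt(2 / pi)` so
#'   the mean Euclidean displacement equals `dispersal`.
#' @param polygyne_dispersal_factor polygyne (budding) dispersal relative to
#'   monogyne flight.
#' @param arena_side side of the square arena in meters.
#' @param territory_mature mature-colony territory in square meters.
#' @param radius_multiplier competition reaches `radius_multiplier` times the
#'   territory radius (overlapping territories compete).
#' @param polygyne_exert polygyne competition output relative to a monogyne
#'   colony of the same age (biomass 2 x 0.6).
#' @param polygyne_pair_coeff competition coefficient between two polygyne
#'   colonies (they do not attack each other).
#' @param survival_base,survival_base_polygyne,survival_amplitude,survival_constant
#'   density-dependent survival of age >= 1 colonies:
#'   `base - amplitude * exp(-survival_constant * S_t / R)` with the
#'   monogyne-equivalent size `S_t`. `survival_constant` is a calibration hook
#'   tied to the carrying capacity.
#' @param competition_calibration multiplier on the competition ratio as it
#'   enters the survival responses inside the spatial simulator (only there;
#'   exported survival functions and the life-table layer are untouched).
#'   The survival constants are calibrated for the mean-field model, where
#'   lifetime reproduction at competition ratio 1 is ~1; in the
#'   individual-colony spatial model a colony has only a few effective
#'   competitors within range, and because density-dependent survival is
#'   (for young colonies) convex in the competition ratio, that per-colony
#'   heterogeneity pushes realised recruitment slightly above the mean-field
#'   rate.  The default (1.1) trims this so a monogyne-only population
#'   equilibrates at `capacity_monogyne`, the same carrying-capacity
#'   criterion the source model calibrated against empirically.  It rescales
#'   competition only, so the low-density growth rate (the suppression
#'   threshold) and the zero-density limits are unchanged.
#' @param capacity_monogyne equilibrium capacity of a monogyne-only
#'   population; anchors expected competition.
#' @param mate_attempts attempts an age-1 queen has to find a mate.
#' @param polygyne_male_rate selection-rate multiplier for polygyne mate
#'   colonies (they produce fewer males).
#' @param mate_radius_factor mate search radius as a multiple of the queen
#'   form's dispersal sigma.
#' @param mate_fallback_k nearest-k fallback when no candidate is in range.
#' @param mass_factor_polygyne worker mass of polygyne relative to monogyne
#'   (biomass bookkeeping).
#' @return An object of class `ecology_params`.
#' @export
ecology_params <- function(s_max_monogyne = 170000, s_max_polygyne = 340000,
                           growth_shape = 66, growth_rate = 1.3,
                           maintenance = 10000, workers_per_queen = 10800,
                           offspring_calibration = 0.95,
                           queen_replacement_prob = 0.5,
                           replacement_fail_death = 0.8,
                           max_age_monogyne = 7, age6_death_rate = 0.5,
                           max_age_polygyne = 70,
                           low_density_growth = 6,
                           dispersal = 100, polygyne_dispersal_factor = 0.5,
                           arena_side = 1850,
                           territory_mature = 100, radius_multiplier = 2,
                           polygyne_exert = 1.2, polygyne_pair_coeff = 1 / 1.2,
                           survival_base = 0.95, survival_base_polygyne = 0.9,
                           survival_amplitude = 0.6714,
                           survival_constant = 2.2221e-5,
                           competition_calibration = 1.1,
                           capacity_monogyne = 100000,
                           mate_attempts = 10,
                           polygyne_male_rate = 0.837352526,
                           mate_radius_factor = 2, mate_fallback_k = 50,
                           mass_factor_polygyne = 0.6) {
  p <- as.list(environment())
  stopifnot(p$low_density_growth > 1, p$arena_side > 0,
            p$queen_replacement_prob >= 0, p$queen_replacement_prob <= 1,
            p$replacement_fail_death >= 0, p$replacement_fail_death <= 1)
  structure(p, class = "ecology_params")
}

#' Colony size from the logistic growth curve
#'
#' `S = S_max / (1 + 66 exp(-1.3 t))` with `S_max` 170 000 workers for
#' monogyne (and native) colonies and 340 000 for polygyne colonies.
#'
#' @param t colony age in years (vectorised, `t >= 0`).
#' @param form `"monogyne"` or `"polygyne"` (native colonies use the monogyne
#'   curve); recycled against `t`.
#' @param params an [ecology_params()].
#' @return Worker numbers.
#' @examples
#' colony_size(1)                      # a young colony, ~8950 workers
#' colony_size(10, form = "polygyne")  # mature polygyne colony
#' @export
colony_size <- function(t, form = "monogyne", params = ecology_params()) {
  if (any(t < 0)) stop("colony age must be >= 0")
  smax <- ifelse(form == "polygyne", params$s_max_polygyne, params$s_max_monogyne)
  smax / (1 + params$growth_shape * exp(-params$growth_rate * t))
}

# Monogyne-equivalent size, the quantity entering queen production,
# competition and survival for both social forms.
size_monogyne <- function(t, params) {
  params$s_max_monogyne / (1 + params$growth_shape * exp(-params$growth_rate * t))
}

#' Mean queen production of a colony
#'
#' Poisson mean for yearly new-queen output:
#' `max(0, (S(t) - maintenance) / workers_per_queen)` scaled by the
#' offspring calibration factor and the queen's fecundity multiplier.  Both
#' social forms use the monogyne-equivalent size: polygyne colonies hold
#' twice the workers, but those workers are smaller and less healthy, so the
#' model approximates equal raw queen production at equal age (the greenbeard
#' cull of SB/SB alates and Sb/Sb lethality then halve the realised polygyne
#' output).
#'
#' @param t colony age in years.
#' @param fecundity queen fecundity multiplier (see [fecundity_multiplier()]).
#' @param params an [ecology_params()].
#' @return The Poisson mean (not a draw).
#' @export
expected_queen_mean <- function(t, fecundity = 1, params = ecology_params()) {
  pmax(0, (size_monogyne(t, params) - params$maintenance) /
         params$workers_per_queen) *
    params$offspring_calibration * fecundity
}

#' Survival of newly founded (age-0) colonies
#'
#' `0.1 * g / ((g - 1) * R + 1)` where `g` is the low-density growth rate and
#' `R` the competition ratio; equals 0.1 exactly at `R = 1` and `0.1 * g` in
#' empty space.
#'
#' @param R competition ratio (actual / expected competition), `>= 0`.
#' @param g low-density growth rate, `> 1`.
#' @return Survival probabilities clamped to `[0, 1]`.
#' @export
age0_survival <- function(R, g = 6) {
  if (any(R < 0)) stop("competition ratio must be >= 0")
  if (g <= 1) stop("low-density growth rate must exceed 1")
  pmin(1, pmax(0, 0.1 * g / ((g - 1) * R + 1)))
}

#' Density-dependent survival of established colonies
#'
#' `L - 0.6714 * exp(-(2.2221 / 100000) * S_t / R)` with `L` 0.95 for
#' monogyne/native colonies and 0.9 for polygyne, `S_t` the
#' monogyne-equivalent colony size at age `t`, and `R` the competition ratio.
#' Survival decreases with `R` and increases with colony size; the constants
#' are calibrated so that the lifetime reproduction of a monogyne queen at
#' `R = 1` is close to 1.
#'
#' @param t colony age in years (`>= 1`).
#' @param form `"monogyne"` or `"polygyne"`.
#' @param R competition ratio, `> 0`.
#' @param params an [ecology_params()].
#' @return Survival probabilities clamped to `[0, 1]`.
#' @export
density_survival <- function(t, form = "monogyne", R = 1, params = ecology_params()) {
  if (any(R <= 0)) stop("competition ratio must be > 0")
  L <- ifelse(form == "polygyne", params$survival_base_polygyne, params$survival_base)
  S <- size_monogyne(t, params)
  pmin(1, pmax(0, L - params$survival_amplitude *
                 exp(-params$survival_constant * S / R)))
}

#' Stationary age distribution at equilibrium
#'
#' Iterates the age-structured survival recursion at competition ratio 1
#' (density survival, the 50% age-6 death and the age cap for monogyne; the
#' queen-replacement process and age cap for polygyne) to its fixed point.
#' The result is the within-year age distribution of established colonies
#' (ages 1 up to the cap) used for expected competition and initialisation.
#'
#' @param form `"monogyne"` or `"polygyne"`.
#' @param params an [ecology_params()].
#' @param tol fixed-point tolerance.
#' @return A named vector of proportions over ages (sums to 1).
#' @export
stationary_age_distribution <- function(form = c("monogyne", "polygyne"),
                                        params = ecology_params(), tol = 1e-10) {
  form <- match.arg(form)
  max_age <- if (form == "monogyne") params$max_age_monogyne else params$max_age_polygyne
  ages <- seq_len(max_age)
  s <- density_survival(ages, form, R = 1, params = params)
  if (form == "monogyne") {
    s[ages == 6] <- s[ages == 6] * (1 - params$age6_death_rate)
  }
  # polygyne: queen replacement succeeds in a healthy population, so the
  # replacement process adds no baseline mortality; only density survival
  # and the hard age cap shape the schedule
  s[max_age] <- 0 # hard cap
  # fixed point of the recursion n_{t+1} = n_t * s_t with unit yearly inflow
  n <- rep(1, max_age)
  repeat {
    n2 <- c(1, (n * s)[-max_age])
    if (max(abs(n2 - n)) < tol) break
    n <- n2
  }
  setNames(n2 / sum(n2), ages)
}
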