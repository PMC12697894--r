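# Arena geometry, dispersal, and the colony competition model.

#' Nuptial-flight dispersal draw
#'
#' Displaces offspring from their mother by independent per-axis Gaussian
#' draws with sigma chosen so the mean Euclidean displacement equals the
#' configured average dispersal distance (`sigma = mean * sqrt(2 / pi)`,
#' the Rayleigh-mean identity).  Positions falling outside the arena are fully
#' redrawn (displacement resampled, not truncated).
#'
#' @param x,y origin coordinates (vectorised).
#' @param mean_dispersal average dispersal distance in meters per offspring
#'   (recycled).
#' @param side arena side length in meters.
#' @return A list with numeric vectors `x` and `y` inside `[0, side]^2`.
#' @export
dispersal_draw <- function(x, y, mean_dispersal, side) {
  n <- length(x)
  sigma <- rep_len(mean_dispersal, n) * sqrt(2 / pi)
  nx <- x + rnorm(n, 0, sigma)
  ny <- y + rnorm(n, 0, sigma)
  bad <- which(nx < 0 | nx > side | ny < 0 | ny > side)
  while (length(bad) > 0) {
    nx[bad] <- x[bad] + rnorm(length(bad), 0, sigma[bad])
    ny[bad] <- y[bad] + rnorm(length(bad), 0, sigma[bad])
    ok <- nx[bad] >= 0 & nx[bad] <= side & ny[bad] >= 0 & ny[bad] <= side
    bad <- bad[!ok]
  }
  list(x = nx, y = ny)
}

#' Competition radius of a colony
#'
#' A mature colony holds a 100 m^2 territory; younger colonies hold territory
#' proportional to their monogyne-equivalent biomass.  The radius yielding the
#' territory area is doubled so colonies with overlapping territories compete:
#' `r_t = 2 * sqrt(A_t / pi)` with `A_t = 100 * S(t) / 170000`.
#'
#' @param t colony age in years (`>= 1`); polygyne colonies use the same
#'   (monogyne-equivalent) territory as monogyne colonies of the same age.
#' @param params an [ecology_params()].
#' @return Radius in meters.
#' @examples
#' competition_radius(25)  # mature: 2 * sqrt(100 / pi) ~ 11.28 m
#' @export
competition_radius <- function(t, params = ecology_params()) {
  area <- params$territory_mature * size_monogyne(t, params) / params$s_max_monogyne
  params$radius_multiplier * sqrt(area / pi)
}

#' Pairwise competition exerted by one colony on another
#'
#' Interaction strength declines linearly from the source's
#' monogyne-equivalent size at distance 0 to zero at the source's competition
#' radius.  Polygyne sources exert 20% more (biomass 2 x 0.6); competition
#' between two polygyne colonies is scaled by 1/1.2 (they do not attack each
#' other); cross-species interactions are scaled by the interspecies factor.
#'
#' @param source_age source colony age in years.
#' @param d distance between the colonies in meters.
#' @param source_form,focal_form `"monogyne"` or `"polygyne"`.
#' @param cross_species_f multiplier applied when source and focal belong to
#'   different species (1 for conspecifics).
#' @param params an [ecology_params()].
#' @return Competition in monogyne-worker units.
#' @export
pairwise_competition <- function(source_age, d, source_form = "monogyne",
                                 focal_form = "monogyne", cross_species_f = 1,
                                 params = ecology_params()) {
  r <- competition_radius(source_age, params)
  s <- size_monogyne(source_age, params)
  s <- ifelse(source_form == "polygyne", s * params$polygyne_exert, s)
  coeff <- ifelse(source_form == "polygyne" & focal_form == "polygyne",
                  params$polygyne_pair_coeff, 1)
  ifelse(d >= r, 0, s * (1 - d / r) * coeff * cross_species_f)
}

# Per-age expected competition integral for one source class:
# S_eff * density * pi * r_t^2 / 3 summed over source ages, where density is
# colonies of that age per square meter.  `exert` is 1 (monogyne/native) or
# polygyne_exert.
.expected_term <- function(n_total, age_dist, exert, arena_area, params) {
  ages <- as.numeric(names(age_dist))
  s <- size_monogyne(ages, params) * exert
  r <- competition_radius(ages, params)
  sum(s * (n_total * age_dist / arena_area) * pi * r^2 / 3)
}

#' Expected competition reference values
#'
#' The expected competition a colony would experience in a uniformly random
#' population at carrying capacity: the denominator of the competition ratio
#' `R`.  Fire-ant-only scenarios anchor on the monogyne-only capacity
#' (100 000 colonies by default).  With a competing native species the
#' cross-species terms are scaled by the interspecies factor `f`
#' (symmetrically when both species hold exclusive niches; in the invasion
#' scenario each species anchors on its own full-arena capacity and only the
#' native-on-fire direction is reduced).
#'
#' @param scenario a [scenario_config()].
#' @param params an [ecology_params()].
#' @return A named list with components `fire` and `native` (competition
#'   units; `native` is `NA` in fire-only scenarios).
#' @export
expected_competition <- function(scenario, params = ecology_params()) {
  A <- params$arena_side^2
  q_mono <- stationary_age_distribution("monogyne", params)
  mono_term <- function(n) .expected_term(n, q_mono, 1, A, params)
  poly_term <- function(n) {
    .expected_term(n, stationary_age_distribution("polygyne", params),
                   params$polygyne_exert, A, params)
  }
  f <- scenario$interspecies_f
  switch(scenario$scenario,
    monogyne_only = ,
    polygyne_only = ,
    mixed = list(fire = mono_term(params$capacity_monogyne), native = NA_real_),
    native_coexist = {
      fire_own <- mono_term(scenario$n_monogyne) + poly_term(scenario$n_polygyne)
      native_own <- mono_term(scenario$n_native)
      list(fire = fire_own + f * native_own,
           native = f * fire_own + native_own)
    },
    invasion = list(fire = mono_term(params$capacity_monogyne),
                    native = mono_term(params$capacity_monogyne)),
    stop("unknown scenario"))
}

# Actual competition received by each row of `recv` from sources age >= 1.
# Both inputs are population data frames (see `new_population`).  Returns a
# numeric vector aligned with `recv`.
actual_competition <- function(src, recv, scenario, params) {
  if (nrow(src) == 0 || nrow(recv) == 0) return(numeric(nrow(recv)))
  strength <- size_monogyne(src$age, params) *
    ifelse(src$form == FORM_POLYGYNE, params$polygyne_exert, 1)
  radius <- competition_radius(src$age, params)
  f_nf <- 1; f_fn <- 1
  if (scenario$scenario == "native_coexist")
    f_nf <- f_fn <- scenario$interspecies_f
  if (scenario$scenario == "invasion") {
    f_nf <- scenario$interspecies_f # native on fire reduced
    f_fn <- 1                       # fire on native at full strength
  }
  cpp_competition(src$x, src$y, strength, radius,
                  src$form, src$species, src$id,
                  recv$x, recv$y, recv$form, recv$species, recv$id,
                  params$polygyne_pair_coeff, f_nf, f_fn)
}

# Reference (brute-force all-pairs) actual competition; used to validate the
# grid-indexed computation.
actual_competition_bruteforce <- function(src, recv, scenario, params) {
  out <- numeric(nrow(recv))
  if (nrow(src) == 0) return(out)
  f_nf <- 1; f_fn <- 1
  if (scenario$scenario == "native_coexist")
    f_nf <- f_fn <- scenario$interspecies_f
  if (scenario$scenario == "invasion") {
    f_nf <- scenario$interspecies_f; f_fn <- 1
  }
  for (j in seq_len(nrow(recv))) {
    d <- sqrt((src$x - recv$x[j])^2 + (src$y - recv$y[j])^2)
    keep <- src$id != recv$id[j]
    sf <- ifelse(src$form == FORM_POLYGYNE, "polygyne", "monogyne")
    ff <- if (recv$form[j] == FORM_POLYGYNE) "polygyne" else "monogyne"
    cross <- ifelse(src$species == recv$species[j], 1,
                    ifelse(src$species == SP_NATIVE, f_nf, f_fn))
    out[j] <- sum(pairwise_competition(src$age[keep], d[keep], sf[keep], ff,
                                       cross[keep], params))
  }
  out
}

#' Clark-Evans nearest-neighbor index
#'
#' Ratio of the mean observed nearest-neighbor distance to the expectation
#' under complete spatial randomness, `0.5 / sqrt(density)`.  Values near 1
#' indicate randomness, below 1 clustering (the patchiness signature of
#' chasing dynamics), above 1 overdispersion (the signature of territorial
#' competition).
#'
#' @param x,y point coordinates (at least 2 points).
#' @param area study area in square meters; defaults to the bounding-box area.
#' @return The dimensionless index.
#' @export
nearest_neighbor_index <- function(x, y, area = NULL) {
  n <- length(x)
  if (n < 2) stop("nearest-neighbor index requires at least 2 points")
  if (is.null(area)) area <- diff(range(x)) * diff(range(y))
  if (area <= 0) return(0)
  mean_nn <- mean(cpp_nn_dist(as.numeric(x), as.numeric(y)))
  expected <- 0.5 / sqrt(n / area)
  mean_nn / expected
}
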