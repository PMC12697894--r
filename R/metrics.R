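# Biomass and allele-frequency metrics, spatial slicing, and file output.

#' Total ant biomass
#'
#' Biomass in units of one monogyne colony worker:
#' `sum(colony_size(age, form) * mass_factor)` over established colonies
#' (age >= 1), with mass factor 1 for monogyne/native colonies and 0.6 for
#' polygyne colonies (whose workers are ~60% the size).
#'
#' @param pop a colony data frame.
#' @param params an [ecology_params()].
#' @param species `"fire"`, `"native"` or `"all"`.
#' @return Biomass in monogyne-worker units.
#' @export
total_biomass <- function(pop, params = ecology_params(), species = "fire") {
  keep <- pop$age >= 1L
  if (species == "fire") keep <- keep & pop$species == SP_FIRE
  if (species == "native") keep <- keep & pop$species == SP_NATIVE
  if (!any(keep)) return(0)
  form <- ifelse(pop$form[keep] == FORM_POLYGYNE, "polygyne", "monogyne")
  mass <- ifelse(pop$form[keep] == FORM_POLYGYNE, params$mass_factor_polygyne, 1)
  sum(colony_size(pop$age[keep], form, params) * mass)
}

# Biomass per colony row (0 for age-0 colonies); internal.
colony_biomass <- function(pop, params) {
  out <- numeric(nrow(pop))
  keep <- pop$age >= 1L
  form <- ifelse(pop$form == FORM_POLYGYNE, "polygyne", "monogyne")
  mass <- ifelse(pop$form == FORM_POLYGYNE, params$mass_factor_polygyne, 1)
  out[keep] <- colony_size(pop$age[keep], form[keep], params) * mass[keep]
  out
}

#' Allele frequencies in the colony population
#'
#' Frequencies are counted over the fire-ant queens' diploid genomes plus the
#' stored haploid mate genomes (males are not agents, so mated-queen sperm is
#' the male allele pool).  `drive_frequency()` returns the drive-allele
#' frequency at the drive's carrier locus (the drive site for two-target
#' variants, the fertility locus otherwise) and errors on an empty
#' population.
#'
#' @param pop a colony data frame.
#' @param config a [drive_config()].
#' @return `allele_frequencies()`: a list with `drive`, `resistance`
#'   (nonfunctional fertility-locus resistance) and `sb` frequencies;
#'   `drive_frequency()`: a single frequency.
#' @export
allele_frequencies <- function(pop, config = drive_config()) {
  fire <- pop[pop$species == SP_FIRE, , drop = FALSE]
  n_q <- nrow(fire)
  if (n_q == 0)
    return(list(drive = NA_real_, resistance = NA_real_, sb = NA_real_))
  mated <- !is.na(fire$mf)
  denom <- 2 * n_q + sum(mated)
  if (uses_drive_site(config)) {
    dcount <- sum(fire$d1 == DS_D, fire$d2 == DS_D, fire$md[mated] == DS_D,
                  na.rm = TRUE)
  } else {
    dcount <- sum(fire$f1 == FERT_D, fire$f2 == FERT_D, fire$mf[mated] == FERT_D,
                  na.rm = TRUE)
  }
  rcount <- sum(fire$f1 %in% c(FERT_R, FERT_RD), fire$f2 %in% c(FERT_R, FERT_RD),
                fire$mf[mated] %in% c(FERT_R, FERT_RD))
  sbcount <- sum(fire$s1 == SOC_Sb, fire$s2 == SOC_Sb, fire$ms[mated] == SOC_Sb)
  list(drive = dcount / denom, resistance = rcount / denom, sb = sbcount / denom)
}

#' @rdname allele_frequencies
#' @export
drive_frequency <- function(pop, config = drive_config()) {
  if (sum(pop$species == SP_FIRE) == 0)
    stop("drive frequency is undefined for an empty population")
  allele_frequencies(pop, config)$drive
}

#' Biomass by vertical arena slice
#'
#' Splits the arena into `n_slices` equal vertical strips and totals biomass
#' per strip and species, the bookkeeping used to track invasion fronts.
#'
#' @param pop a colony data frame.
#' @param params an [ecology_params()].
#' @param n_slices number of strips.
#' @return A data frame with `slice`, `fire`, `native` biomass columns; the
#'   slice totals sum to the arena totals.
#' @export
slice_biomass <- function(pop, params = ecology_params(), n_slices = 10) {
  side <- params$arena_side
  idx <- pmin(n_slices, 1L + as.integer(floor(pop$x / side * n_slices)))
  bm <- colony_biomass(pop, params)
  agg <- function(sp) {
    v <- numeric(n_slices)
    sel <- pop$species == sp
    if (any(sel)) {
      sums <- tapply(bm[sel], idx[sel], sum)
      v[as.integer(names(sums))] <- sums
    }
    v
  }
  data.frame(slice = seq_len(n_slices), fire = agg(SP_FIRE), native = agg(SP_NATIVE))
}

# One row of the per-year record.
year_record <- function(year, pop, config) {
  eco <- config$ecology
  fire <- pop$species == SP_FIRE
  freqs <- allele_frequencies(pop, config$drive)
  nn <- NA_real_
  if (sum(fire) >= 2)
    nn <- nearest_neighbor_index(pop$x[fire], pop$y[fire],
                                 area = eco$arena_side^2)
  data.frame(
    year = year,
    n_colonies = nrow(pop),
    n_fire = sum(fire),
    n_fire_monogyne = sum(fire & pop$form == FORM_MONOGYNE),
    n_fire_polygyne = sum(fire & pop$form == FORM_POLYGYNE),
    n_native = sum(!fire),
    biomass_fire = total_biomass(pop, eco, "fire"),
    biomass_fire_monogyne = {
      sel <- pop[fire & pop$form == FORM_MONOGYNE, , drop = FALSE]
      total_biomass(sel, eco, "fire")
    },
    biomass_fire_polygyne = {
      sel <- pop[fire & pop$form == FORM_POLYGYNE, , drop = FALSE]
      total_biomass(sel, eco, "fire")
    },
    biomass_native = total_biomass(pop, eco, "native"),
    freq_drive = freqs$drive,
    freq_resistance = freqs$resistance,
    freq_sb = freqs$sb,
    nn_index = nn)
}

#' Write / read a simulation time series
#'
#' One CSV row per recorded year with the column schema of the per-year
#' record: colony counts by species and social form, biomass
#' (monogyne-worker units), drive/resistance/Sb allele frequencies (counted
#' over queens plus stored mates; released but unmated males are excluded)
#' and the Clark-Evans nearest-neighbor index.
#'
#' @param records the `records` data frame of a [simulate_drive()] result.
#' @param path file path.
#' @return `write_timeseries()` the path invisibly; `read_timeseries()` the
#'   data frame.
#' @export
write_timeseries <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  read.csv(path)
}

#' Echo a resolved run configuration to JSON
#'
#' Serialises the full configuration (including seed) so a run can be
#' replayed bit-identically.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_config_echo <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(drive = unclass(config$drive), ecology = unclass(config$ecology),
              scenario = Filter(Negate(is.null), unclass(config$scenario)),
              seed = config$seed, replicates = config$replicates,
              scale = config$scale)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a spatial snapshot
#'
#' Positions, ages, forms, species and genotype columns of every colony, as
#' CSV; the raw material for nearest-neighbor/chasing analyses and movies.
#'
#' @param pop a colony data frame.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_snapshot <- function(pop, path) {
  write.csv(pop, path, row.names = FALSE)
  invisible(path)
}
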