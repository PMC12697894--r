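SCENARIOS <- c("mixed", "monogyne_only", "polygyne_only", "native_coexist",
               "invasion")

#' Scenario configuration
#'
#' Chooses the population layout and release programme.  Default initial
#' counts: 100 000 monogyne colonies alone; 61 882 polygyne alone; the mixed
#' default of 50 000 monogyne plus 30 941 polygyne (each social form holding
#' half the territory); native coexistence adds 50 000 native colonies; the
#' invasion scenario confines fire ants to the left 40% of the arena (polygyne
#' in the leftmost 20%, monogyne next) at equilibrium density with native ants
#' filling the right 60%, increases dispersal to 138.75 m, and starts the
#' release only when fire ants make up half the biomass in the left half of
#' slice 7.
#'
#' @param scenario one of `"mixed"`, `"monogyne_only"`, `"polygyne_only"`,
#'   `"native_coexist"`, `"invasion"`.
#' @param n_monogyne,n_polygyne,n_native initial colony counts (defaults per
#'   scenario, see above).
#' @param release_fraction released drive males as a fraction of the male pool
#'   produced by resident colonies (0 disables releases).
#' @param release_years number of consecutive yearly releases.
#' @param release_Sb_fraction fraction of released males carrying the
#'   polygyne Sb allele.
#' @param years simulation horizon in years.
#' @param interspecies_f interspecies competition factor in `[0, 1]`
#'   (native-coexist: symmetric; invasion: applied only to the competition
#'   native ants exert on fire ants).
#' @param dispersal_override average dispersal distance replacing the ecology
#'   default (the invasion scenario uses 138.75 m).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = SCENARIOS,
                            n_monogyne = NULL, n_polygyne = NULL,
                            n_native = NULL,
                            release_fraction = 0.15, release_years = 6,
                            release_Sb_fraction = 0.5,
                            years = 100,
                            interspecies_f = 0.5,
                            dispersal_override = NULL) {
  scenario <- match.arg(scenario)
  defaults <- switch(scenario,
    monogyne_only = c(100000, 0, 0),
    polygyne_only = c(0, 61882, 0),
    mixed = c(50000, 30941, 0),
    native_coexist = c(50000, 30941, 50000),
    invasion = c(20000, 12376, 60000))
  if (is.null(n_monogyne)) n_monogyne <- defaults[1]
  if (is.null(n_polygyne)) n_polygyne <- defaults[2]
  if (is.null(n_native)) n_native <- defaults[3]
  if (scenario == "invasion" && is.null(dispersal_override))
    dispersal_override <- 138.75
  stopifnot(n_monogyne >= 0, n_polygyne >= 0, n_native >= 0,
            release_fraction >= 0, release_years >= 0,
            release_Sb_fraction >= 0, release_Sb_fraction <= 1,
            interspecies_f >= 0, interspecies_f <= 1, years >= 1)
  structure(list(scenario = scenario,
                 n_monogyne = n_monogyne, n_polygyne = n_polygyne,
                 n_native = n_native,
                 release_fraction = release_fraction,
                 release_years = release_years,
                 release_Sb_fraction = release_Sb_fraction,
                 years = years,
                 interspecies_f = interspecies_f,
                 dispersal_override = dispersal_override),
            class = "scenario_config")
}

#' Full run configuration
#'
#' Bundles drive performance, ecology and scenario with the random seed and
#' replicate count; the unit consumed by [simulate_drive()] and the command
#' line interface.
#'
#' @param drive a [drive_config()].
#' @param ecology an [ecology_params()].
#' @param scenario a [scenario_config()].
#' @param seed base random seed.
#' @param replicates number of replicates.
#' @param scale density-preserving spatial scale already applied (1 = full
#'   arena); set through [make_fixture()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(drive = drive_config(), ecology = ecology_params(),
                       scenario = scenario_config("mixed"),
                       seed = 1L, replicates = 1L, scale = 1) {
  stopifnot(inherits(drive, "drive_config"), inherits(ecology, "ecology_params"),
            inherits(scenario, "scenario_config"), scale > 0, scale <= 1)
  structure(list(drive = drive, ecology = ecology, scenario = scenario,
                 seed = as.integer(seed), replicates = as.integer(replicates),
                 scale = scale),
            class = "run_config")
}

#' Density-preserving scaled fixture
#'
#' Scales the arena area and every colony count/capacity by `scale` while
#' preserving densities, so competition ratios and per-capita dynamics are
#' unchanged; used for fast desk-scale runs of the full model.
#'
#' @param config a [run_config()].
#' @param scale fraction of the full problem size in `(0, 1]`.
#' @return A new `run_config` with scaled ecology and scenario; counts are
#'   rounded to integers.
#' @examples
#' small <- make_fixture(run_config(), scale = 0.04)
#' small$ecology$capacity_monogyne   # 4000 colonies, same density
#' @export
make_fixture <- function(config, scale) {
  stopifnot(inherits(config, "run_config"), scale > 0, scale <= 1)
  eco <- config$ecology
  sc <- config$scenario
  eco$arena_side <- eco$arena_side * sqrt(scale)
  eco$capacity_monogyne <- round(eco$capacity_monogyne * scale)
  for (fld in c("n_monogyne", "n_polygyne", "n_native"))
    sc[[fld]] <- round(sc[[fld]] * scale)
  run_config(drive = config$drive, ecology = eco, scenario = sc,
             seed = config$seed, replicates = config$replicates,
             scale = config$scale * scale)
}

# Effective dispersal distance by form, honouring the scenario override.
dispersal_mean <- function(form, ecology, scenario) {
  base <- if (is.null(scenario$dispersal_override)) ecology$dispersal
          else scenario$dispersal_override
  ifelse(form == FORM_POLYGYNE, base * ecology$polygyne_dispersal_factor, base)
}

#' Read / write a run configuration as YAML
#'
#' `read_run_config()` loads a YAML file holding any subset of the `drive`,
#' `ecology`, `scenario`, `seed`, `replicates` and `scale` fields (missing
#' entries take package defaults); `write_run_config()` writes the fully
#' resolved configuration back, producing a lossless round trip.
#'
#' @param path file path.
#' @param config a [run_config()].
#' @return `read_run_config()` a [run_config()]; `write_run_config()` the
#'   path, invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  drive <- do.call(drive_config, raw$drive %||% list())
  ecology <- do.call(ecology_params, raw$ecology %||% list())
  scen <- do.call(scenario_config, raw$scenario %||% list())
  run_config(drive = drive, ecology = ecology, scenario = scen,
             seed = raw$seed %||% 1L, replicates = raw$replicates %||% 1L,
             scale = raw$scale %||% 1)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(drive = unclass(config$drive),
              ecology = unclass(config$ecology),
              scenario = Filter(Negate(is.null), unclass(config$scenario)),
              seed = config$seed, replicates = config$replicates,
              scale = config$scale)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
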