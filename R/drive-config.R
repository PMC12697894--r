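DRIVE_VARIANTS <- c("standard", "dominant_sterile", "two_target_haplosufficient",
                    "two_target_haplolethal", "polygyne_drive", "greenbeard_drive",
                    "cleave_SB", "cleave_Sb")

#' Drive performance configuration
#'
#' Bundles the performance rates of the homing suppression drive and selects
#' the active drive variant.  Defaults correspond to an effective but imperfect
#' drive calibrated on a constructed *Anopheles gambiae* drive: conversion
#' 0.95, germline resistance 0.5, embryo resistance 0.05, somatic fitness 0.98.
#'
#' @param conversion probability that a wild-type allele in a drive
#'   heterozygote's germline is converted to a drive copy.
#' @param germline_resistance probability that a cut, non-converted wild-type
#'   allele becomes a (nonfunctional) resistance allele.  By default this is
#'   *conditional* on non-conversion, so the net germline resistance rate is
#'   `(1 - conversion) * germline_resistance` and the total cut rate is
#'   `conversion + (1 - conversion) * germline_resistance`; set
#'   `germline_res_absolute = TRUE` for the additive reading in which
#'   conversion and resistance are both absolute probabilities (resistance is
#'   then capped at `1 - conversion`).
#' @param embryo_resistance probability that a wild-type allele in an offspring
#'   of a drive-carrying mother is converted to a resistance allele by
#'   maternally deposited Cas9.
#' @param somatic_fitness fecundity multiplier in `[0, 1]` for drive/wild-type
#'   heterozygous females (leaky somatic Cas9 expression).
#' @param variant drive variant, one of `"standard"`, `"dominant_sterile"`,
#'   `"two_target_haplosufficient"`, `"two_target_haplolethal"`,
#'   `"polygyne_drive"`, `"greenbeard_drive"`, `"cleave_SB"`, `"cleave_Sb"`.
#' @param germline_res_absolute logical; see `germline_resistance`.
#' @return An object of class `drive_config`.
#' @examples
#' drive_config()                                   # Table-style defaults
#' drive_config(conversion = 1, somatic_fitness = 1) # a perfect drive
#' @export
drive_config <- function(conversion = 0.95, germline_resistance = 0.5,
                         embryo_resistance = 0.05, somatic_fitness = 0.98,
                         variant = DRIVE_VARIANTS,
                         germline_res_absolute = FALSE) {
  variant <- match.arg(variant)
  probs <- c(conversion = conversion, germline_resistance = germline_resistance,
             embryo_resistance = embryo_resistance, somatic_fitness = somatic_fitness)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all drive rates must lie in [0, 1]")
  structure(list(conversion = conversion,
                 germline_resistance = germline_resistance,
                 embryo_resistance = embryo_resistance,
                 somatic_fitness = somatic_fitness,
                 variant = variant,
                 germline_res_absolute = germline_res_absolute),
            class = "drive_config")
}

#' @export
print.drive_config <- function(x, ...) {
  cat(sprintf(
    "<drive_config> variant %s: conversion %.3g, germline resistance %.3g (%s), embryo resistance %.3g, somatic fitness %.3g\n",
    x$variant, x$conversion, x$germline_resistance,
    if (x$germline_res_absolute) "absolute" else "conditional",
    x$embryo_resistance, x$somatic_fitness))
  invisible(x)
}

# Does the variant use a second (drive-site) locus?
uses_drive_site <- function(config) {
  config$variant %in% c("two_target_haplosufficient", "two_target_haplolethal")
}

# Resistance allele state produced at the fertility locus.
fert_res_code <- function(config) {
  if (config$variant == "dominant_sterile") FERT_RD else FERT_R
}

# Net per-allele germline resistance probability (given no conversion).
germline_res_net <- function(config) {
  if (config$germline_res_absolute) {
    min(config$germline_resistance, 1 - config$conversion)
  } else {
    (1 - config$conversion) * config$germline_resistance
  }
}

#' Total germline cut rate of the drive
#'
#' Probability that a wild-type allele in the germline of a drive carrier is
#' cut at all (converted to drive or mutated to resistance).  This is the axis
#' along which dominant-sterile and two-target designs retain high genetic
#' load even when conversion itself is low.
#'
#' @param config a [drive_config()].
#' @return a probability.
#' @export
total_cut_rate <- function(config) {
  config$conversion + germline_res_net(config)
}
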