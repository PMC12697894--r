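# Integer allele codes used throughout the internal (vectorised) machinery.
# Fertility locus: W wild-type, D drive, R nonfunctional resistance,
# RD dominant-sterile resistance.  Social supergene: SB, Sb (Sb dominant
# polygyne).  Drive site (two-target variants only): W, D (drive with rescue),
# R (nonfunctional resistance).
FERT_W <- 0L; FERT_D <- 1L; FERT_R <- 2L; FERT_RD <- 3L
SOC_SB <- 0L; SOC_Sb <- 1L
DS_W <- 0L; DS_D <- 1L; DS_R <- 2L

FORM_MONOGYNE <- 1L
FORM_POLYGYNE <- 2L
SP_FIRE <- 1L
SP_NATIVE <- 2L

.fert_levels <- c("W", "D", "R", "RD")
.soc_levels <- c("SB", "Sb")
.ds_levels <- c("W", "D", "R")

fert_code <- function(x) {
  i <- match(x, .fert_levels)
  if (anyNA(i)) stop("unknown fertility allele; use ", paste(.fert_levels, collapse = "/"))
  i - 1L
}
soc_code <- function(x) {
  i <- match(x, .soc_levels)
  if (anyNA(i)) stop("unknown social allele; use SB/Sb")
  i - 1L
}
ds_code <- function(x) {
  i <- match(x, .ds_levels)
  if (anyNA(i)) stop("unknown drive-site allele; use W/D/R")
  i - 1L
}

#' Construct an ant genome
#'
#' A genome is diploid (queens, two alleles per locus) or haploid (males, one
#' allele per locus).  Loci are the female-fertility target locus, the social
#' SB/Sb supergene, and - for two-target drive variants only - the drive's own
#' (rescued essential gene) site.
#'
#' @param fertility character vector of fertility alleles: `"W"` (wild-type),
#'   `"D"` (drive), `"R"` (nonfunctional resistance), `"RD"` (dominant-sterile
#'   resistance).  Length 2 for diploid, 1 for haploid.
#' @param social social alleles, `"SB"` or `"Sb"`; same length as `fertility`.
#' @param drive_site optional drive-site alleles (`"W"`, `"D"`, `"R"`) for
#'   two-target variants; `NULL` otherwise.
#' @return An object of class `ant_genome` with integer-coded alleles and a
#'   `ploidy` field.
#' @examples
#' genome(c("D", "W"))                  # drive/wild-type heterozygous queen
#' genome("D", social = "Sb")           # haploid drive male carrying Sb
#' @export
genome <- function(fertility = c("W", "W"),
                   social = rep("SB", length(fertility)),
                   drive_site = NULL) {
  n <- length(fertility)
  if (!n %in% 1:2) stop("fertility must hold 1 (haploid) or 2 (diploid) alleles")
  if (length(social) != n) stop("social must match fertility in length")
  if (!is.null(drive_site) && length(drive_site) != n)
    stop("drive_site must match fertility in length")
  structure(list(
    ploidy = if (n == 2L) "diploid" else "haploid",
    fertility = fert_code(fertility),
    social = soc_code(social),
    drive_site = if (is.null(drive_site)) NULL else ds_code(drive_site)
  ), class = "ant_genome")
}

#' @export
print.ant_genome <- function(x, ...) {
  fmt <- function(codes, levels) paste(levels[codes + 1L], collapse = "/")
  cat(sprintf("<ant_genome %s> fertility %s, social %s%s\n",
              x$ploidy,
              fmt(x$fertility, .fert_levels),
              fmt(x$social, .soc_levels),
              if (is.null(x$drive_site)) ""
              else paste0(", drive site ", fmt(x$drive_site, .ds_levels))))
  invisible(x)
}

stop_if_not_diploid <- function(g) {
  if (!inherits(g, "ant_genome")) stop("expected an ant_genome")
  if (g$ploidy != "diploid") stop("operation requires a diploid genome")
  invisible(g)
}
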