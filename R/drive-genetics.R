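# Haplodiploid drive genetics.
#
# All inheritance logic lives in vectorised helpers operating on integer
# allele columns (used by the spatial simulator and, through exact
# enumeration, by the panmictic recursion).  The exported single-genome
# functions wrap these for interactive use and testing.

# ---- vectorised predicates on diploid female genotypes ----------------------

vec_female_fertile <- function(f1, f2, config) {
  fert <- (f1 == FERT_W) | (f2 == FERT_W)
  if (config$variant == "dominant_sterile")
    fert <- fert & (f1 != FERT_RD) & (f2 != FERT_RD)
  fert
}

vec_female_viable <- function(s1, s2, d1, d2, config) {
  ok <- !((s1 == SOC_Sb) & (s2 == SOC_Sb))
  if (config$variant == "two_target_haplosufficient")
    ok <- ok & !((d1 == DS_R) & (d2 == DS_R))
  if (config$variant == "two_target_haplolethal")
    ok <- ok & (d1 != DS_R) & (d2 != DS_R)
  ok
}

# Haploid males: a nonfunctional allele at an essential drive-site gene is
# lethal in a haploid regardless of haplosufficiency (there is no second copy).
vec_male_viable <- function(md, config) {
  if (uses_drive_site(config)) !(md == DS_R) else rep(TRUE, length(md))
}

vec_social_form <- function(f1, f2, s1, s2, config) {
  poly <- (s1 == SOC_Sb) | (s2 == SOC_Sb)
  if (config$variant == "polygyne_drive")
    poly <- poly | (f1 == FERT_D) | (f2 == FERT_D)
  ifelse(poly, FORM_POLYGYNE, FORM_MONOGYNE)
}

# TRUE when workers of a polygyne mother colony cull the new queen (greenbeard
# elimination of SB/SB alates), with the greenbeard-drive rescue.
vec_greenbeard_culled <- function(mother_form, f1, f2, s1, s2, config) {
  culled <- (mother_form == FORM_POLYGYNE) & (s1 == SOC_SB) & (s2 == SOC_SB)
  if (config$variant == "greenbeard_drive")
    culled <- culled & !((f1 == FERT_D) | (f2 == FERT_D))
  culled
}

vec_fecundity <- function(f1, f2, d1, d2, config) {
  out <- rep(1, length(f1))
  if (uses_drive_site(config)) {
    het <- ((d1 == DS_D) & (d2 == DS_W)) | ((d1 == DS_W) & (d2 == DS_D))
  } else {
    het <- ((f1 == FERT_D) & (f2 == FERT_W)) | ((f1 == FERT_W) & (f2 == FERT_D))
  }
  out[het] <- config$somatic_fitness
  out[!vec_female_fertile(f1, f2, config)] <- 0
  out
}

# Does the mother's genotype carry active Cas9 (drive allele)?
vec_mother_has_drive <- function(f1, f2, d1, d2, config) {
  if (uses_drive_site(config)) (d1 == DS_D) | (d2 == DS_D)
  else (f1 == FERT_D) | (f2 == FERT_D)
}

# ---- germline gamete formation ---------------------------------------------

# Exact per-allele-state distribution of the inherited allele at a homing
# locus for an allele pair (a1, a2), allele codes 0..3 (W, D, R[, RD]).
homing_locus_probs <- function(a1, a2, config, res_code, n_states) {
  p <- numeric(n_states)
  het <- (a1 == 1L && a2 == 0L) || (a1 == 0L && a2 == 1L)
  if (het) {
    c0 <- config$conversion
    rnet <- germline_res_net(config)
    p[1L + 1L] <- (1 + c0) / 2          # drive
    p[res_code + 1L] <- p[res_code + 1L] + rnet / 2
    p[0L + 1L] <- (1 - c0 - rnet) / 2   # surviving wild-type
  } else {
    p[a1 + 1L] <- p[a1 + 1L] + 0.5
    p[a2 + 1L] <- p[a2 + 1L] + 0.5
  }
  p
}

#' Exact gamete allele-state probabilities
#'
#' Closed-form (enumerated) distribution of the maternal gamete for a diploid
#' queen under the active drive variant: homing-locus conversion and germline
#' resistance, distant-site cutting for two-target variants, and germline
#' cleavage of the social locus for the cleave-SB/Sb variants.  Loci segregate
#' independently.
#'
#' @param mother a diploid [genome()].
#' @param config a [drive_config()].
#' @return A list of named probability vectors, one per locus
#'   (`fertility`, `social`, and `drive_site` for two-target variants).
#' @examples
#' gamete_probabilities(genome(c("D", "W")), drive_config(conversion = 0.95))
#' @export
gamete_probabilities <- function(mother, config) {
  stop_if_not_diploid(mother)
  f <- mother$fertility; s <- mother$social; d <- mother$drive_site
  if (uses_drive_site(config) && is.null(d))
    stop("two-target variants require drive_site alleles")

  if (uses_drive_site(config)) {
    dsp <- homing_locus_probs(d[1], d[2], config, res_code = DS_R, n_states = 3L)
    # distant fertility site: drive carriers cut each W allele at the total
    # cut rate (no homing there), then one allele segregates
    kappa <- if (any(d == DS_D)) total_cut_rate(config) else 0
    fp <- numeric(4)
    for (a in f) {
      if (a == FERT_W) {
        fp[FERT_R + 1L] <- fp[FERT_R + 1L] + 0.5 * kappa
        fp[FERT_W + 1L] <- fp[FERT_W + 1L] + 0.5 * (1 - kappa)
      } else fp[a + 1L] <- fp[a + 1L] + 0.5
    }
  } else {
    fp <- homing_locus_probs(f[1], f[2], config,
                             res_code = fert_res_code(config), n_states = 4L)
    dsp <- NULL
  }

  sp <- numeric(2)
  het_soc <- any(s == SOC_SB) && any(s == SOC_Sb)
  cleaving <- config$variant %in% c("cleave_SB", "cleave_Sb") &&
    any(f == FERT_D) && het_soc
  if (cleaving) {
    # ideal-efficiency germline conversion of the social locus
    sp[(if (config$variant == "cleave_SB") SOC_Sb else SOC_SB) + 1L] <- 1
  } else {
    sp[s[1] + 1L] <- sp[s[1] + 1L] + 0.5
    sp[s[2] + 1L] <- sp[s[2] + 1L] + 0.5
  }

  out <- list(fertility = setNames(fp, .fert_levels),
              social = setNames(sp, .soc_levels))
  if (!is.null(dsp)) out$drive_site <- setNames(dsp, .ds_levels)
  out
}

# Vectorised stochastic gamete sampler.  Mother allele columns are given
# per offspring (already expanded); returns one haploid allele per locus.
sample_gametes <- function(f1, f2, s1, s2, d1, d2, config) {
  n <- length(f1)
  if (n == 0L)
    return(list(f = integer(0), s = integer(0), d = integer(0)))
  c0 <- config$conversion
  rnet <- germline_res_net(config)

  draw_homing <- function(a1, a2, res_code) {
    het <- ((a1 == 1L) & (a2 == 0L)) | ((a1 == 0L) & (a2 == 1L))
    pick <- ifelse(runif(n) < 0.5, a1, a2)
    out <- pick
    if (any(het)) {
      u <- runif(n)
      # resolve the het case from the per-gamete allele pool {D, cut(W)}
      cutres <- ifelse(u < c0, 1L, ifelse(u < c0 + rnet, res_code, 0L))
      pool2 <- ifelse(runif(n) < 0.5, 1L, cutres)  # D vs modified W
      out[het] <- pool2[het]
    }
    out
  }

  if (uses_drive_site(config)) {
    d <- draw_homing(d1, d2, DS_R)
    f <- ifelse(runif(n) < 0.5, f1, f2)
    kappa <- total_cut_rate(config)
    carrier <- (d1 == DS_D) | (d2 == DS_D)
    cut <- carrier & (f == FERT_W) & (runif(n) < kappa)
    f[cut] <- FERT_R
  } else {
    f <- draw_homing(f1, f2, fert_res_code(config))
    d <- rep(NA_integer_, n)
  }

  s <- ifelse(runif(n) < 0.5, s1, s2)
  if (config$variant %in% c("cleave_SB", "cleave_Sb")) {
    carrier <- (f1 == FERT_D) | (f2 == FERT_D)
    het_soc <- (s1 != s2)
    forced <- if (config$variant == "cleave_SB") SOC_Sb else SOC_SB
    s[carrier & het_soc] <- forced
  }
  list(f = f, s = s, d = d)
}

# Vectorised embryo resistance: each W allele at a drive-targeted locus in the
# offspring independently becomes the resistance state with prob r_e when the
# mother carries a drive allele.
embryo_cut <- function(allele, active, rate, res_code) {
  hit <- active & (allele == 0L) & (runif(length(allele)) < rate)
  allele[hit] <- res_code
  allele
}

# ---- exported single-genome operations -------------------------------------

#' Draw a maternal germline gamete
#'
#' Stochastic single draw from the gamete distribution of a diploid queen
#' (see [gamete_probabilities()] for the closed form): drive conversion and
#' germline resistance at the homing locus, distant-site cutting for
#' two-target variants, social-locus cleavage for cleave variants, then
#' independent segregation of one allele per locus.
#'
#' @inheritParams gamete_probabilities
#' @return A haploid [genome()].
#' @export
female_germline_gamete <- function(mother, config) {
  stop_if_not_diploid(mother)
  f <- mother$fertility; s <- mother$social
  d <- if (is.null(mother$drive_site)) c(NA_integer_, NA_integer_) else mother$drive_site
  g <- sample_gametes(f[1], f[2], s[1], s[2], d[1], d[2], config)
  structure(list(ploidy = "haploid", fertility = g$f, social = g$s,
                 drive_site = if (uses_drive_site(config)) g$d else NULL),
            class = "ant_genome")
}

#' Apply embryo resistance from maternal Cas9
#'
#' If the mother carries a drive allele, each wild-type allele at each
#' drive-targeted locus in the offspring (haploid sons included) is converted
#' to the variant's resistance state independently with probability
#' `embryo_resistance`.
#'
#' @param offspring a haploid or diploid [genome()].
#' @param mother the diploid mother [genome()].
#' @param config a [drive_config()].
#' @return The (possibly modified) offspring genome.
#' @export
apply_embryo_resistance <- function(offspring, mother, config) {
  stop_if_not_diploid(mother)
  md <- if (is.null(mother$drive_site)) c(NA_integer_, NA_integer_) else mother$drive_site
  active <- vec_mother_has_drive(mother$fertility[1], mother$fertility[2],
                                 md[1], md[2], config)
  if (!isTRUE(active)) return(offspring)
  r <- config$embryo_resistance
  offspring$fertility <- embryo_cut(offspring$fertility, TRUE, r, fert_res_code(config))
  if (uses_drive_site(config) && !is.null(offspring$drive_site))
    offspring$drive_site <- embryo_cut(offspring$drive_site, TRUE, r, DS_R)
  offspring
}

#' Female fertility, viability, social form, greenbeard survival, fecundity
#'
#' Genotype-level rules of the model: a female is fertile if she retains a
#' functional (wild-type) allele at the fertility locus (and, under the
#' dominant-sterile variant, carries no dominant-sterile resistance allele);
#' Sb/Sb females are nonviable, as are females without a functional rescued
#' copy at the drive site under two-target variants; any Sb allele (or any
#' drive allele under the polygyne-drive variant) confers the polygyne form;
#' polygyne workers cull SB/SB new queens unless rescued by the greenbeard
#' drive; drive/wild-type heterozygous females have fecundity
#' `somatic_fitness`, sterile females 0.
#'
#' @param g,offspring a diploid [genome()].
#' @param config a [drive_config()].
#' @param mother_form the mother colony's social form, `"monogyne"` or
#'   `"polygyne"`.
#' @return `is_female_fertile`, `is_female_viable`, `greenbeard_survives`:
#'   a logical; `social_form`: `"monogyne"` or `"polygyne"`;
#'   `fecundity_multiplier`: a number in `[0, 1]`.
#' @examples
#' cfg <- drive_config()
#' is_female_fertile(genome(c("D", "D")), cfg)   # drive homozygote: sterile
#' social_form(genome(social = c("SB", "Sb")), cfg)
#' @export
is_female_fertile <- function(g, config) {
  stop_if_not_diploid(g)
  vec_female_fertile(g$fertility[1], g$fertility[2], config)
}

#' @rdname is_female_fertile
#' @export
is_female_viable <- function(g, config) {
  stop_if_not_diploid(g)
  d <- if (is.null(g$drive_site)) c(NA_integer_, NA_integer_) else g$drive_site
  vec_female_viable(g$social[1], g$social[2], d[1], d[2], config)
}

#' @rdname is_female_fertile
#' @export
social_form <- function(g, config) {
  stop_if_not_diploid(g)
  form <- vec_social_form(g$fertility[1], g$fertility[2],
                          g$social[1], g$social[2], config)
  c("monogyne", "polygyne")[form]
}

#' @rdname is_female_fertile
#' @export
greenbeard_survives <- function(mother_form, offspring, config) {
  stop_if_not_diploid(offspring)
  mform <- match.arg(mother_form, c("monogyne", "polygyne"))
  !vec_greenbeard_culled(if (mform == "polygyne") FORM_POLYGYNE else FORM_MONOGYNE,
                         offspring$fertility[1], offspring$fertility[2],
                         offspring$social[1], offspring$social[2], config)
}

#' @rdname is_female_fertile
#' @export
fecundity_multiplier <- function(g, config) {
  stop_if_not_diploid(g)
  d <- if (is.null(g$drive_site)) c(NA_integer_, NA_integer_) else g$drive_site
  vec_fecundity(g$fertility[1], g$fertility[2], d[1], d[2], config)
}
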