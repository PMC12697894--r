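test_that("gamete probabilities match exact enumeration for all fertility genotypes", {
  cfg <- drive_config(conversion = 0.95, germline_resistance = 0.5)
  rg_net <- (1 - 0.95) * 0.5
  alleles <- c("W", "D", "R")
  for (a1 in alleles) for (a2 in alleles) {
    if (match(a1, alleles) > match(a2, alleles)) next
    pr <- gamete_probabilities(genome(c(a1, a2)), cfg)$fertility
    expect_equal(sum(pr), 1)
    expect_equal(unname(pr), unname(oracle_fert_gamete(a1, a2, 0.95, rg_net)),
                 tolerance = 1e-12)
  }
  # spec-level frozen values for the heterozygote
  pr <- gamete_probabilities(genome(c("D", "W")), cfg)$fertility
  expect_equal(unname(pr[["D"]]), 0.975)
  expect_equal(unname(pr[["R"]]), 0.0125)
  expect_equal(unname(pr[["W"]]), 0.0125)
})

test_that("full conversion and wild-type mothers are degenerate cases", {
  cfg1 <- drive_config(conversion = 1)
  expect_equal(unname(gamete_probabilities(genome(c("D", "W")), cfg1)$fertility[["D"]]), 1)
  cfg <- drive_config()
  expect_equal(unname(gamete_probabilities(genome(c("W", "W")), cfg)$fertility[["W"]]), 1)
})

test_that("absolute germline resistance caps the total cut rate at 1", {
  cfg <- drive_config(conversion = 0.95, germline_resistance = 0.5,
                      germline_res_absolute = TRUE)
  expect_equal(total_cut_rate(cfg), 1)
  pr <- gamete_probabilities(genome(c("D", "W")), cfg)$fertility
  expect_equal(unname(pr[["W"]]), 0)   # every wild-type allele is cut
  cfg2 <- drive_config(conversion = 0.8, germline_resistance = 0.2,
                       germline_res_absolute = TRUE)
  pr2 <- gamete_probabilities(genome(c("D", "W")), cfg2)$fertility
  expect_equal(unname(pr2[["R"]]), 0.1)
})

test_that("Monte-Carlo gamete frequencies match closed form within 3 SE", {
  cfg <- drive_config(conversion = 0.9, germline_resistance = 0.4)
  n <- 1e5
  set.seed(42)
  g <- firedrive:::sample_gametes(rep(1L, n), rep(0L, n), rep(0L, n), rep(0L, n),
                                  rep(NA_integer_, n), rep(NA_integer_, n), cfg)
  pr <- gamete_probabilities(genome(c("D", "W")), cfg)$fertility
  for (k in 0:2) {
    p <- unname(pr[k + 1])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(g$f == k) - p), 3 * se + 1e-9)
  }
})

test_that("cleave variants convert the social locus with ideal efficiency", {
  cfgSB <- drive_config(variant = "cleave_SB")
  mom <- genome(c("D", "W"), social = c("SB", "Sb"))
  expect_equal(unname(gamete_probabilities(mom, cfgSB)$social[["Sb"]]), 1)
  cfgSb <- drive_config(variant = "cleave_Sb")
  expect_equal(unname(gamete_probabilities(mom, cfgSb)$social[["SB"]]), 1)
  # no drive, no cleavage
  wild <- genome(c("W", "W"), social = c("SB", "Sb"))
  expect_equal(unname(gamete_probabilities(wild, cfgSb)$social[["SB"]]), 0.5)
  # Monte-Carlo: no gamete from a drive SB/Sb mother carries Sb under cleave_Sb
  n <- 2e4
  set.seed(7)
  g <- firedrive:::sample_gametes(rep(1L, n), rep(0L, n), rep(0L, n), rep(1L, n),
                                  rep(NA_integer_, n), rep(NA_integer_, n), cfgSb)
  expect_equal(sum(g$s == 1L), 0)
})

test_that("embryo resistance converts wild-type alleles of drive mothers", {
  cfg <- drive_config(embryo_resistance = 1)
  mom <- genome(c("D", "W"))
  off <- genome(c("W", "W"))
  out <- apply_embryo_resistance(off, mom, cfg)
  expect_equal(out$fertility, c(2L, 2L)) # forced limit: R/R
  # mother without drive leaves offspring untouched
  out2 <- apply_embryo_resistance(genome(c("W", "W")), genome(c("W", "W")), cfg)
  expect_equal(out2$fertility, c(0L, 0L))
  # rate behaves binomially at the Table default
  cfg2 <- drive_config(embryo_resistance = 0.05)
  set.seed(1)
  hits <- replicate(4000, apply_embryo_resistance(genome("W", social = "SB"),
                                                  mom, cfg2)$fertility == 2L)
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("fertility, viability, social form, greenbeard and fecundity rules", {
  cfg <- drive_config()
  expect_false(is_female_fertile(genome(c("D", "D")), cfg))   # homozygous sterile
  expect_true(is_female_fertile(genome(c("W", "W")), cfg))
  expect_true(is_female_fertile(genome(c("W", "R")), cfg))
  expect_false(is_female_fertile(genome(c("D", "R")), cfg))
  # dominant-sterile: a single resistance allele sterilises
  cfgd <- drive_config(variant = "dominant_sterile")
  expect_false(is_female_fertile(genome(c("W", "RD")), cfgd))
  expect_false(is_female_fertile(genome(c("D", "RD")), cfgd))
  # viability
  expect_false(is_female_viable(genome(social = c("Sb", "Sb")), cfg))
  expect_true(is_female_viable(genome(social = c("SB", "Sb")), cfg))
  cfg2h <- drive_config(variant = "two_target_haplolethal")
  expect_false(is_female_viable(genome(drive_site = c("D", "R")), cfg2h))
  cfg2s <- drive_config(variant = "two_target_haplosufficient")
  expect_true(is_female_viable(genome(drive_site = c("D", "R")), cfg2s))
  expect_false(is_female_viable(genome(drive_site = c("R", "R")), cfg2s))
  # social form
  expect_equal(social_form(genome(social = c("SB", "SB")), cfg), "monogyne")
  expect_equal(social_form(genome(social = c("SB", "Sb")), cfg), "polygyne")
  cfgp <- drive_config(variant = "polygyne_drive")
  expect_equal(social_form(genome(c("D", "W")), cfgp), "polygyne")
  # greenbeard
  expect_false(greenbeard_survives("polygyne", genome(social = c("SB", "SB")), cfg))
  expect_true(greenbeard_survives("monogyne", genome(social = c("SB", "SB")), cfg))
  cfgg <- drive_config(variant = "greenbeard_drive")
  expect_true(greenbeard_survives("polygyne",
                                  genome(c("D", "W"), social = c("SB", "SB")), cfgg))
  # fecundity
  expect_equal(fecundity_multiplier(genome(c("D", "W")), cfg), 0.98)
  expect_equal(fecundity_multiplier(genome(c("W", "W")), cfg), 1)
  expect_equal(fecundity_multiplier(genome(c("D", "D")), cfg), 0)
})

test_that("two-target variants cut the distant fertility site at the total cut rate", {
  cfg <- drive_config(conversion = 0.8, germline_resistance = 0.5,
                      variant = "two_target_haplolethal")
  kappa <- total_cut_rate(cfg) # 0.8 + 0.2*0.5 = 0.9
  expect_equal(kappa, 0.9)
  mom <- genome(c("W", "W"), drive_site = c("D", "W"))
  pr <- gamete_probabilities(mom, cfg)
  expect_equal(unname(pr$fertility[["R"]]), kappa)
  expect_equal(unname(pr$fertility[["W"]]), 1 - kappa)
  # homing happens at the drive's own site
  expect_equal(unname(pr$drive_site[["D"]]), (1 + 0.8) / 2)
  # non-carriers do not cut
  mom2 <- genome(c("W", "W"), drive_site = c("W", "W"))
  expect_equal(unname(gamete_probabilities(mom2, cfg)$fertility[["W"]]), 1)
})

test_that("diploid-only operations reject haploid genomes", {
  cfg <- drive_config()
  expect_error(is_female_fertile(genome("D"), cfg), "diploid")
  expect_error(female_germline_gamete(genome("W"), cfg), "diploid")
})
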