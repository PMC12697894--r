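test_that("initialisation matches the scenario layouts", {
  # default mixed arena holds exactly 80941 colonies
  pop <- initialize_population(run_config(scenario = scenario_config("mixed")))
  expect_equal(nrow(pop), 80941)
  expect_equal(sum(pop$form == 2L), 30941)
  # single-form scenario
  cfg <- tiny_config("monogyne_only", scale = 0.02)
  popm <- initialize_population(cfg)
  expect_equal(sum(popm$form == 2L), 0)
  # invasion geometry: fire confined to the left 40%, natives to the right 60%
  cfgi <- tiny_config("invasion", scale = 0.04)
  popi <- initialize_population(cfgi)
  side <- cfgi$ecology$arena_side
  expect_true(all(popi$x[popi$species == 1L] <= 0.4 * side))
  expect_true(all(popi$x[popi$species == 2L] >= 0.4 * side))
  expect_true(all(popi$x[popi$species == 1L & popi$form == 2L] <= 0.2 * side))
  # polygyne queens are SB/Sb heterozygotes, monogyne SB/SB
  expect_true(all(popi$s1[popi$form == 2L] + popi$s2[popi$form == 2L] == 1L))
  expect_true(all(popi$s2[popi$form == 1L] == 0L))
})

test_that("identical seeds give bit-identical time series", {
  cfg <- tiny_config("mixed", scale = 0.01)
  s1 <- simulate_drive(cfg, seed = 7, years = 8)
  s2 <- simulate_drive(cfg, seed = 7, years = 8)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$final_pop, s2$final_pop)
})

test_that("age caps are respected in simulation output", {
  cfg <- tiny_config("mixed", scale = 0.02, release_fraction = 0)
  sim <- simulate_drive(cfg, seed = 3, years = 15)
  pop <- sim$final_pop
  expect_lte(max(pop$age[pop$form == 1L]), 6)   # census after age-7 death
  expect_lte(max(pop$age[pop$form == 2L]), 69)
})

test_that("released drive males carry Sb at the configured fraction", {
  set.seed(13)
  g <- firedrive:::release_male_genomes(1e4, drive_config(), scenario_config("mixed"))
  expect_true(all(g$f == 1L))
  expect_lt(abs(mean(g$s == 1L) - 0.5), 3 * sqrt(0.25 / 1e4))
  # two-target drive males carry the construct at the drive site
  g2 <- firedrive:::release_male_genomes(100,
        drive_config(variant = "two_target_haplolethal"), scenario_config("mixed"))
  expect_true(all(g2$d == 1L) && all(g2$f == 0L))
})

test_that("no release means the drive never appears", {
  cfg <- tiny_config("mixed", scale = 0.01, release_fraction = 0)
  sim <- simulate_drive(cfg, seed = 2, years = 10)
  expect_true(all(sim$records$freq_drive == 0, na.rm = TRUE))
})

test_that("drive frequency rises after release under default parameters", {
  cfg <- tiny_config("mixed", scale = 0.02)
  sim <- simulate_drive(cfg, seed = 5, years = 14)
  r <- sim$records
  expect_gt(r$freq_drive[r$year == 10], r$freq_drive[r$year == 3])
  expect_gt(r$freq_drive[r$year == 14], 0.02)
})

test_that("a perfect drive eliminates a polygyne-only population", {
  cfg <- make_fixture(run_config(
    drive = drive_config(conversion = 1, somatic_fitness = 1),
    scenario = scenario_config("polygyne_only")), 0.02)
  sim <- simulate_drive(cfg, seed = 2, years = 100)
  expect_equal(sim$termination, "eliminated")
  expect_lt(sim$last_year, 100)
})

test_that("monogyne queens reject Sb-bearing males", {
  # one monogyne queen, one father colony whose sons all carry Sb
  cfg <- run_config(ecology = ecology_params(arena_side = 100),
                    scenario = scenario_config("mixed", release_fraction = 0))
  pop <- firedrive:::new_population(2L)
  pop$id <- 1:2
  pop$x <- c(50, 55); pop$y <- c(50, 50)
  pop$age <- c(1L, 5L)
  pop$form <- c(1L, 2L)
  pop$species <- 1L
  pop$f1 <- 0L; pop$f2 <- 0L
  pop$s1 <- c(0L, 1L); pop$s2 <- c(0L, 1L)  # father queen Sb/Sb
  pop$d1 <- NA_integer_; pop$d2 <- NA_integer_
  pop$mf <- c(NA, 0L); pop$ms <- c(NA, 0L); pop$md <- NA_integer_
  set.seed(4)
  res <- firedrive:::mate_queens(pop, 50, 50, 1L, 1L, cfg, FALSE)
  expect_true(is.na(res$mf))
  # a polygyne queen accepts the same males
  res2 <- firedrive:::mate_queens(pop, 50, 50, 2L, 1L, cfg, FALSE)
  expect_false(is.na(res2$mf))
  expect_equal(res2$ms, 1L)
})

test_that("a single wild monogyne candidate in range supplies a wild SB mate", {
  cfg <- run_config(ecology = ecology_params(arena_side = 100),
                    scenario = scenario_config("mixed", release_fraction = 0))
  pop <- firedrive:::new_population(2L)
  pop$id <- 1:2; pop$x <- c(20, 30); pop$y <- c(20, 20)
  pop$age <- c(1L, 6L); pop$form <- 1L; pop$species <- 1L
  pop$f1 <- 0L; pop$f2 <- 0L; pop$s1 <- 0L; pop$s2 <- 0L
  pop$d1 <- NA_integer_; pop$d2 <- NA_integer_
  pop$mf <- c(NA, 0L); pop$ms <- c(NA, 0L); pop$md <- NA_integer_
  set.seed(8)
  res <- firedrive:::mate_queens(pop, 20, 20, 1L, 1L, cfg, FALSE)
  expect_equal(res$mf, 0L)
  expect_equal(res$ms, 0L)
})

test_that("all-sterile queens drive the population extinct within a lifespan", {
  cfg <- tiny_config("monogyne_only", scale = 0.005, release_fraction = 0)
  pop <- initialize_population(cfg)
  pop$f1 <- 1L; pop$f2 <- 1L # every queen drive-homozygous (sterile)
  set.seed(1)
  # run the cycle manually from the sterile state
  expected <- expected_competition(cfg$scenario, cfg$ecology)
  for (yr in 1:9) {
    if (nrow(pop) == 0) break
    pop$age <- pop$age + 1L
    ro <- firedrive:::reproduce_step(pop, cfg, 1e6L)
    expect_equal(nrow(ro$offspring), 0)
    pop <- firedrive:::mating_step(pop, cfg, FALSE)
    pop <- rbind(pop, ro$offspring)
    pop <- firedrive:::survival_step(pop, cfg, expected)
  }
  expect_equal(nrow(pop), 0)
})
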