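one_colony <- function(age, form, species = 1L, f = c(0L, 0L), s = c(0L, 0L),
                       mf = 0L, ms = 0L) {
  pop <- firedrive:::new_population(1L)
  pop$id <- 1L; pop$x <- 10; pop$y <- 10
  pop$age <- as.integer(age); pop$form <- as.integer(form)
  pop$species <- as.integer(species)
  pop$f1 <- f[1]; pop$f2 <- f[2]; pop$s1 <- s[1]; pop$s2 <- s[2]
  pop$d1 <- NA_integer_; pop$d2 <- NA_integer_
  pop$mf <- mf; pop$ms <- ms; pop$md <- NA_integer_
  pop
}

test_that("biomass follows colony size times mass factor", {
  expect_equal(total_biomass(one_colony(30, 1)), colony_size(30), tolerance = 1e-6)
  expect_lt(abs(total_biomass(one_colony(30, 1)) - 170000), 0.1)
  expect_equal(total_biomass(one_colony(30, 2)),
               colony_size(30, "polygyne") * 0.6, tolerance = 1e-6)
  expect_lt(abs(total_biomass(one_colony(30, 2)) - 204000), 0.1)
  expect_equal(total_biomass(firedrive:::new_population(0L)), 0)
  # age-0 colonies carry no biomass yet
  expect_equal(total_biomass(one_colony(0, 1)), 0)
})

test_that("drive frequency counts queen and stored-mate alleles", {
  pop <- one_colony(3, 1, f = c(1L, 0L), mf = 1L) # D/W queen with D mate
  expect_equal(drive_frequency(pop), 2 / 3)
  wild <- one_colony(3, 1)
  expect_equal(drive_frequency(wild), 0)
  dd <- one_colony(3, 1, f = c(1L, 1L), mf = 1L)
  expect_equal(drive_frequency(dd), 1)
  expect_error(drive_frequency(firedrive:::new_population(0L)), "empty")
  # two-target drives are counted at the drive site
  tt <- one_colony(3, 1)
  tt$d1 <- 1L; tt$d2 <- 0L; tt$md <- 1L
  expect_equal(drive_frequency(tt, drive_config(variant = "two_target_haplolethal")),
               2 / 3)
})

test_that("slice biomasses sum to the arena totals", {
  cfg <- tiny_config("invasion", scale = 0.04)
  pop <- initialize_population(cfg)
  sl <- slice_biomass(pop, cfg$ecology)
  expect_equal(sum(sl$fire), total_biomass(pop, cfg$ecology, "fire"),
               tolerance = 1e-9)
  expect_equal(sum(sl$native), total_biomass(pop, cfg$ecology, "native"),
               tolerance = 1e-9)
  # invasion layout: native biomass only in the right 60%
  expect_equal(sum(sl$native[1:4]), 0)
})

test_that("time series round-trip through CSV", {
  cfg <- tiny_config("mixed", scale = 0.01)
  sim <- simulate_drive(cfg, seed = 1, years = 5)
  path <- tempfile(fileext = ".csv")
  write_timeseries(sim$records, path)
  back <- read_timeseries(path)
  expect_equal(back, sim$records, tolerance = 1e-12, ignore_attr = TRUE)
  # 5-year run records year 0 as well
  expect_equal(nrow(back), 6)
})

test_that("a config echo replays the run bit-identically", {
  cfg <- tiny_config("mixed", scale = 0.01)
  yml <- tempfile(fileext = ".yaml")
  write_run_config(cfg, yml)
  cfg2 <- read_run_config(yml)
  expect_equal(cfg2$ecology, cfg$ecology)
  expect_equal(cfg2$drive, cfg$drive)
  s1 <- simulate_drive(cfg, seed = 3, years = 6)
  s2 <- simulate_drive(cfg2, seed = 3, years = 6)
  expect_identical(s1$records, s2$records)
  # JSON echo parses and preserves the seed
  js <- tempfile(fileext = ".json")
  write_config_echo(cfg, js)
  echo <- jsonlite::read_json(js)
  expect_equal(echo$seed, cfg$seed)
  expect_equal(echo$drive$conversion, 0.95)
})

test_that("snapshots preserve the colony table", {
  cfg <- tiny_config("mixed", scale = 0.005)
  pop <- initialize_population(cfg)
  path <- tempfile(fileext = ".csv")
  write_snapshot(pop, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(pop))
  expect_equal(back$x, pop$x, tolerance = 1e-9)
  # metrics are exactly recomputable from the snapshot
  expect_equal(total_biomass(back, cfg$ecology), total_biomass(pop, cfg$ecology))
})
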