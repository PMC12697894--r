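test_that("dispersal draws have the configured mean displacement", {
  set.seed(5)
  n <- 1e5
  side <- 1e6 # effectively unbounded
  out <- dispersal_draw(rep(side / 2, n), rep(side / 2, n), 100, side)
  d <- sqrt((out$x - side / 2)^2 + (out$y - side / 2)^2)
  expect_lt(abs(mean(d) - 100) / 100, 0.01)
  # polygyne budding moves half as far (via the halved mean)
  out2 <- dispersal_draw(rep(side / 2, n), rep(side / 2, n), 50, side)
  d2 <- sqrt((out2$x - side / 2)^2 + (out2$y - side / 2)^2)
  expect_lt(abs(mean(d2) - 50) / 50, 0.015)
  # zero dispersal leaves positions unchanged
  out0 <- dispersal_draw(c(1, 2), c(3, 4), 0, 10)
  expect_equal(out0$x, c(1, 2))
  # redraws keep everything inside the arena
  set.seed(6)
  out3 <- dispersal_draw(runif(5000, 0, 50), runif(5000, 0, 50), 100, 50)
  expect_true(all(out3$x >= 0 & out3$x <= 50 & out3$y >= 0 & out3$y <= 50))
})

test_that("competition radius scales with monogyne-equivalent territory", {
  expect_equal(competition_radius(30), 2 * sqrt(100 / pi), tolerance = 1e-6)
  expect_equal(competition_radius(30), 11.284, tolerance = 1e-3)
  expect_equal(competition_radius(1),
               sqrt(colony_size(1) / 170000) * 2 * sqrt(100 / pi),
               tolerance = 1e-6)
  expect_true(all(diff(competition_radius(1:10)) > 0))
})

test_that("pairwise competition kernel and form/species coefficients", {
  p <- ecology_params()
  S <- firedrive:::size_monogyne(5, p)
  expect_equal(pairwise_competition(5, 0), S)
  expect_equal(pairwise_competition(5, 0, source_form = "polygyne"), 1.2 * S)
  expect_equal(pairwise_competition(5, 0, "polygyne", "polygyne"), S) # 1.2/1.2
  expect_equal(pairwise_competition(5, competition_radius(5)), 0)
  expect_equal(pairwise_competition(5, competition_radius(5) / 2), S / 2 * 1,
               tolerance = 1e-10)
  expect_equal(pairwise_competition(5, 1, cross_species_f = 0.5),
               pairwise_competition(5, 1) * 0.5)
})

test_that("grid-indexed competition equals brute force on mixed instances", {
  p <- ecology_params(arena_side = 500)
  for (scen in c("mixed", "native_coexist", "invasion")) {
    sc <- scenario_config(scen)
    pop <- random_colonies(400, 500, seed = match(scen, SCENARIOS),
                           species_prob = c(0.8, 0.2))
    src <- pop[pop$age >= 1, ]
    a1 <- firedrive:::actual_competition(src, pop, sc, p)
    a2 <- firedrive:::actual_competition_bruteforce(src, pop, sc, p)
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("actual competition averages to the expected reference at capacity", {
  # uniform random population with the stationary within-year age structure
  p <- ecology_params()
  sc <- scenario_config("monogyne_only")
  q <- stationary_age_distribution("monogyne", p)
  n <- 100000
  set.seed(9)
  pop <- firedrive:::new_population(n)
  pop$id <- seq_len(n)
  pop$x <- runif(n, 0, p$arena_side); pop$y <- runif(n, 0, p$arena_side)
  pop$age <- as.integer(sample(1:7, n, TRUE, prob = q))
  pop$form <- 1L; pop$species <- 1L
  act <- firedrive:::actual_competition(pop, pop, sc, p)
  E <- expected_competition(sc, p)$fire
  expect_lt(abs(mean(act) / E - 1), 0.02)
})

test_that("expected competition limits", {
  p <- ecology_params()
  sc0 <- scenario_config("native_coexist", n_native = 0, interspecies_f = 0.5)
  scf <- scenario_config("native_coexist", interspecies_f = 0)
  # f = 0 removes the cross-species term
  own <- expected_competition(scf, p)
  with_f <- expected_competition(scenario_config("native_coexist",
                                                 interspecies_f = 0.5), p)
  expect_gt(with_f$fire, own$fire)
  # zero native capacity removes the native contribution
  expect_equal(expected_competition(sc0, p)$fire, own$fire)
})

test_that("Clark-Evans index classifies regular, coincident and random patterns", {
  g <- expand.grid(x = seq(5, 95, by = 10), y = seq(5, 95, by = 10))
  expect_gt(nearest_neighbor_index(g$x, g$y, area = 100^2), 1)
  expect_equal(nearest_neighbor_index(rep(1, 5), rep(1, 5), area = 100), 0)
  set.seed(11)
  n <- 1e4
  x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
  expect_lt(abs(nearest_neighbor_index(x, y, area = 1000^2) - 1), 0.03)
  expect_error(nearest_neighbor_index(1, 1), "at least 2")
})

test_that("grid nearest-neighbor distances equal brute force", {
  set.seed(12)
  n <- 300
  x <- runif(n, 0, 100); y <- runif(n, 0, 100)
  d1 <- firedrive:::cpp_nn_dist(x, y)
  d2 <- sapply(seq_len(n), function(i) {
    dd <- sqrt((x - x[i])^2 + (y - y[i])^2)
    min(dd[-i])
  })
  expect_equal(d1, d2, tolerance = 1e-12)
})
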