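cfg50 <- metric_config()

test_that("mixing score counts immune cells with a cancer neighbor", {
  # 5 immune cells, exactly 2 of them within 50 um of a cancer cell
  m <- make_map(
    x = c(0, 40, 500, 500, 600, 700, 900),
    y = c(0, 30, 500, 540, 800, 800, 100),
    type = c("CANCER_PROGENITOR", "T_EFF", "CANCER_CSC", "T_EFF",
             "T_EFF", "T_EFF", "T_EFF"))
  expect_equal(mixing_score(m, cfg50), 0.4)

  # immune cells but no cancer: the score is a true 0, not undefined
  m0 <- make_map(c(0, 100), c(0, 0), c("T_EFF", "T_CYT"))
  expect_equal(mixing_score(m0, cfg50), 0)

  # no immune cells: undefined, distinguishable from 0
  mc <- make_map(c(0, 100), c(0, 0), rep("CANCER_CSC", 2))
  expect_warning(v <- mixing_score(mc, cfg50), "undefined")
  expect_true(is.na(v))
})

test_that("average neighbor frequency is the mean per-cell cancer fraction", {
  # immune1 at origin: neighbors = 1 cancer + 1 immune -> 1/2
  # immune2 at (45,0): neighbors = immune1 only -> 0; mean = 1/4
  m <- make_map(
    x = c(-45, 0, 45), y = c(0, 0, 0),
    type = c("CANCER_PROGENITOR", "T_EFF", "T_EFF"))
  expect_equal(avg_neighbor_frequency(m, cfg50), 0.25)

  # every neighbor of every immune cell is cancer
  m1 <- make_map(c(0, 10, 20, 300, 310), c(0, 0, 0, 0, 0),
                 c("CANCER_CSC", "T_EFF", "CANCER_PROGENITOR",
                   "CANCER_SENESCENT", "T_CYT"))
  expect_equal(avg_neighbor_frequency(m1, cfg50), 1)

  expect_warning(avg_neighbor_frequency(
    make_map(0, 0, "CANCER_CSC"), cfg50), "undefined")
})

test_that("spatial entropy matches hand-computable distance geometries", {
  # equilateral construction: d_int = d_ext = a, p = 1/2 -> ESP = 0.5
  a <- 200
  m <- make_map(
    x = c(0, a, a / 2, a / 2),
    y = c(0, 0, a * sqrt(3) / 2, -a * sqrt(3) / 2),
    type = c("CANCER_PROGENITOR", "CANCER_PROGENITOR", "T_EFF", "T_EFF"))
  expect_equal(shannon_entropy(m, cfg50), 0.5)

  # cancer pair at distance D with immune cells on the joining segment:
  # d_int = D, d_ext = D/2, p = 2/8 -> ESP = -2 * 0.25 * log2(0.25) = 1
  D <- 400
  xs <- c(50, 120, 180, 250, 300, 370)
  m2 <- make_map(
    x = c(0, D, xs), y = rep(0, 8),
    type = c(rep("CANCER_PROGENITOR", 2), rep("T_EFF", 6)))
  expect_equal(shannon_entropy(m2, cfg50), 1)

  # single-type map (p = 1) and sub-minimal cancer sets use the 0 convention
  expect_equal(shannon_entropy(
    make_map(c(0, 50, 90), c(0, 0, 0), rep("CANCER_CSC", 3)), cfg50), 0)
  expect_equal(shannon_entropy(
    make_map(c(0, 50), c(0, 0), c("CANCER_CSC", "T_EFF")), cfg50), 0)
  expect_warning(shannon_entropy(
    cell_map(data.frame(id = integer(), x = numeric(), y = numeric(),
                        cell_type = character()),
             bounds(c(0, 1), c(0, 1))), cfg50), "undefined")
})

test_that("entropy approaches 0 as the cancer fraction approaches 1", {
  set.seed(5)
  n <- 400
  x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
  ent <- vapply(c(200, 320, 380, 396), function(n_can) {
    type <- c(rep("CANCER_PROGENITOR", n_can), rep("T_EFF", n - n_can))
    shannon_entropy(make_map(x, y, type), cfg50)
  }, numeric(1))
  expect_true(all(diff(ent) < 0))
  expect_lt(ent[length(ent)], 0.1)
})

test_that("gcross AUC matches the erf closed form and stays below r", {
  # uniform-density evaluation vs the independent closed form
  for (p_y in c(1e-4, 1e-3, 5e-3)) {
    expect_equal(gcross_auc_uniform(p_y),
                 gcross_auc_closed_form(p_y),
                 tolerance = 1e-4)
  }
  # no cancer near any immune cell -> integrand identically zero
  far <- make_map(c(0, 5000), c(0, 0), c("CANCER_CSC", "T_EFF"))
  expect_equal(gcross_auc(far, cfg50), 0)

  # saturated density: approaches but never exceeds r = 50
  dense <- grid_fixture(n_cancer = 2500, n_immune = 25, spacing = 10)
  v <- gcross_auc(dense, cfg50)
  expect_lt(v, 50)
  expect_gt(v, 40)

  # point-pattern route agrees with the uniform evaluation at the same
  # integer neighbor count
  m <- make_map(
    x = c(0, 10, -10, 0, 0, 2000), y = c(0, 0, 0, 10, -10, 0),
    type = c("T_EFF", rep("CANCER_PROGENITOR", 4), "T_EFF"))
  k <- 4 # first immune cell sees 4 cancer cells; second sees 0
  expect_equal(gcross_auc(m, cfg50),
               mean(c(gcross_auc_uniform(k / (pi * 50^2)), 0)))
  expect_warning(gcross_auc(make_map(0, 0, "CANCER_CSC"), cfg50),
                 "undefined")
})

test_that("cell ratio divides class counts and flags the empty case", {
  g <- grid_fixture(319, 100)
  expect_equal(cell_ratio(g), 3.19)
  expect_equal(cell_ratio(grid_fixture(0, 10)), 0)
  expect_warning(v <- cell_ratio(grid_fixture(5, 0)), "undefined")
  expect_true(is.na(v))
  expect_equal(cell_ratio(grid_fixture(100, 20)), 5)
})

test_that("compute_metrics is consistent with the individual metrics", {
  set.seed(9)
  m <- generate_pattern(pattern_spec("MIXED", n_cancer = 300,
                                     n_immune = 60, seed = 9))
  rec <- compute_metrics(m, cfg50, time = 12)
  expect_equal(rec$mixing_score, mixing_score(m, cfg50))
  expect_equal(rec$avg_neighbor_frequency, avg_neighbor_frequency(m, cfg50))
  expect_equal(rec$shannon_entropy, shannon_entropy(m, cfg50))
  expect_equal(rec$gcross_auc, gcross_auc(m, cfg50))
  expect_equal(rec$cell_ratio, 5)
  expect_equal(rec$n_cancer, 300)
  expect_equal(rec$n_immune, 60)
  expect_equal(rec$time, 12)

  # no immune cells: undefined metrics are NA, counts still populated
  mc <- make_map(c(0, 40, 80), c(0, 0, 0), rep("CANCER_CSC", 3))
  expect_warning(rec0 <- compute_metrics(mc, cfg50), "no immune")
  expect_true(all(is.na(rec0[c("mixing_score", "avg_neighbor_frequency",
                               "gcross_auc", "cell_ratio")])))
  expect_equal(rec0$n_cancer, 3)
  expect_equal(rec0$n_immune, 0)
})

test_that("production neighbor index equals the brute-force scan", {
  for (seed in 1:5) {
    set.seed(seed)
    nq <- sample(50:400, 1); nt <- sample(50:1600, 1)
    qx <- runif(nq, 0, 1200); qy <- runif(nq, 0, 1200)
    tx <- runif(nt, 0, 1200); ty <- runif(nt, 0, 1200)
    for (r in c(30, 50, 120)) {
      expect_identical(count_within_radius(qx, qy, tx, ty, r),
                       brute_count_within(qx, qy, tx, ty, r))
    }
  }
  # lattice points with ties exactly at the radius (inclusive convention)
  g <- expand.grid(x = seq(0, 200, 20), y = seq(0, 200, 20))
  expect_identical(count_within_radius(g$x, g$y, g$x, g$y, 40),
                   brute_count_within(g$x, g$y, g$x, g$y, 40))
})

test_that("neighbor metrics are monotone in radius and anf <= mixing", {
  for (seed in 1:8) {
    arch <- c("COLD", "MIXED", "COMPARTMENTALIZED")[seed %% 3 + 1]
    m <- generate_pattern(pattern_spec(arch, n_cancer = 400, n_immune = 80,
                                       seed = seed))
    radii <- c(30, 40, 50, 80)
    ms <- vapply(radii, function(r)
      mixing_score(m, metric_config(neighbor_radius = r)), numeric(1))
    anf <- vapply(radii, function(r)
      avg_neighbor_frequency(m, metric_config(neighbor_radius = r)),
      numeric(1))
    expect_true(all(diff(ms) >= 0))
    expect_true(all(anf <= ms + 1e-12))
  }
})

test_that("gcross AUC increases with any immune cell's local cancer count", {
  base_k <- c(0, 2, 5, 9, 20)
  aucs <- gcross_auc_uniform(base_k / (pi * 50^2))
  expect_true(all(diff(aucs) > 0))
  expect_true(all(aucs >= 0 & aucs <= 50))
})
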