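small_cfg <- function(...) {
  args <- list(dims = c(40L, 40L, 6L), seed_block = c(10L, 10L, 3L),
               duration = 10, n_replicates = 1L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_config, args)
}

test_that("initial state has the printed seeding composition", {
  cfg <- sim_config()
  set.seed(1)
  st <- init_state(cfg)
  expect_equal(sum(st$can_type > 0L), 25 * 25 * 4)
  expect_equal(sum(st$can_type == 1L), 250) # exactly 10% CSC
  expect_equal(sum(st$can_type == 2L), 2250)
  expect_equal(length(st$imm_vox), 0L) # no immune cells at the start
  expect_true(all(st$il2 == 0) && all(st$ifng == 0))
  expect_silent(validate_state(st))
  expect_error(sim_config(dims = c(10, 10, 2), seed_block = c(25, 25, 4)),
               "larger than the box")
})

test_that("domain arithmetic matches the physical box", {
  cfg <- sim_config(dims = c(500, 500, 10)) # 10 x 10 x 0.2 mm at 20 um
  expect_equal(n_voxels(cfg), 2.5e6)
  expect_equal(cfg$dims * cfg$voxel_size, c(10000, 10000, 200))
})

test_that("PK surrogate and blockade follow their closed forms", {
  cfg <- sim_config(dose = 3, dose_day = 25, pk_half_life = 60)
  expect_equal(drug_concentration(10, cfg), 0) # pre-dose level is zero
  expect_equal(drug_concentration(25, cfg), 3)
  expect_equal(drug_concentration(25 + 60, cfg), 1.5) # one half-life
  expect_equal(pd1_blockade_factor(0, cfg), 0)
  expect_equal(pd1_blockade_factor(cfg$ec50, cfg), 0.5)
  expect_equal(pd1_blockade_factor(1e12, cfg), 1, tolerance = 1e-9)
})

test_that("without killing, cancer can only grow or senesce in place", {
  cfg <- small_cfg(base_kill_prob = 0, senescent_lifespan = Inf)
  set.seed(2)
  st <- init_state(cfg)
  n0 <- sum(st$can_type > 0L)
  for (i in 1:40) {
    st <- advance(st, cfg)
    n1 <- sum(st$can_type > 0L)
    expect_gte(n1, n0)
    n0 <- n1
  }
})

test_that("no cancer anywhere means no eligible entry points", {
  cfg <- small_cfg()
  set.seed(3)
  st <- init_state(cfg)
  st$can_type[] <- 0L
  st <- advance(st, cfg)
  expect_equal(length(st$entry_points), 0L)
  expect_equal(length(st$imm_vox), 0L)
})

test_that("a forced adjacent kill removes exactly one cancer cell", {
  cfg <- small_cfg(base_kill_prob = 1, dose = 1e12, ec50 = 1e-9,
                   dose_day = 0, entry_point_density = 0,
                   csc_division_rate = 0, prog_division_rate = 0,
                   senescent_lifespan = Inf)
  set.seed(4)
  st <- init_state(cfg)
  # cancer everywhere: wherever the single T cell walks it stays adjacent
  st$can_type[] <- 2L
  st$imm_vox <- 20L + 40L * 19L + 1600L * 2L
  st$imm_type <- 1L
  st$imm_kills <- 0L
  st$imm_count <- tabulate(st$imm_vox, st$nvox)
  n0 <- sum(st$can_type > 0L)
  st <- advance(st, cfg)
  expect_equal(sum(st$can_type > 0L), n0 - 1L)
  expect_equal(st$events$kills, 1L)
  expect_equal(st$imm_kills, 1L)
  expect_equal(st$imm_type, 2L) # first kill promotes effector to cytotoxic
})

test_that("capacity invariant and event bookkeeping hold every step", {
  cfg <- small_cfg(duration = 15, dose = 3, dose_day = 2,
                   entry_point_density = 0.01)
  res <- run_simulation(cfg, sample_interval = NULL, check_state = TRUE)
  cc <- res$trajectories[[1]]$counts
  dn <- diff(cc$n_cancer)
  expected <- (cc$births - cc$kills - cc$senescent_deaths)[-1]
  expect_identical(dn, expected) # exact per-step reconciliation
})

test_that("runs are bit-reproducible from (config, seed)", {
  cfg <- small_cfg(duration = 6, dose = 3, dose_day = 2,
                   n_replicates = 2L)
  r1 <- run_simulation(cfg, sample_interval = 3, keep_snapshots = TRUE)
  r2 <- run_simulation(cfg, sample_interval = 3, keep_snapshots = TRUE)
  expect_identical(r1$trajectories[[1]]$counts, r2$trajectories[[1]]$counts)
  expect_identical(r1$trajectories[[2]]$snapshots[["6"]]$cells,
                   r2$trajectories[[2]]$snapshots[["6"]]$cells)
  # replicates differ from each other
  expect_false(identical(r1$trajectories[[1]]$counts$n_cancer,
                         r1$trajectories[[2]]$counts$n_cancer))
})

test_that("replicate SD bands are nonzero for stochastic configs and zero
          when every stochastic rate is degenerate", {
  cfg <- small_cfg(duration = 8, n_replicates = 3L)
  res <- run_simulation(cfg, sample_interval = NULL)
  expect_gt(max(res$summary$sd_relative_change), 0)

  degenerate <- small_cfg(duration = 8, n_replicates = 3L,
                          csc_division_rate = 0, prog_division_rate = 0,
                          base_kill_prob = 0, entry_point_density = 0,
                          senescent_lifespan = Inf)
  res0 <- run_simulation(degenerate, sample_interval = NULL)
  expect_equal(max(res0$summary$sd_relative_change), 0)
})

test_that("state converts to a valid 3-D cell map at voxel centers", {
  cfg <- small_cfg()
  set.seed(6)
  st <- init_state(cfg)
  cm <- state_to_cellmap(st, cfg)
  expect_equal(n_cells(cm), 300)
  expect_equal(cm$dimensionality, 3L)
  # voxel-center coordinates are odd multiples of half the voxel size
  expect_true(all(abs((cm$cells$x / 10) %% 2) == 1))
  expect_true(all(table(cm$cells$cell_type)[c("CANCER_CSC")] == 30))
})
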