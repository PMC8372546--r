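test_that("random packing keeps template geometry and separation guarantees", {
  tm <- water_template()
  one <- random_packed_configuration(list(tm), 1L, box = 8, seed = 4)
  d <- dist(one$positions)
  expect_equal(as.numeric(d), as.numeric(dist(tm$positions)), tolerance = 1e-10)
  expect_identical(one$partition, list(1:3))

  box <- random_packed_configuration(list(tm), 10L, box = 7,
                                     min_dist = 1.7, seed = 11)
  expect_identical(n_atoms(box), 30L)
  ## brute-force check of every cross-molecule minimum-image pair
  mol <- rep(1:10, each = 3L)
  for (i in 1:29) {
    for (j in (i + 1):30) {
      if (mol[i] == mol[j]) next
      dd <- minimum_image_displacement(box, i, j)
      expect_gte(sqrt(sum(dd^2)), 1.7)
    }
  }

  expect_error(random_packed_configuration(list(tm), 2L, box = 3,
                                           min_dist = 3, seed = 1,
                                           max_attempts = 50L), "pack")
  expect_identical(
    random_packed_configuration(list(tm), 3L, box = 7, seed = 5)$positions,
    random_packed_configuration(list(tm), 3L, box = 7, seed = 5)$positions)
})

test_that("the monomer grid enumerates the full Cartesian product", {
  set <- grid_monomer_configurations(grid_spec())
  expect_length(set, 512L)
  r1 <- vapply(unclass(set), function(c) c$info$r_OH1, numeric(1))
  expect_equal(sort(unique(r1)), seq(0.8, 1.5, length.out = 8))
  expect_equal(diff(sort(unique(r1)))[1], 0.1, tolerance = 1e-12)

  ## geometry matches the stored internal coordinates
  cfg <- set[[100]]
  expect_equal(sqrt(sum((cfg$positions[2, ] - cfg$positions[1, ])^2)),
               cfg$info$r_OH1, tolerance = 1e-12)
  expect_equal(sqrt(sum((cfg$positions[3, ] - cfg$positions[1, ])^2)),
               cfg$info$r_OH2, tolerance = 1e-12)
  if (isTRUE(cfg$info$feasible)) {
    expect_equal(sqrt(sum((cfg$positions[3, ] - cfg$positions[2, ])^2)),
                 cfg$info$r_HH, tolerance = 1e-12)
  }

  ## the (0.8, 0.8, 2.5) corner violates the triangle inequality
  corner <- Filter(function(c) {
    isTRUE(all.equal(c(c$info$r_OH1, c$info$r_OH2, c$info$r_HH),
                     c(0.8, 0.8, 2.5)))
  }, unclass(set))
  expect_length(corner, 1L)
  expect_false(corner[[1]]$info$feasible)
  expect_lt(length(feasible_configurations(set)), 512L)
})

test_that("the episode schedule follows n^3 + 2", {
  expect_identical(episode_length(1), 3)
  expect_identical(episode_length(3), 29)
  expect_identical(episode_length(10), 1002)
  expect_error(episode_length(0))
})

test_that("an already-accurate model increments n without new additions", {
  truth <- evb_truth()
  wells <- evb_well_configurations(truth)
  init <- configuration_set(list(wells$reactant))
  out <- run_active_learning(
    truth, init, evb_gap_specs(),
    hyper_params(sigma_E = 3e-4, sigma_F = 0.02, n_sparse = 60L),
    md_params(dt = 0.5, gamma = 0.05),
    al_params(E_add = 0.5, T_AL = 50, max_truth_evals = 50L,
              target_time = 100, seed = 3),
    start = wells$reactant)
  h <- out$history
  expect_true(h$converged)
  expect_identical(sum(h$records$added), 0L)
  ## n walks 1, 2, 3, 4 and stops when episode_length(5) = 127 >= 100
  expect_identical(h$records$n, 1:4)
  expect_equal(h$records$time_fs, h$records$n^3 + 2)
  expect_identical(h$truth_evals_used, length(init) + nrow(h$records))
})

test_that("histories agree on their common prefix under different budgets", {
  truth <- evb_truth()
  ts <- evb_ts_configuration(truth)
  args <- function(budget) {
    list(truth, configuration_set(list(ts)), evb_gap_specs(),
         hyper_params(sigma_E = 3e-4, sigma_F = 0.02, n_sparse = 60L),
         md_params(dt = 0.5, gamma = 0.05),
         al_params(E_add = 0.02, T_AL = 300, max_truth_evals = budget,
                   target_time = 80, seed = 9),
         start = ts)
  }
  short <- do.call(run_active_learning, args(6L))$history
  long <- do.call(run_active_learning, args(12L))$history
  n <- nrow(short$records)
  expect_gt(n, 0L)
  expect_equal(long$records[seq_len(n), ], short$records[seq_len(n), ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("every added configuration carries ground-truth energy and forces", {
  truth <- evb_truth()
  ts <- evb_ts_configuration(truth)
  out <- run_active_learning(
    truth, configuration_set(list(ts)), evb_gap_specs(),
    hyper_params(sigma_E = 3e-4, sigma_F = 0.02, n_sparse = 60L),
    md_params(dt = 0.5, gamma = 0.05),
    al_params(E_add = 0.003, T_AL = 400, max_truth_evals = 12L,
              target_time = 300, seed = 5),
    start = ts)
  h <- out$history
  expect_gt(sum(h$records$added), 0L)
  for (cfg in unclass(h$train_set)) {
    expect_false(is.null(cfg$energy))
    expect_false(is.null(cfg$forces))
    expect_identical(cfg$level_tag, truth$level_tag)
  }
  ## the budget identity for the diff strategy
  expect_identical(h$truth_evals_used, h$n_init + nrow(h$records))
  ## n resets to 1 after every addition
  after_add <- which(h$records$added)
  after_add <- after_add[after_add < nrow(h$records)]
  if (length(after_add)) {
    expect_true(all(h$records$n[after_add + 1L] == 1L))
  }
})

test_that("the gp_var strategy only consults the truth on acceptance", {
  truth <- evb_truth()
  ts <- evb_ts_configuration(truth)
  out <- run_active_learning(
    truth, configuration_set(list(ts)), evb_gap_specs(),
    hyper_params(sigma_E = 3e-4, sigma_F = 0.02, n_sparse = 60L),
    md_params(dt = 0.5, gamma = 0.05),
    al_params(strategy = "gp_var", var_add = 1e-4, T_AL = 400,
              max_truth_evals = 12L, target_time = 300, seed = 5),
    start = ts)
  h <- out$history
  expect_identical(h$strategy, "gp_var")
  expect_identical(h$truth_evals_used, h$n_init + sum(h$records$added))
})

test_that("histories serialise to CSV and data frames", {
  truth <- evb_truth()
  ts <- evb_ts_configuration(truth)
  out <- run_active_learning(
    truth, configuration_set(list(ts)), evb_gap_specs(),
    hyper_params(sigma_E = 3e-4, sigma_F = 0.02, n_sparse = 40L),
    md_params(dt = 0.5, gamma = 0.05),
    al_params(E_add = 0.5, T_AL = 100, max_truth_evals = 5L,
              target_time = 30, seed = 1),
    start = ts)
  path <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(out$history, path)
  back <- read.csv(path)
  expect_identical(nrow(back), nrow(as.data.frame(out$history)))
  expect_named(back, c("episode", "n", "time_fs", "metric", "added",
                       "unstable"))
})
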