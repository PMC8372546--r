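## independent brute-force accumulator used as the tau_acc oracle
brute_tau <- function(times, errors, E_l, E_T, mode = "full") {
  cum <- 0
  for (k in seq_along(times)) {
    eps <- errors[k]
    if (eps > E_l) {
      cum <- cum + if (mode == "full") eps else eps - E_l
    }
    if (cum > E_T) return(list(tau = times[k], censored = FALSE))
  }
  list(tau = times[length(times)], censored = TRUE)
}

test_that("tau_acc matches the brute-force accumulator on random traces", {
  set.seed(42)
  for (k in 1:200) {
    n <- sample(3:40, 1)
    times <- cumsum(runif(n, 1, 20))
    errors <- abs(rnorm(n, sd = runif(1, 0.01, 0.4)))
    E_l <- runif(1, 0.01, 0.2)
    E_T <- E_l * runif(1, 2, 12)
    tr <- error_trace(times, errors)
    for (mode in c("full", "excess")) {
      got <- tau_acc_from_trace(tr, E_l, E_T, mode = mode)
      want <- brute_tau(times, errors, E_l, E_T, mode)
      expect_identical(got$tau_acc, want$tau)
      expect_identical(got$censored, want$censored)
    }
  }
})

test_that("tau_acc is monotone non-decreasing in both thresholds", {
  set.seed(7)
  for (k in 1:100) {
    n <- sample(5:50, 1)
    times <- cumsum(runif(n, 1, 15))
    errors <- abs(rnorm(n, sd = 0.2))
    tr <- error_trace(times, errors)
    t1 <- tau_acc_from_trace(tr, 0.05, 0.4)$tau_acc
    t2 <- tau_acc_from_trace(tr, 0.05, 0.8)$tau_acc
    expect_gte(t2, t1)
    t3 <- tau_acc_from_trace(tr, 0.1, 0.4)$tau_acc
    expect_gte(t3, t1)
  }
})

test_that("tau_acc reproduces hand-computed example traces", {
  tr <- error_trace(c(10, 20), c(0.5, 0.6))
  out <- tau_acc_from_trace(tr, E_l = 0.1, E_T = 1.0)
  expect_identical(out$tau_acc, 20)        # 0.5, then 1.1 > 1.0
  expect_false(out$censored)

  one <- tau_acc_from_trace(error_trace(10, 1.2), E_l = 0.1, E_T = 1.0)
  expect_identical(one$tau_acc, 10)        # one-frame catastrophe fires
  expect_false(one$censored)

  quiet <- tau_acc_from_trace(error_trace(c(5, 10, 15), c(0.01, 0.05, 0.1)),
                              E_l = 0.1, E_T = 1.0)
  expect_true(quiet$censored)
  expect_identical(quiet$tau_acc, 15)

  expect_error(error_trace(numeric(0), numeric(0)), "empty")
  expect_error(tau_acc_from_trace(tr, E_l = 0.5, E_T = 0.4))
})

test_that("the default upper threshold is ten times the lower", {
  expect_identical(default_upper_threshold(0.1), 1)
  x <- 0.8 * 0.0434
  expect_equal(default_upper_threshold(x), 10 * x)
  expect_error(default_upper_threshold(0))
})

test_that("a model observing itself is always censored", {
  pot <- harmonic_bond_potential()
  self_truth <- ground_truth(function(cfg) pot(cfg), "self")
  cfg <- configuration(c("O", "H"), rbind(c(0, 0, 0), c(1.0, 0, 0)),
                       velocities = matrix(0, 2, 3))
  res <- evaluate_tau_acc(pot, self_truth, cfg,
                          md_params(T = 0, dt = 0.5, gamma = 0, seed = 1),
                          interval = 10, E_l = 0.01, E_T = 0.1, t_max = 200)
  expect_true(res$censored)
  expect_identical(res$tau_acc, 200)
  expect_equal(max(res$trace$errors), 0)
})

test_that("a constant offset of 2 E_l fires on the sixth evaluation", {
  pot <- harmonic_bond_potential()
  E_l <- 0.05
  offset_pot <- function(cfg) {
    out <- pot(cfg)
    out$energy <- out$energy + 2 * E_l
    out
  }
  truth <- ground_truth(function(cfg) pot(cfg), "base")
  cfg <- configuration(c("O", "H"), rbind(c(0, 0, 0), c(1.0, 0, 0)),
                       velocities = matrix(0, 2, 3))
  res <- evaluate_tau_acc(offset_pot, truth, cfg,
                          md_params(T = 0, dt = 0.5, gamma = 0, seed = 1),
                          interval = 10, E_l = E_l,
                          E_T = default_upper_threshold(E_l), t_max = 500)
  ## cumulative error 2 E_l k exceeds 10 E_l strictly at k = 6
  expect_identical(res$tau_acc, 60)
  expect_false(res$censored)
})

test_that("the interval must divide the MD timestep grid", {
  pot <- harmonic_bond_potential()
  truth <- ground_truth(function(cfg) pot(cfg), "base")
  cfg <- configuration(c("O", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(evaluate_tau_acc(pot, truth, cfg,
                                md_params(dt = 0.5, seed = 1),
                                interval = 10.3, E_l = 0.1, t_max = 100),
               "integer multiple")
})

test_that("the RDF of an ideal gas is flat and integrates to the right count", {
  set.seed(15)
  L <- 12
  frames <- lapply(1:200, function(k) {
    configuration(rep("O", 100), matrix(runif(300, 0, L), 100, 3),
                  cell = diag(L, 3), pbc = TRUE)
  })
  traj <- trajectory(frames, seq_along(frames))
  g <- rdf(traj, c("O", "O"), r_max = 5, bin_width = 0.1)
  sel <- g$r >= 2 & g$r <= 5
  expect_lt(max(abs(g$g[sel] - 1)), 0.05)
  ## coordination integral: 4 pi rho int g r^2 dr within 2% of ideal
  rho <- 100 / L^3
  n_coord <- 4 * pi * rho * sum(g$g * g$r^2 * 0.1)
  n_ideal <- 4 / 3 * pi * 5^3 * rho
  expect_lt(abs(n_coord - n_ideal) / n_ideal, 0.02)
})

test_that("a frozen pair contributes a single occupied bin", {
  cfg <- configuration(c("O", "O"), rbind(c(1, 1, 1), c(1, 1, 4.52)),
                       cell = diag(10, 3), pbc = TRUE)
  traj <- trajectory(list(cfg), 0)
  g <- rdf(traj, c("O", "O"), r_max = 4.5, bin_width = 0.05)
  occupied <- which(g$g > 0)
  expect_length(occupied, 1L)
  expect_equal(g$r[occupied], 3.525, tolerance = 0.05)
  expect_true(all(g$g[g$r < 3.4] == 0))
  expect_error(rdf(traj, c("O", "O"), r_max = 6), "half")
})

test_that("parity statistics match their definitions", {
  p <- parity_stats(c(1, 2, 3), c(1, 2, 3))
  expect_identical(p$rmse, 0)
  expect_identical(p$n_within_band, 3L)

  off <- parity_stats(c(1.2, 2.2), c(1, 2))
  expect_equal(off$rmse, 0.2, tolerance = 1e-12)
  expect_equal(off$max_abs, 0.2, tolerance = 1e-12)

  set.seed(3)
  a <- rnorm(50); b <- rnorm(50)
  p2 <- parity_stats(a, b)
  expect_equal(p2$rmse, sqrt(mean((a - b)^2)))
  expect_equal(p2$n_within_band, sum(abs(a - b) <= 0.0434))
  expect_error(parity_stats(1:3, 1:2))
})

test_that("learning curves aggregate repeats with standard errors", {
  rep1 <- data.frame(budget = c(10, 20), tau_acc = c(2000, 4000))
  rep2 <- data.frame(budget = c(10, 20), tau_acc = c(2000, 4000))
  lc <- learning_curve(list(rep1, rep2))
  expect_equal(lc$sem_tau, c(0, 0))

  rep3 <- data.frame(budget = c(10, 20), tau_acc = c(2000, 2000))
  lc2 <- learning_curve(list(rep1, rep3))
  expect_equal(lc2$mean_tau[2], 3000)
  expect_equal(lc2$sem_tau[2], 1000)

  tiny <- data.frame(budget = c(10, 20), tau_acc = c(0, 500))
  lc3 <- learning_curve(list(tiny, tiny))
  expect_equal(lc3$tau_floored[1], 0.1)    # reporting floor only
  expect_equal(lc3$mean_tau[1], 0)         # raw value retained

  bad <- data.frame(budget = c(10, 30), tau_acc = c(1, 2))
  expect_error(learning_curve(list(rep1, bad)), "budget")
  expect_error(learning_curve(list(rep1)), "length")
})

test_that("trace CSV and summary writers round-trip", {
  tr <- error_trace(c(10, 20, 30), c(0.02, 0.2, 0.01))
  res <- tau_acc_from_trace(tr, 0.1, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(res, path)
  back <- read.csv(path)
  expect_equal(back$time_fs, tr$times)
  expect_equal(back$error_eV, tr$errors)
  s <- tau_acc_summary(res, "m")
  expect_identical(nrow(s), 1L)
  expect_true(s$censored)
})
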