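## EVB-based fixtures give fast 3-atom models for most GP contract checks.

evb_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- evb_truth()
      set.seed(21)
      configs <- lapply(1:25, function(k) {
        rab <- runif(1, 1.7, 3.2); rbc <- runif(1, 1.7, 3.2)
        bend <- runif(1, -0.25, 0.25)
        gt_label(truth, configuration(
          c("Cl", "C", "Cl"),
          rbind(c(0, 0, 0), c(rab, 0, 0), c(rab + rbc * cos(bend),
                                            rbc * sin(bend), 0))))
      })
      model <- gp_fit(configuration_set(configs), evb_gap_specs(),
                      hyper_params(sigma_E = 3e-4, sigma_F = 0.02,
                                   n_sparse = 100L), seed = 2)
      cache <<- list(truth = truth, train = configuration_set(configs),
                     model = model)
    }
    cache
  }
})

test_that("a one-configuration fit reproduces its energy within the noise", {
  truth <- evb_truth()
  cfg <- gt_label(truth, configuration(c("Cl", "C", "Cl"),
                                       rbind(c(0, 0, 0), c(2, 0, 0), c(4.4, 0, 0))))
  hy <- hyper_params(sigma_E = 1e-4, sigma_F = 0.05, n_sparse = 50L)
  m <- gp_fit(configuration_set(list(cfg)), evb_gap_specs(), hy, seed = 1)
  expect_lt(abs(predict_energy(m, cfg) - cfg$energy), 10 * hy$sigma_E * 3)
})

test_that("the fitted model reproduces training labels within the fit tolerance", {
  fx <- evb_fixture()
  errs <- vapply(unclass(fx$train), function(c) {
    predict_energy(fx$model, c) - c$energy
  }, numeric(1))
  expect_lt(max(abs(errs)), 10 * fx$model$hyper$sigma_E * 3)
})

test_that("training sets identical up to like-atom permutation give identical predictions", {
  truth <- evb_truth()
  base <- lapply(c(2.0, 2.3, 2.8), function(rab) {
    gt_label(truth, configuration(c("Cl", "C", "Cl"),
                                  rbind(c(0, 0, 0), c(rab, 0, 0), c(rab + 2.4, 0, 0))))
  })
  swapped <- lapply(base, function(cfg) {
    cfg$positions <- cfg$positions[c(3, 2, 1), ]
    cfg$forces <- cfg$forces[c(3, 2, 1), ]
    cfg
  })
  hy <- hyper_params(sigma_E = 1e-3, sigma_F = 0.1, n_sparse = 30L)
  m1 <- gp_fit(configuration_set(base), evb_gap_specs(), hy, seed = 7)
  m2 <- gp_fit(configuration_set(swapped), evb_gap_specs(), hy, seed = 7)
  probe <- configuration(c("Cl", "C", "Cl"),
                         rbind(c(0, 0, 0), c(2.1, 0, 0), c(4.4, 0.2, 0)))
  expect_equal(predict_energy(m1, probe), predict_energy(m2, probe),
               tolerance = 1e-8)
})

test_that("predicted energies respect mirror symmetry and smoothness", {
  fx <- evb_fixture()
  probe <- configuration(c("Cl", "C", "Cl"),
                         rbind(c(0, 0, 0), c(2.1, 0, 0), c(4.6, 0.3, 0)))
  mirror <- probe
  mirror$positions <- probe$positions %*% diag(c(-1, 1, 1))
  expect_equal(predict_energy(fx$model, probe),
               predict_energy(fx$model, mirror), tolerance = 1e-8)

  shifted <- probe
  shifted$positions[2, 1] <- shifted$positions[2, 1] + 1e-6
  expect_lt(abs(predict_energy(fx$model, shifted) -
                predict_energy(fx$model, probe)), 1e-3)
})

test_that("predicted forces are finite-difference consistent with the energy", {
  fx <- evb_fixture()
  set.seed(5)
  for (k in 1:5) {
    probe <- configuration(c("Cl", "C", "Cl"),
                           rbind(c(0, 0, 0),
                                 c(runif(1, 1.9, 2.6), runif(1, -0.2, 0.2), 0),
                                 c(runif(1, 3.8, 5.0), runif(1, -0.4, 0.4), 0)))
    pf <- predict_forces(fx$model, probe)
    fd <- finite_difference_forces(fx$model, probe, h = 1e-4)
    expect_lt(max(abs(pf - fd)), 1e-3)
  }
})

test_that("a single isolated atom feels no force", {
  fx <- evb_fixture()
  lone <- configuration("Cl", matrix(0, 1, 3))
  expect_equal(predict_forces(fx$model, lone), matrix(0, 1, 3),
               tolerance = 1e-12)
})

test_that("sparse predictions agree with a brute-force dense GP on small sets", {
  ## independent oracle: dense weight-space solve of the same 2-body kernel
  ## built directly in R
  rc <- 3.4; theta <- 0.3
  fcut <- function(r) ifelse(r < rc, 0.5 * (cos(pi * r / rc) + 1), 0)
  phi <- function(r) 2 / r          # arbitrary smooth pair target
  rs <- seq(1.9, 3.1, length.out = 15)
  configs <- lapply(rs, function(r) {
    configuration(c("O", "O"), rbind(c(0, 0, 0), c(r, 0, 0)),
                  partition = list(1L, 2L), energy = phi(r),
                  level_tag = "dense-check")
  })
  sp <- descriptor_spec("two_body", "O", r_c = rc, sigma_atom = theta,
                        delta = 1, neighbor_species = "O",
                        intermolecular = TRUE)
  sigma_E <- 1e-5
  m <- gp_fit(configuration_set(configs), list(sp),
              hyper_params(sigma_E = sigma_E, sigma_F = 0.1,
                           n_sparse = 1000L, jitter = 1e-10,
                           e0_mode = "zero"), seed = 1)

  ## dense GP: inducing set = all data sites; per-config kernel row
  ## k(config_i, site_j) = 2 fc(r_i) fc(r_j) exp(-(r_i-r_j)^2/(2 theta^2))
  K <- outer(rs, rs, function(a, b) {
    2 * fcut(a) * fcut(b) * exp(-(a - b)^2 / (2 * theta^2))
  })
  Kmm <- K / 2                       # site-site gram (one pair per site)
  noise <- diag((sigma_E * 2)^2, length(rs))
  alpha <- solve(K %*% solve(Kmm + diag(1e-10, length(rs))) %*% t(K) + noise +
                   diag(1e-12, length(rs)), phi(rs))
  dense_pred <- function(r) {
    kx <- 2 * fcut(r) * fcut(rs) * exp(-(r - rs)^2 / (2 * theta^2))
    drop(kx %*% solve(Kmm + diag(1e-10, length(rs))) %*% t(K) %*% alpha)
  }
  for (r in c(2.0, 2.45, 2.9)) {
    probe <- configuration(c("O", "O"), rbind(c(0, 0, 0), c(r, 0, 0)),
                           partition = list(1L, 2L))
    expect_equal(predict_energy(m, probe), dense_pred(r), tolerance = 2e-3)
    expect_equal(predict_energy(m, probe), phi(r), tolerance = 2e-3)
  }
})

test_that("training residuals do not increase as the energy noise shrinks", {
  fx <- evb_fixture()
  rmse <- vapply(c(1e-2, 1e-3, 1e-4), function(se) {
    m <- gp_fit(fx$train, evb_gap_specs(),
                hyper_params(sigma_E = se, sigma_F = 0.05, n_sparse = 100L),
                seed = 2)
    errs <- vapply(unclass(fx$train), function(c) {
      predict_energy(m, c) - c$energy
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 1e-9))
})

test_that("per-atom variance vanishes at sparse environments and grows far away", {
  fx <- evb_fixture()
  m <- fx$model
  near <- fx$train[[3]]
  v_near <- max(predict_atom_variance(m, near))
  far <- configuration(c("Cl", "C", "Cl"),
                       rbind(c(0, 0, 0), c(1.05, 0, 0), c(2.1, 0, 0)))
  v_far <- max(predict_atom_variance(m, far))
  expect_true(all(predict_atom_variance(m, near) >= 0))
  expect_lt(v_near, v_far)

  ## far outside every sparse environment the SOAP variance approaches the
  ## prior delta^2 k(x,x)
  soap_delta <- m$specs[[3]]$delta
  lone <- configuration(c("C", "Cl", "Cl"),
                        rbind(c(0, 0, 0), c(30, 0, 0), c(60, 0, 0)))
  v_lone <- predict_atom_variance(m, lone)[1L]
  expect_lt(abs(v_lone - soap_delta^2) / soap_delta^2, 0.5)

  ## ordering holds across random near/far pairs
  set.seed(31)
  for (k in 1:10) {
    tr <- fx$train[[sample(length(fx$train), 1)]]
    vn <- max(predict_atom_variance(m, tr))
    fr <- configuration(c("Cl", "C", "Cl"),
                        rbind(c(0, 0, 0), c(runif(1, 0.8, 1.2), 0, 0),
                              c(runif(1, 1.6, 2.2), 0.8, 0)))
    expect_lt(vn, max(predict_atom_variance(m, fr)))
  }
})

test_that("uplift with the original truth is idempotent", {
  fx <- evb_fixture()
  up <- uplift(fx$model, fx$truth)
  probe <- configuration(c("Cl", "C", "Cl"),
                         rbind(c(0, 0, 0), c(2.2, 0, 0), c(4.5, 0, 0)))
  expect_equal(predict_energy(up, probe), predict_energy(fx$model, probe),
               tolerance = 1e-10)
  expect_identical(up$level_tag, fx$model$level_tag)
})

test_that("uplift to a shifted truth moves energies by the shift and keeps forces", {
  fx <- evb_fixture()
  shift <- 0.7
  shifted <- ground_truth(function(cfg) {
    out <- gt_evaluate(fx$truth, cfg)
    out$energy <- out$energy + shift
    out
  }, level_tag = "evb-shifted")
  up <- uplift(fx$model, shifted)
  expect_identical(up$level_tag, "evb-shifted")
  probe <- configuration(c("Cl", "C", "Cl"),
                         rbind(c(0, 0, 0), c(2.2, 0, 0), c(4.5, 0, 0)))
  expect_equal(predict_energy(up, probe) - predict_energy(fx$model, probe),
               shift, tolerance = 5e-3)
  expect_lt(max(abs(predict_forces(up, probe) -
                    predict_forces(fx$model, probe))), 1e-6)
})

test_that("uplift to a deepened surface deepens the fitted minimum", {
  fx <- evb_fixture()
  deeper_truth <- evb_truth(evb_params(De1 = 2.6, De2 = 2.6),
                            level_tag = "evb-deep")
  up <- uplift(fx$model, deeper_truth)
  well <- configuration(c("Cl", "C", "Cl"),
                        rbind(c(0, 0, 0), c(2.0, 0, 0), c(4.8, 0, 0)))
  drop_model <- predict_energy(up, well) - predict_energy(fx$model, well)
  drop_truth <- gt_evaluate(deeper_truth, well)$energy -
    gt_evaluate(fx$truth, well)$energy
  expect_equal(drop_model, drop_truth, tolerance = 0.05)
})

test_that("uplift aborts on evaluator failure without a partial model", {
  fx <- evb_fixture()
  broken <- ground_truth(function(cfg) stop("backend down"), "broken")
  expect_error(uplift(fx$model, broken), "backend down")
})

test_that("model archives round-trip and reject schema mismatches", {
  fx <- evb_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fx$model, path)
  back <- load_model(path)
  probe <- configuration(c("Cl", "C", "Cl"),
                         rbind(c(0, 0, 0), c(2.15, 0, 0), c(4.4, 0.1, 0)))
  expect_equal(predict_energy(back, probe), predict_energy(fx$model, probe),
               tolerance = 1e-8)
  expect_equal(predict_forces(back, probe), predict_forces(fx$model, probe),
               tolerance = 1e-8)

  obj <- jsonlite::read_json(path)
  obj$schema_version <- 99L
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, auto_unbox = TRUE)
  expect_error(load_model(bad), "schema")
})

test_that("the monomer-grid intra model generalises to held-out grid points", {
  truth <- toy_water_truth(test_water_params())
  grid <- feasible_configurations(grid_monomer_configurations())
  lab <- configuration_set(lapply(unclass(grid), function(c) gt_label(truth, c)))
  set.seed(11)
  hold <- sample(length(lab), round(0.1 * length(lab)))
  m <- gp_fit(lab[-hold], water_intra_specs(),
              hyper_params(n_sparse = 10000L, sigma_E = 1e-5, sigma_F = 0.02),
              seed = 1)
  errs <- vapply(unclass(lab[hold]), function(c) {
    predict_energy(m, c) - c$energy
  }, numeric(1))
  ## measured recovery is ~1.2 meV RMSE on this grid; the bound leaves room
  ## for numerical variation while staying far below the 0.2 kcal/mol
  ## per-molecule yardstick for usable bulk models
  expect_lt(sqrt(mean(errs^2)), 2e-3)
  expect_lt(max(abs(errs)), 8e-3)
})
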