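test_that("Maxwell-Boltzmann initialisation has the right moments and zero momentum", {
  big <- configuration(rep(c("O", "H"), 500), matrix(runif(3000, 0, 50), 1000, 3))
  cold <- maxwell_boltzmann_velocities(big, T = 0, seed = 1)
  expect_equal(max(abs(cold$velocities)), 0)

  hot <- maxwell_boltzmann_velocities(big, T = 300, seed = 2)
  m <- atomic_masses(hot$species)
  p_tot <- colSums(hot$velocities * m)
  expect_lt(max(abs(p_tot)), 1e-12 * sum(m))
  ke <- kinetic_energy(hot)
  kb <- 8.617333262e-5
  expect_lt(abs(ke - (3 * 1000 - 3) / 2 * kb * 300) / ke, 0.05)

  expect_identical(maxwell_boltzmann_velocities(big, 300, seed = 2)$velocities,
                   hot$velocities)
})

test_that("bond-energy injection deposits exactly the requested relative energy", {
  cfg <- configuration(c("Cl", "C"), rbind(c(0, 0, 0), c(1.8, 0, 0)),
                       velocities = matrix(0, 2, 3))
  same <- inject_bond_energy(cfg, 1, 2, 0)
  expect_identical(same$velocities, cfg$velocities)

  kicked <- inject_bond_energy(cfg, 1, 2, 0.5)
  expect_equal(kinetic_energy(kicked), 0.5, tolerance = 1e-12)
  m <- atomic_masses(kicked$species)
  expect_lt(max(abs(colSums(kicked$velocities * m))), 1e-12)

  eq <- configuration(c("O", "O"), rbind(c(0, 0, 0), c(2, 0, 0)),
                      velocities = matrix(0, 2, 3))
  E <- 0.2
  out <- inject_bond_energy(eq, 1, 2, E)
  mO <- atomic_masses("O")
  v_expect <- sqrt(E / mO / 103.642696562)
  expect_equal(abs(out$velocities[1, 1]), v_expect, tolerance = 1e-12)
  expect_equal(out$velocities[1, 1], -out$velocities[2, 1], tolerance = 1e-12)

  expect_error(inject_bond_energy(cfg, 1, 1, 0.1))
  expect_error(inject_bond_energy(
    configuration(c("O", "O"), matrix(0, 2, 3)), 1, 2, 0.1), "coincident")
})

test_that("NVE dynamics reproduces the harmonic bond period within 1%", {
  k_b <- 25; mO <- atomic_masses("O"); mH <- atomic_masses("H")
  pot <- harmonic_bond_potential(k = k_b, r0 = 0.96)
  cfg <- configuration(c("O", "H"), rbind(c(0, 0, 0), c(1.06, 0, 0)),
                       velocities = matrix(0, 2, 3))
  traj <- run_md(pot, cfg, md_params(T = 0, dt = 0.5, gamma = 0,
                                     n_steps = 2000L, stride = 1L, seed = 1))
  r <- vapply(unclass(traj$frames), function(f) {
    sqrt(sum((f$positions[2, ] - f$positions[1, ])^2))
  }, numeric(1))
  ## period from mean spacing of maxima of the bond-length signal
  peaks <- which(diff(sign(diff(r))) == -2) + 1L
  period_md <- mean(diff(traj$times[peaks]))
  mu <- mO * mH / (mO + mH)
  period_exact <- 2 * pi * sqrt(mu / (k_b / 103.642696562))
  expect_lt(abs(period_md - period_exact) / period_exact, 0.01)
})

test_that("a resting system at a stationary point never moves", {
  pot <- harmonic_bond_potential(k = 10, r0 = 1.0)
  cfg <- configuration(c("O", "H"), rbind(c(0, 0, 0), c(1.0, 0, 0)),
                       velocities = matrix(0, 2, 3))
  traj <- run_md(pot, cfg, md_params(T = 0, dt = 0.5, gamma = 0,
                                     n_steps = 100L, stride = 10L, seed = 1))
  final <- traj$frames[[length(traj$frames)]]
  expect_equal(final$positions, cfg$positions, tolerance = 1e-12)
})

test_that("trajectory times follow k * stride * dt and frames carry velocities", {
  pot <- harmonic_bond_potential()
  cfg <- configuration(c("O", "H"), rbind(c(0, 0, 0), c(1.02, 0, 0)),
                       velocities = matrix(0, 2, 3))
  traj <- run_md(pot, cfg, md_params(T = 0, dt = 0.5, gamma = 0,
                                     n_steps = 40L, stride = 8L, seed = 1))
  expect_equal(traj$times, c(0, 8, 16, 24, 32, 40) * 0.5)
  expect_false(is.null(traj$frames[[2]]$velocities))
})

test_that("short NVE runs of the water dimer conserve energy", {
  truth <- toy_water_truth()
  dm <- water_dimer()
  dm <- maxwell_boltzmann_velocities(dm, 200, seed = 3)
  traj <- run_md(truth, dm, md_params(T = 0, dt = 0.5, gamma = 0,
                                      n_steps = 2000L, stride = 100L, seed = 1))
  etot <- vapply(unclass(traj$frames), function(f) {
    f$energy + kinetic_energy(f)
  }, numeric(1))
  expect_lt(max(etot) - min(etot), 1e-3)
  expect_false(traj$unstable)
})

test_that("unstable dynamics aborts with a flagged partial trajectory", {
  blowup <- function(cfg) {
    d <- cfg$positions[2, 1] - cfg$positions[1, 1]
    if (abs(d) > 1.05) {
      list(energy = NaN, forces = matrix(NaN, 2, 3))
    } else {
      list(energy = 0, forces = rbind(c(50, 0, 0), c(-50, 0, 0)))
    }
  }
  cfg <- configuration(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)),
                       velocities = matrix(0, 2, 3))
  traj <- run_md(blowup, cfg, md_params(T = 0, dt = 0.5, gamma = 0,
                                        n_steps = 500L, stride = 1L, seed = 1))
  expect_true(traj$unstable)
  expect_lt(length(traj$frames), 501L)
})

test_that("minimisation reaches the analytic water minimum and never climbs", {
  p <- toy_water_params()
  truth <- toy_water_truth(p)
  distorted <- water_template(1.15, 2.2)
  e_start <- gt_evaluate(truth, distorted)$energy
  out <- minimise(truth, distorted, f_max = 1e-4)
  expect_lt(out$energy, e_start)
  expect_lt(out$energy, 1e-6)
  d1 <- sqrt(sum((out$positions[2, ] - out$positions[1, ])^2))
  d2 <- sqrt(sum((out$positions[3, ] - out$positions[1, ])^2))
  u <- (out$positions[2, ] - out$positions[1, ])
  v <- (out$positions[3, ] - out$positions[1, ])
  ang <- acos(sum(u * v) / (d1 * d2))
  expect_equal(d1, p$r0, tolerance = 1e-3)
  expect_equal(d2, p$r0, tolerance = 1e-3)
  expect_equal(ang, p$theta0, tolerance = 1e-3)

  again <- minimise(truth, out, f_max = 1e-4)
  expect_equal(again$positions, out$positions, tolerance = 1e-9)

  cond <- tryCatch(minimise(truth, distorted, f_max = 1e-12, max_steps = 3L),
                   error = function(e) e)
  expect_s3_class(cond, "error")
  expect_false(is.null(cond$best))
})

test_that("NEB handles flat potentials and degenerate endpoints exactly", {
  flat <- function(cfg) list(energy = sum(cfg$positions[, 1]) * 0.3,
                             forces = matrix(rep(c(-0.3, 0, 0), each = n_atoms(cfg)),
                                             n_atoms(cfg), 3))
  a <- configuration(c("O", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  b <- configuration(c("O", "H"), rbind(c(2, 0, 0), c(3, 0, 0)))
  path <- neb_relax(flat, a, b, n_images = 5, f_max = 0.05)
  expect_true(path$converged)
  ## interior images stay on the straight interpolation line
  for (k in 2:4) {
    lam <- (k - 1) / 4
    expect_equal(path$images[[k]]$positions,
                 (1 - lam) * a$positions + lam * b$positions,
                 tolerance = 1e-9)
  }
  expect_identical(path$images[[1]]$positions, a$positions)
  expect_identical(path$images[[5]]$positions, b$positions)

  same <- neb_relax(flat, a, a, n_images = 5, f_max = 0.05)
  expect_true(same$converged)
  expect_equal(same$images[[3]]$positions, a$positions, tolerance = 1e-12)
})

test_that("NEB on the EVB surface finds the symmetric barrier", {
  truth <- evb_truth()
  wells <- evb_well_configurations(truth)
  ## the straight-line interpolation of an identity exchange lies on a
  ## symmetry ridge; a small seeded perturbation lets the band fall into
  ## the reaction valley
  path <- neb_relax(truth, wells$reactant, wells$product, n_images = 13,
                    k_spring = 5, f_max = 0.02, init_noise = 0.05, seed = 2)
  expect_true(path$converged)
  barrier_neb <- max(path$energies) - path$energies[1L]
  ts <- evb_ts_configuration(truth)
  barrier_exact <- gt_evaluate(truth, ts)$energy - wells$reactant$energy
  expect_equal(barrier_neb, barrier_exact, tolerance = 0.05)
  expect_identical(path$images[[1]]$positions, wells$reactant$positions)
})
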