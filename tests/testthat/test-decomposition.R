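test_that("connectivity partitioning finds molecules and honours the solute override", {
  dm <- water_dimer(sep = 3.0)
  dm$partition <- NULL
  expect_identical(infer_molecules(dm), list(1:3, 4:6))
  expect_identical(infer_molecules(water_template()), list(1:3))

  ## metal-centre cluster: Zn + 6 coordinated waters declared as one solute,
  ## 4 distant waters as separate molecules (hand-checked connectivity)
  set.seed(3)
  tm <- water_template()
  zn_pos <- matrix(0, 1, 3)
  near <- do.call(rbind, lapply(1:6, function(k) {
    dir <- rbind(diag(3), -diag(3))[k, ]
    sweep(tm$positions, 2L, dir * 2.1, "+")
  }))
  far <- do.call(rbind, lapply(1:4, function(k) {
    sweep(tm$positions, 2L, c(8 + 3 * k, 0, 0), "+")
  }))
  cfg <- configuration(c("Zn", rep(tm$species, 10)), rbind(zn_pos, near, far))
  part <- infer_molecules(cfg, solute_atoms = 1:19)
  expect_identical(part[[1L]], 1:19)
  expect_identical(lengths(part), c(19L, 3L, 3L, 3L, 3L))
})

test_that("expand_for_intra scales the box but keeps molecules rigid", {
  p <- test_water_params()
  cfg <- thermal_water_box(n_waters = 2L, seed = 9L, params = p)
  ex <- expand_for_intra(cfg, cfg$partition, factor = 10)
  expect_equal(ex$cell, cfg$cell * 10)
  for (grp in cfg$partition) {
    for (i in grp) for (j in grp) {
      if (i < j) {
        d0 <- sqrt(sum((cfg$positions[i, ] - cfg$positions[j, ])^2))
        d1 <- sqrt(sum((ex$positions[i, ] - ex$positions[j, ])^2))
        expect_equal(d1, d0, tolerance = 1e-12)
      }
    }
  }
  ## cross-molecule separation grows roughly tenfold
  cross0 <- min(sapply(cfg$partition[[1]], function(i) {
    sapply(cfg$partition[[2]], function(j) {
      sqrt(sum(minimum_image_displacement(cfg, i, j)^2))
    })
  }))
  cross1 <- min(sapply(cfg$partition[[1]], function(i) {
    sapply(cfg$partition[[2]], function(j) {
      sqrt(sum(minimum_image_displacement(ex, i, j)^2))
    })
  }))
  expect_gt(cross1, 5 * cross0)
  expect_gt(cross1, 6)  # far beyond any intra cutoff used here

  expect_error(expand_for_intra(cfg, cfg$partition, factor = 1), "> 1")
  gas <- water_template()
  expect_error(expand_for_intra(gas, list(1:3), 10), "periodic")
})

intra_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- toy_water_truth(test_water_params())
      gs <- grid_spec(n_per_dim = 6L)
      cache <<- fit_water_intra(truth, gs)
    }
    cache
  }
})

test_that("intra evaluation equals the sum over isolated molecules", {
  m_intra <- intra_fixture()
  comp <- composite_potential(list(H2O1 = m_intra), inter_model = NULL)
  cfg <- thermal_water_box(n_waters = 3L, seed = 13L)
  total <- intra_evaluate(comp, cfg, forces = TRUE)
  by_mol <- lapply(cfg$partition, function(grp) {
    mol <- configuration(cfg$species[grp], cfg$positions[grp, ])
    gp_eval(m_intra, mol, forces = TRUE)
  })
  expect_equal(total$energy, sum(vapply(by_mol, function(x) x$energy, 0)),
               tolerance = 1e-9)
  for (g in seq_along(cfg$partition)) {
    expect_equal(total$forces[cfg$partition[[g]], ], by_mol[[g]]$forces,
                 tolerance = 1e-9)
  }

  ## single gas-phase molecule: identity with the direct model prediction
  mono <- water_template(1.0, 1.8)
  expect_equal(intra_evaluate(comp, mono, forces = FALSE)$energy,
               predict_energy(m_intra, mono), tolerance = 1e-12)

  ## permuting molecule order permutes forces consistently
  perm <- cfg
  ord <- c(4:6, 1:3, 7:9)
  perm$positions <- cfg$positions[ord, ]
  perm$species <- cfg$species[ord]
  perm$partition <- list(1:3, 4:6, 7:9)
  total_p <- intra_evaluate(comp, perm, forces = TRUE)
  expect_equal(total_p$energy, total$energy, tolerance = 1e-9)
  expect_equal(total_p$forces, total$forces[ord, ], tolerance = 1e-9)
})

test_that("intra evaluation requires a model for every molecule type", {
  m_intra <- intra_fixture()
  comp <- composite_potential(list(H2O1 = m_intra), inter_model = NULL)
  odd <- configuration(c("O", "H", "H", "Cl"),
                       rbind(water_template()$positions, c(6, 0, 0)))
  expect_error(intra_evaluate(comp, odd), "no intramolecular model")
})

test_that("inter labels are the exact bookkeeping complement of the intra part", {
  m_intra <- intra_fixture()
  p <- test_water_params()
  truth <- toy_water_truth(p)
  comp <- composite_potential(list(H2O1 = m_intra), inter_model = NULL)
  cfg <- gt_label(truth, thermal_water_box(n_waters = 3L, seed = 17L, params = p))
  lab <- make_inter_labels(cfg, comp)
  expect_match(lab$level_tag, "-inter$")
  intra <- intra_evaluate(comp, cfg, forces = TRUE)
  expect_equal(lab$energy + intra$energy, cfg$energy, tolerance = 1e-12)
  expect_equal(lab$forces + intra$forces, cfg$forces, tolerance = 1e-12)

  ## the label tracks the analytic intermolecular part within fit tolerance
  expect_lt(abs(lab$energy - toy_water_evaluate(cfg, p)$e_inter), 0.05)

  ## an isolated molecule has (near) zero inter label
  mono <- gt_label(truth, water_template(0.98, 1.85))
  lab1 <- make_inter_labels(mono, comp)
  expect_lt(abs(lab1$energy), 5e-3)
  expect_lt(max(abs(lab1$forces)), 0.05)

  expect_error(make_inter_labels(water_template(), comp), "energy and forces")
})

test_that("the composite is exactly additive and linear in the inter weights", {
  m_intra <- intra_fixture()
  p <- test_water_params()
  truth <- toy_water_truth(p)
  comp0 <- composite_potential(list(H2O1 = m_intra), inter_model = NULL)
  frames <- lapply(c(19L, 23L), function(s) {
    gt_label(truth, thermal_water_box(n_waters = 3L, seed = s, params = p))
  })
  train <- configuration_set(lapply(frames, make_inter_labels, comp = comp0))
  m_inter <- gp_fit(train, water_inter_specs(),
                    hyper_params(sigma_E = 1e-4, sigma_F = 0.1,
                                 n_sparse = 80L, e0_mode = "zero"), seed = 1)
  comp <- composite_potential(list(H2O1 = m_intra), m_inter)
  cfg <- frames[[1L]]
  out <- composite_evaluate(comp, cfg, forces = TRUE)
  intra <- intra_evaluate(comp, cfg, forces = TRUE)
  inter <- gp_eval(m_inter, cfg, forces = TRUE)
  expect_equal(out$energy, intra$energy + inter$energy, tolerance = 1e-12)
  expect_equal(out$forces, intra$forces + inter$forces, tolerance = 1e-12)

  zeroed <- comp
  zeroed$inter_model$weights[] <- 0
  out0 <- composite_evaluate(zeroed, cfg, forces = FALSE)
  expect_equal(out0$energy, intra$energy, tolerance = 1e-12)

  scaled <- comp
  scaled$inter_model$weights <- 0.5 * comp$inter_model$weights
  outs <- composite_evaluate(scaled, cfg, forces = FALSE)
  expect_equal(outs$energy - intra$energy, 0.5 * (out$energy - intra$energy),
               tolerance = 1e-10)
})

test_that("composite archives bundle and restore both components", {
  m_intra <- intra_fixture()
  p <- test_water_params()
  truth <- toy_water_truth(p)
  comp0 <- composite_potential(list(H2O1 = m_intra), inter_model = NULL)
  cfg <- gt_label(truth, thermal_water_box(n_waters = 3L, seed = 29L, params = p))
  train <- configuration_set(list(make_inter_labels(cfg, comp0)))
  m_inter <- gp_fit(train, water_inter_specs(),
                    hyper_params(sigma_E = 1e-3, sigma_F = 0.2,
                                 n_sparse = 40L, e0_mode = "zero"), seed = 1)
  comp <- composite_potential(list(H2O1 = m_intra), m_inter,
                              expansion_factor = 10, bond_scale = 1.2)
  path <- withr::local_tempfile(fileext = ".json")
  save_composite(comp, path)
  back <- load_composite(path)
  expect_equal(composite_evaluate(back, cfg, forces = FALSE)$energy,
               composite_evaluate(comp, cfg, forces = FALSE)$energy,
               tolerance = 1e-8)
  expect_equal(back$expansion_factor, 10)
})
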