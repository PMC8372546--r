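## Shared fixtures, built in code.

## two water molecules separated along x by `sep` (gas phase)
water_dimer <- function(sep = 2.8) {
  tm <- water_template()
  configuration(c(tm$species, tm$species),
                rbind(tm$positions,
                      sweep(tm$positions, 2L, c(sep, 0.3, 0.2), "+")),
                partition = list(1:3, 4:6))
}

## a small periodic water box sampled near 300 K from the surrogate
thermal_water_box <- function(n_waters = 3L, box = 7, seed = 1L,
                              n_steps = 400L, params = test_water_params()) {
  truth <- toy_water_truth(params)
  pack <- random_packed_configuration(list(water_template()), n_waters,
                                      box = box, min_dist = 1.7, seed = seed)
  minim <- minimise(truth, pack, f_max = 0.1, max_steps = 2000L)
  traj <- run_md(truth, minim, md_params(T = 300, dt = 0.5, gamma = 0.05,
                                         n_steps = n_steps, stride = n_steps,
                                         seed = seed))
  cfg <- traj$frames[[length(traj$frames)]]
  cfg$velocities <- NULL
  cfg
}

## surrogate parameters whose interaction range fits a 7 A periodic box
test_water_params <- function() toy_water_params(r_switch = 2.5, r_cut = 3.0)

## random rotation matrix (seeded by caller)
rotation_matrix <- function(axis = c(0, 0, 1), angle = 0.7) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

## 1-d harmonic bond potential between two atoms (analytic test potential)
harmonic_bond_potential <- function(k = 25, r0 = 0.96) {
  function(cfg) {
    d <- cfg$positions[2, ] - cfg$positions[1, ]
    r <- sqrt(sum(d * d))
    u <- d / r
    f <- k * (r - r0)
    list(energy = 0.5 * k * (r - r0)^2,
         forces = rbind(f * u, -f * u))
  }
}
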