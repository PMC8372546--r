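## End-to-end training pipelines: the intra+inter (I+I) strategy for bulk
## water boxes against the toy surrogate, and the random-configuration
## baseline it is compared with.

#' Descriptor specification for the water intramolecular model
#'
#' 2- and 3-body terms on oxygen centres, fitted to the monomer grid.
#'
#' @param r_c cutoff, A.
#' @param theta squared-exponential length scale, A (and on the cosine).
#' @param delta signal amplitude, eV.
#' @return list of `descriptor_spec`s.
#' @export
water_intra_specs <- function(r_c = 3.0, theta = 0.25, delta = 3) {
  list(descriptor_spec("two_body", "O", r_c = r_c, sigma_atom = theta,
                       delta = delta),
       descriptor_spec("three_body", "O", r_c = r_c, sigma_atom = theta,
                       theta_cos = theta, delta = delta))
}

#' Descriptor specification for the water intermolecular model
#'
#' Species-resolved intermolecular pair terms plus an oxygen-centred SOAP
#' many-body residual term.
#'
#' @param r_c cutoff, A (3.0 A for the 7 A study boxes).
#' @param theta pair-kernel length scale, A.
#' @param delta_2b,delta_soap signal amplitudes, eV.
#' @param n_sparse_2b,n_sparse_soap per-descriptor sparse-point counts.
#' @return list of `descriptor_spec`s.
#' @export
water_inter_specs <- function(r_c = 3.0, theta = 0.12, delta_2b = 5,
                              delta_soap = 1, n_sparse_2b = 60L,
                              n_sparse_soap = 250L) {
  list(descriptor_spec("two_body", "O", r_c = r_c, sigma_atom = theta,
                       delta = delta_2b, neighbor_species = "O",
                       intermolecular = TRUE, n_sparse = n_sparse_2b),
       descriptor_spec("two_body", "O", r_c = r_c, sigma_atom = theta,
                       delta = delta_2b, neighbor_species = "H",
                       intermolecular = TRUE, n_sparse = n_sparse_2b),
       descriptor_spec("two_body", "H", r_c = r_c, sigma_atom = theta,
                       delta = delta_2b, neighbor_species = "H",
                       intermolecular = TRUE, n_sparse = n_sparse_2b),
       descriptor_spec("soap", "O", r_c = r_c, sigma_atom = 0.5, n_max = 4L,
                       l_max = 3L, zeta = 4, delta = delta_soap,
                       n_sparse = n_sparse_soap))
}

#' Fit the water intramolecular model on the monomer grid
#'
#' Labels the geometrically feasible part of the evenly spaced monomer grid
#' with the ground truth and fits the 2+3-body model tightly. An optional
#' refinement stage then samples monomer geometries from MD driven by the
#' grid-fitted model at an elevated temperature, labels them with the ground
#' truth and refits — sharpening the model exactly where thermal dynamics
#' lives, in the spirit of the elevated-temperature intramolecular active
#' learning used when no grid is available.
#'
#' @param truth a `ground_truth` for single water molecules.
#' @param gspec a `grid_spec`.
#' @param specs intra descriptor specs.
#' @param refine_n number of refinement geometries (0 disables the stage).
#' @param refine_T refinement MD temperature, K.
#' @param seed integer seed.
#' @return a `gp_model`.
#' @export
fit_water_intra <- function(truth, gspec = grid_spec(),
                            specs = water_intra_specs(), refine_n = 24L,
                            refine_T = 600, seed = 1L) {
  grid <- feasible_configurations(grid_monomer_configurations(gspec))
  lab <- configuration_set(lapply(unclass(grid), function(c) gt_label(truth, c)))
  hy <- hyper_params(n_sparse = 10000L, sigma_E = 1e-5, sigma_F = 0.02)
  model <- gp_fit(lab, specs, hy, seed = seed)
  if (refine_n > 0L) {
    eq <- grid_centre_monomer(gspec)
    traj <- run_md(model, eq,
                   md_params(T = refine_T, dt = 0.5, gamma = 0.1,
                             n_steps = 100L * refine_n, stride = 100L,
                             seed = stage_seed(seed, "intra-refine")))
    extra <- lapply(unclass(traj$frames)[-1], function(f) {
      f$velocities <- NULL
      gt_label(truth, f)
    })
    model <- gp_fit(c(lab, configuration_set(extra)), specs, hy, seed = seed)
  }
  model
}

## monomer at the centre of the grid ranges (refinement MD start)
grid_centre_monomer <- function(gspec) {
  r <- mean(gspec$r_OH1)
  rhh <- min(mean(gspec$r_HH), 1.9 * r)
  ct <- (2 * r^2 - rhh^2) / (2 * r^2)
  configuration(c("O", "H", "H"),
                rbind(c(0, 0, 0), c(r, 0, 0),
                      c(r * ct, r * sqrt(1 - ct^2), 0)),
                partition = list(1:3))
}

#' Train a bulk-water composite potential by intra+inter active learning
#'
#' Stage 1 fits the intramolecular model on the monomer grid; stage 2 runs
#' the episode-scheduled active-learning loop on the intermolecular
#' residual: exploration MD under the current composite, subtraction labels
#' via [make_inter_labels()], refits on every accepted addition. The start
#' configuration is a randomly packed, minimised box, the same for every
#' episode.
#'
#' @param truth a `ground_truth` for the periodic water boxes.
#' @param n_waters molecules in the box.
#' @param box cubic box edge, A.
#' @param al an `al_params` (threshold, budget, exploration temperature).
#' @param md an `md_params` (timestep, friction).
#' @param inter_specs intermolecular descriptor specs.
#' @param inter_hyper hyperparameters of the intermolecular fit.
#' @param intra_model optionally, a pre-fitted intramolecular model.
#' @param start optionally, a pre-built start configuration.
#' @param seed integer seed.
#' @return list with `composite` (a `composite_potential`), `history`
#'   (an `al_history`), `start` (the minimised start configuration) and
#'   `intra_model`.
#' @export
train_water_composite <- function(truth, n_waters = 10L, box = 7,
                                  al = al_params(E_add = 0.01,
                                                 max_truth_evals = 250L,
                                                 target_time = 1000),
                                  md = md_params(dt = 0.5, gamma = 0.02),
                                  inter_specs = water_inter_specs(),
                                  inter_hyper = hyper_params(
                                    sigma_E = 3e-5, sigma_F = 0.1,
                                    n_sparse = 250L, e0_mode = "zero"),
                                  intra_model = NULL, start = NULL,
                                  seed = 1L) {
  if (is.null(intra_model)) {
    intra_model <- fit_water_intra(truth, seed = seed)
  }
  if (is.null(start)) {
    pack <- random_packed_configuration(list(water_template()), n_waters,
                                        box = box, min_dist = 1.7,
                                        seed = stage_seed(seed, "pack"))
    ## start-structure preparation is shared by every training strategy and
    ## is not charged to the truth-evaluation budget
    start <- minimise(truth, pack, f_max = 0.05, max_steps = 5000L)
    start$energy <- NULL
  }
  comp_frame <- composite_potential(list(H2O1 = intra_model),
                                    inter_model = NULL)
  fitter <- make_incremental_fitter(inter_specs, inter_hyper)
  label_cache <- list()   # subtraction labels are deterministic; compute once
  refit <- function(set, s) {
    set <- unclass(set)
    for (i in seq_along(set)) {
      if (i > length(label_cache) || is.null(label_cache[[i]])) {
        label_cache[[i]] <<- make_inter_labels(set[[i]], comp_frame)
      }
    }
    fitter(configuration_set(label_cache[seq_along(set)]), s)
  }
  as_pot <- function(m) composite_potential(list(H2O1 = intra_model), m)
  al$seed <- stage_seed(seed, "al")
  res <- run_active_learning(truth, configuration_set(list(start)),
                             inter_specs, inter_hyper, md, al,
                             start = start, refit = refit,
                             as_potential = as_pot)
  list(composite = as_pot(res$model), history = res$history, start = start,
       intra_model = intra_model)
}

#' Train the random-configuration baseline model
#'
#' A single (non-decomposed) GP potential fitted to randomly packed,
#' truth-labelled boxes — the baseline strategy the active-learning
#' composite is compared against.
#'
#' @param truth a `ground_truth`.
#' @param n_configs number of random configurations (the truth budget).
#' @param n_waters,box system definition.
#' @param specs descriptor specs (default: O- and H-centred SOAP).
#' @param hyper fit hyperparameters.
#' @param seed integer seed.
#' @return a `gp_model`.
#' @export
train_water_random <- function(truth, n_configs = 50L, n_waters = 10L,
                               box = 7,
                               specs = list(
                                 descriptor_spec("soap", "O", r_c = 3.0,
                                                 n_max = 4L, l_max = 3L,
                                                 zeta = 4, delta = 1),
                                 descriptor_spec("soap", "H", r_c = 3.0,
                                                 n_max = 4L, l_max = 3L,
                                                 zeta = 4, delta = 1)),
                               hyper = hyper_params(sigma_E = 1e-3,
                                                    sigma_F = 0.1,
                                                    n_sparse = 150L),
                               seed = 1L) {
  tmpl <- water_template()
  labelled <- lapply(seq_len(n_configs), function(i) {
    cfg <- random_packed_configuration(list(tmpl), n_waters, box = box,
                                       min_dist = 1.7,
                                       seed = stage_seed(seed, paste0("rand", i)))
    gt_label(truth, cfg)
  })
  gp_fit(configuration_set(labelled), specs, hyper, seed = seed)
}
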