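## Reactive-surface tooling for the EVB triatomic: well and transition-state
## geometries, and transition-state-initialised active learning with an
## optional NEB refinement stage.

evb_params_of <- function(truth) {
  env <- environment(truth$fun)
  if (!is.null(env$params)) env$params else evb_params()
}

#' Collinear well geometries of the EVB surrogate
#'
#' Minimised reactant (A-B bonded) and product (B-C bonded) configurations,
#' laid out along x.
#'
#' @param truth an EVB `ground_truth`.
#' @param species element symbols for atoms A, B, C.
#' @param r_far initial distance of the departing atom, A.
#' @return list with `reactant` and `product` configurations.
#' @export
evb_well_configurations <- function(truth, species = c("Cl", "C", "Cl"),
                                    r_far = 3.5) {
  p <- evb_params_of(truth)
  ## B at the origin in both wells; no atom exchanges identity between the
  ## endpoints, so a band between them follows the A-leaves/C-arrives
  ## valley instead of a coordinate-swap path
  react0 <- configuration(species, rbind(c(-p$re1, 0, 0), c(0, 0, 0),
                                         c(r_far, 0, 0)))
  prod0 <- configuration(species, rbind(c(-r_far, 0, 0), c(0, 0, 0),
                                        c(p$re2, 0, 0)))
  list(reactant = minimise(truth, react0, f_max = 1e-4, max_steps = 5000L),
       product = minimise(truth, prod0, f_max = 1e-4, max_steps = 5000L))
}

#' Symmetric transition-state geometry of the EVB surrogate
#'
#' For symmetric parameters the saddle lies on the collinear
#' `r_AB = r_BC` line; the position along that line is found by 1-d
#' minimisation of the constrained energy.
#'
#' @param truth an EVB `ground_truth`.
#' @param species element symbols for atoms A, B, C.
#' @return a 3-atom `configuration` at the saddle point.
#' @export
evb_ts_configuration <- function(truth, species = c("Cl", "C", "Cl")) {
  e_sym <- function(r) {
    cfg <- configuration(species, rbind(c(0, 0, 0), c(r, 0, 0), c(2 * r, 0, 0)))
    gt_evaluate(truth, cfg)$energy
  }
  r_ts <- stats::optimize(e_sym, c(1.2, 4.0))$minimum
  configuration(species, rbind(c(0, 0, 0), c(r_ts, 0, 0), c(2 * r_ts, 0, 0)))
}

#' Descriptors for the EVB triatomic GAP
#'
#' Central-atom-centred SOAP plus species-resolved pair terms.
#'
#' @param r_c SOAP cutoff, A (6 A spans the whole reactive complex).
#' @return list of `descriptor_spec`s.
#' @export
evb_gap_specs <- function(r_c = 6) {
  list(descriptor_spec("two_body", "C", r_c = r_c, sigma_atom = 0.3,
                       delta = 3, neighbor_species = "Cl"),
       descriptor_spec("two_body", "Cl", r_c = r_c, sigma_atom = 0.3,
                       delta = 3, neighbor_species = "Cl"),
       descriptor_spec("soap", "C", r_c = r_c, sigma_atom = 0.5, n_max = 6L,
                       l_max = 4L, zeta = 4, delta = 1))
}

#' Train a reactive GAP on the EVB surface by TS-initialised active learning
#'
#' Active learning starts from the symmetric transition state and explores
#' under the model's own dynamics; an optional refinement stage relaxes a
#' nudged elastic band between the two wells on the current model, labels
#' the relaxed images with the ground truth, adds those whose energy error
#' exceeds the acceptance threshold, and refits — the step that samples the
#' product region adequately.
#'
#' @param truth an EVB `ground_truth`.
#' @param al an `al_params`.
#' @param md an `md_params`.
#' @param specs descriptor specs.
#' @param hyper fit hyperparameters.
#' @param neb_rounds number of NEB refinement rounds.
#' @param n_images NEB images per round.
#' @param downhill_n frames sampled per direction from strongly damped
#'   model dynamics started at the TS with a small kick along each breaking
#'   bond (an inexpensive IRC trace); 0 disables the stage.
#' @param seed integer seed.
#' @return list with `model`, `history`, `ts`, `wells` and
#'   `neb_added` (count of refinement additions).
#' @export
train_evb_gap <- function(truth,
                          al = al_params(E_add = 0.01, T_AL = 300,
                                         max_truth_evals = 150L,
                                         target_time = 1000,
                                         max_energy_rise = 5),
                          md = md_params(dt = 0.5, gamma = 0.05),
                          specs = evb_gap_specs(),
                          hyper = hyper_params(sigma_E = 3e-4, sigma_F = 0.02,
                                               n_sparse = 120L),
                          neb_rounds = 4L, n_images = 21L,
                          downhill_n = 0L, seed = 1L) {
  ts <- evb_ts_configuration(truth)
  wells <- evb_well_configurations(truth)
  init <- configuration_set(list(ts, wells$reactant, wells$product))
  al$seed <- stage_seed(seed, "evb-al")
  res <- run_active_learning(truth, init, specs, hyper, md, al, start = ts)
  model <- res$model
  train <- res$history$train_set
  evals <- res$history$truth_evals_used
  if (downhill_n > 0L) {
    ## strongly damped dynamics from the TS in both directions follows the
    ## steepest-descent (IRC-like) path into each well
    for (bond in list(c(1L, 2L), c(2L, 3L))) {
      kick <- inject_bond_energy(ts, bond[1L], bond[2L], 0.02)
      traj <- run_md(model, kick,
                     md_params(T = 0, dt = 0.5, gamma = 0.5,
                               n_steps = 24L * downhill_n, stride = 24L,
                               seed = stage_seed(seed, "downhill")))
      for (f in unclass(traj$frames)[-1]) {
        f$velocities <- NULL
        lab <- gt_label(truth, f)
        evals <- evals + 1L
        train <- c(train, configuration_set(list(lab)))
      }
    }
    model <- gp_fit(train, specs, hyper, seed = al$seed)
  }
  neb_added <- 0L
  e_floor <- min(vapply(unclass(train), function(c) c$energy, numeric(1)))
  for (round in seq_len(neb_rounds)) {
    path <- tryCatch(
      neb_relax(model, wells$reactant, wells$product, n_images = n_images,
                k_spring = 5, f_max = 0.02, max_steps = 3000L,
                init_noise = 0.05, seed = stage_seed(seed, paste0("neb", round))),
      error = function(e) e$path)
    if (is.null(path)) break
    added_this <- 0L
    for (img in unclass(path$images)[2:(n_images - 1L)]) {
      img$velocities <- NULL
      lab <- gt_label(truth, img)
      if (abs(lab$energy - img$energy) > al$E_add &&
          lab$energy - e_floor <= al$max_energy_rise) {
        train <- c(train, configuration_set(list(lab)))
        added_this <- added_this + 1L
      }
    }
    neb_added <- neb_added + added_this
    if (added_this == 0L) break
    model <- gp_fit(train, specs, hyper, seed = al$seed)
  }
  list(model = model, history = res$history, ts = ts, wells = wells,
       neb_added = neb_added,
       truth_evals_total = if (exists("evals")) evals + neb_added else
         res$history$truth_evals_used + neb_added)
}

#' Relaxed 1-d scan of the EVB exchange coordinate (oracle)
#'
#' For each value of the asymmetric coordinate `q = r_AB - r_BC`, minimises
#' the collinear energy over the total span `r_AB + r_BC`; the maximum over
#' `q` is the reaction barrier.
#'
#' @param pot any energy provider (surrogate or model).
#' @param species element symbols for A, B, C.
#' @param q_range range of `r_AB - r_BC`, A.
#' @param n_q scan resolution.
#' @return data.frame with `q`, `energy` (eV), `r_AB`, `r_BC`.
#' @export
evb_scan_profile <- function(pot, species = c("Cl", "C", "Cl"),
                             q_range = c(-1.5, 1.5), n_q = 61L) {
  qs <- seq(q_range[1L], q_range[2L], length.out = n_q)
  rows <- lapply(qs, function(q) {
    e_of_s <- function(s) {
      rab <- (s + q) / 2; rbc <- (s - q) / 2
      cfg <- configuration(species,
                           rbind(c(0, 0, 0), c(rab, 0, 0), c(rab + rbc, 0, 0)))
      evaluate_potential(pot, cfg, forces = FALSE)$energy
    }
    opt <- stats::optimize(e_of_s, c(max(abs(q)) + 2.4, abs(q) + 8))
    data.frame(q = q, energy = opt$objective,
               r_AB = (opt$minimum + q) / 2, r_BC = (opt$minimum - q) / 2)
  })
  do.call(rbind, rows)
}
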