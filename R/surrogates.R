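## Analytic surrogate ground-truth potentials and the evaluator contract.
##
## A ground truth is any object usable with gt_evaluate(): deterministic,
## translation-invariant, rotation-invariant for non-periodic inputs and
## invariant under permutation of identical atoms. The in-repo surrogates
## stand in for expensive electronic-structure references so the full
## training workflow can be exercised end-to-end.

#' Construct a ground-truth evaluator
#'
#' @param fun function taking a `configuration` and returning
#'   `list(energy=, forces=)` (eV, eV/A).
#' @param level_tag free-text label of the level of theory.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(fun, level_tag) {
  structure(list(fun = fun, level_tag = level_tag), class = "ground_truth")
}

#' Evaluate a ground truth on a configuration
#'
#' @param truth a `ground_truth`.
#' @param cfg a `configuration`.
#' @return `list(energy=, forces=)`.
#' @export
gt_evaluate <- function(truth, cfg) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- truth$fun(cfg)
  if (!is.finite(out$energy) || !all(is.finite(out$forces))) {
    stop("ground truth returned non-finite energy/forces")
  }
  out
}

#' Attach ground-truth labels to a configuration
#'
#' @param truth a `ground_truth`.
#' @param cfg a `configuration`.
#' @return the configuration with `energy`, `forces` and `level_tag` filled.
#' @export
gt_label <- function(truth, cfg) {
  out <- gt_evaluate(truth, cfg)
  cfg$energy <- out$energy
  cfg$forces <- out$forces
  cfg$level_tag <- truth$level_tag
  cfg
}

## ---------------------------------------------------------------------------
## Flexible toy water: harmonic bonds + angle per molecule, switched
## Lennard-Jones on O pairs and switched Coulomb on intermolecular pairs.
## Strictly separable into intra- and inter-molecular parts by construction.

#' Parameters of the flexible toy water surrogate
#'
#' SPC-like magnitudes: harmonic O-H bonds and H-O-H angle, Lennard-Jones on
#' oxygen and point-charge Coulomb between intermolecular pairs, both
#' multiplied by a C1 cubic-Hermite switching function between `r_switch` and
#' `r_cut`. When `box` is given, the cutoff is limited to remain inside the
#' minimum-image safe regime of that cubic box.
#'
#' @param k_b O-H bond force constant, eV/A^2.
#' @param r0 equilibrium O-H length, A.
#' @param k_a angle force constant, eV/rad^2.
#' @param theta0 equilibrium H-O-H angle, rad.
#' @param epsilon,sigma Lennard-Jones well depth (eV) and size (A) on O.
#' @param q_O,q_H point charges, e (constraint `q_O + 2 q_H = 0`).
#' @param r_switch,r_cut intermolecular switch/cutoff radii, A.
#' @param box optional cubic box edge, A; limits `r_cut` below half the edge.
#' @return named list of parameters.
#' @export
toy_water_params <- function(k_b = 25, r0 = 0.96, k_a = 3, theta0 = 1.824,
                             epsilon = 0.007, sigma = 3.166,
                             q_O = -0.82, q_H = 0.41,
                             r_switch = 5, r_cut = 6, box = NULL) {
  if (!is.null(box)) {
    safe <- 0.49 * min(box)
    if (r_cut > safe) {
      r_cut <- safe
      r_switch <- r_cut * 5 / 6
    }
  }
  stopifnot(k_b > 0, k_a > 0, r_switch < r_cut,
            abs(q_O + 2 * q_H) < 1e-12)
  list(k_b = k_b, r0 = r0, k_a = k_a, theta0 = theta0, epsilon = epsilon,
       sigma = sigma, q_O = q_O, q_H = q_H, k_coul = .COULOMB_EV_A,
       r_switch = r_switch, r_cut = r_cut)
}

toy_water_prepare <- function(cfg, params) {
  if (!all(cfg$species %in% c("O", "H"))) {
    stop("toy water requires O/H composition only")
  }
  nO <- sum(cfg$species == "O")
  nH <- sum(cfg$species == "H")
  if (nH != 2L * nO) stop("toy water requires O:H in 1:2 ratio")
  part <- cfg$partition
  if (is.null(part)) part <- infer_molecules(cfg)
  if (any(lengths(part) != 3L)) stop("toy water molecules must have 3 atoms")
  mol_id <- integer(n_atoms(cfg))
  for (m in seq_along(part)) mol_id[part[[m]]] <- m - 1L
  if (any(cfg$pbc)) {
    L <- assert_orthorhombic(cfg$cell)
    if (params$r_cut >= min(L[cfg$pbc]) / 2) {
      stop("toy water cutoff must be below half the periodic box edge")
    }
    Ldiag <- L
  } else {
    Ldiag <- c(1, 1, 1)
  }
  list(mol_id = mol_id, Ldiag = Ldiag)
}

#' Evaluate the toy water surrogate
#'
#' @param cfg a `configuration` of O/H atoms in 1:2 ratio; the molecular
#'   partition is taken from `cfg$partition` or inferred from connectivity.
#' @param params from [toy_water_params()].
#' @return list with `energy`, `forces` and the separable components
#'   `e_intra`, `f_intra`, `e_inter`, `f_inter`.
#' @export
toy_water_evaluate <- function(cfg, params = toy_water_params()) {
  prep <- toy_water_prepare(cfg, params)
  cpp_toy_water(cfg$positions, as.integer(cfg$species == "O"), prep$mol_id,
                prep$Ldiag, cfg$pbc, params)
}

#' Toy water as a ground-truth evaluator
#'
#' @param params from [toy_water_params()].
#' @param component `"total"`, `"intra"` or `"inter"`: which separable part
#'   the evaluator reports (the intra/inter parts serve the decomposition
#'   oracles).
#' @return a `ground_truth`.
#' @export
toy_water_truth <- function(params = toy_water_params(),
                            component = c("total", "intra", "inter")) {
  component <- match.arg(component)
  tag <- paste0("toy-water", if (component != "total") paste0("-", component))
  ground_truth(function(cfg) {
    out <- toy_water_evaluate(cfg, params)
    switch(component,
           total = list(energy = out$energy, forces = out$forces),
           intra = list(energy = out$e_intra, forces = out$f_intra),
           inter = list(energy = out$e_inter, forces = out$f_inter))
  }, level_tag = tag)
}

## ---------------------------------------------------------------------------
## Two-state empirical valence bond (EVB) reactive surface on a triatomic.

#' Parameters of the two-state EVB surrogate
#'
#' Diabats `V1 = Morse_AB(r_AB) + C_rep exp(-r_BC/rho)` and
#' `V2 = Morse_BC(r_BC) + C_rep exp(-r_AB/rho)`; the surface is the lower
#' eigenvalue of the 2x2 matrix with constant coupling `delta`. The defaults
#' give a symmetric identity-exchange reaction (two equivalent wells separated
#' by a barrier of a few tenths of an eV, in the range typical of solution
#' substitution chemistry).
#'
#' @param De1,a1,re1 Morse parameters of the A-B diabat (eV, 1/A, A).
#' @param De2,a2,re2 Morse parameters of the B-C diabat.
#' @param delta constant diabatic coupling, eV.
#' @param C_rep,rho non-bonded pair repulsion amplitude (eV) and range (A).
#' @return named list of parameters.
#' @export
evb_params <- function(De1 = 2.0, a1 = 1.2, re1 = 2.0,
                       De2 = 2.0, a2 = 1.2, re2 = 2.0,
                       delta = 0.25, C_rep = 100, rho = 0.4) {
  stopifnot(De1 > 0, De2 > 0, a1 > 0, a2 > 0, delta > 0, rho > 0)
  list(De1 = De1, a1 = a1, re1 = re1, De2 = De2, a2 = a2, re2 = re2,
       delta = delta, C_rep = C_rep, rho = rho)
}

#' Evaluate the EVB surrogate
#'
#' Atoms are taken as A, B, C in configuration order (exactly 3 atoms).
#'
#' @param cfg a 3-atom `configuration`.
#' @param params from [evb_params()].
#' @return list with `energy`, `forces` and the diabat values `V1`, `V2`.
#' @export
evb_evaluate <- function(cfg, params = evb_params()) {
  if (n_atoms(cfg) != 3L) stop("EVB surface requires exactly 3 atoms")
  cpp_evb(cfg$positions, params)
}

#' EVB surface as a ground-truth evaluator
#'
#' @param params from [evb_params()].
#' @param level_tag label, default "evb".
#' @return a `ground_truth`.
#' @export
evb_truth <- function(params = evb_params(), level_tag = "evb") {
  ground_truth(function(cfg) {
    out <- evb_evaluate(cfg, params)
    list(energy = out$energy, forces = out$forces)
  }, level_tag = level_tag)
}

## ---------------------------------------------------------------------------

#' Central finite-difference forces (test oracle)
#'
#' @param truth a `ground_truth` (or anything accepted by
#'   [evaluate_potential()]).
#' @param cfg a `configuration`.
#' @param h displacement step, A.
#' @return N x 3 matrix of forces, eV/A.
#' @export
finite_difference_forces <- function(truth, cfg, h = 1e-5) {
  stopifnot(h > 0)
  energy_of <- function(c2) evaluate_potential(truth, c2, forces = FALSE)$energy
  n <- n_atoms(cfg)
  f <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    for (a in 1:3) {
      cp <- cfg; cp$positions[i, a] <- cp$positions[i, a] + h
      cm <- cfg; cm$positions[i, a] <- cm$positions[i, a] - h
      f[i, a] <- -(energy_of(cp) - energy_of(cm)) / (2 * h)
    }
  }
  f
}

#' File-based adapter to an external ground-truth code
#'
#' Interface only: writes the configuration as extended-XYZ, substitutes the
#' input/output paths into a user command template, runs it, and parses the
#' labelled extended-XYZ it must produce (`energy=` plus a forces block).
#'
#' @param command_template shell command containing `{input}` and `{output}`
#'   placeholders.
#' @param level_tag label for the external level of theory.
#' @return a `ground_truth`.
#' @export
external_truth <- function(command_template, level_tag = "external") {
  ground_truth(function(cfg) {
    tin <- tempfile(fileext = ".xyz"); tout <- tempfile(fileext = ".xyz")
    on.exit(unlink(c(tin, tout)))
    write_extxyz(configuration_set(list(cfg)), tin)
    cmd <- gsub("{input}", tin, command_template, fixed = TRUE)
    cmd <- gsub("{output}", tout, cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0L) stop("external ground-truth command failed: ", cmd)
    res <- read_extxyz(tout)[[1L]]
    if (is.null(res$energy) || is.null(res$forces)) {
      stop("external ground truth must return energy= and forces")
    }
    list(energy = res$energy, forces = res$forces)
  }, level_tag = level_tag)
}
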