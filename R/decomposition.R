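## Intra+inter (I+I) molecular decomposition: connectivity-based molecular
## partitioning, expanded-box intramolecular evaluation, subtraction-based
## intermolecular labels, and the combined composite potential.

#' Molecule type label from a species multiset ("H2O", "Cl2C1", ...)
#' @param species element symbols of one molecule.
#' @return character label.
#' @export
molecule_type <- function(species) {
  tb <- table(species)
  paste0(names(tb), as.integer(tb), collapse = "")
}

#' Partition a configuration into molecules by covalent connectivity
#'
#' Atoms are bonded when their minimum-image distance is below
#' `bond_scale * (R_cov_i + R_cov_j)`; molecules are the connected components,
#' sorted by lowest atom index. When `solute_atoms` is given those atoms are
#' removed first and returned as the first group regardless of connectivity
#' (used, e.g., to keep a reactive solute as one intra component).
#'
#' @param cfg a `configuration`.
#' @param bond_scale covalent-radius multiplier.
#' @param solute_atoms optional integer vector of 1-based atom indices.
#' @return list of integer vectors (disjoint 1-based atom groups).
#' @export
infer_molecules <- function(cfg, bond_scale = 1.2, solute_atoms = NULL) {
  n <- n_atoms(cfg)
  rc <- covalent_radii(cfg$species)
  rest <- seq_len(n)
  groups <- list()
  if (!is.null(solute_atoms)) {
    solute_atoms <- sort(unique(as.integer(solute_atoms)))
    stopifnot(all(solute_atoms >= 1L), all(solute_atoms <= n))
    groups[[1L]] <- solute_atoms
    rest <- setdiff(rest, solute_atoms)
  }
  if (length(rest)) {
    idx <- rest
    m <- length(idx)
    adj <- vector("list", m)
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        i <- idx[a]; j <- idx[b]
        d <- minimum_image_displacement(cfg, i, j)
        if (sum(d * d) < (bond_scale * (rc[i] + rc[j]))^2) {
          adj[[a]] <- c(adj[[a]], b)
          adj[[b]] <- c(adj[[b]], a)
        }
      }
    }
    seen <- logical(m)
    for (a in seq_len(m)) {
      if (seen[a]) next
      comp <- integer(0); stack <- a
      while (length(stack)) {
        v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        if (seen[v]) next
        seen[v] <- TRUE
        comp <- c(comp, v)
        stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
      }
      groups[[length(groups) + 1L]] <- sort(idx[comp])
    }
  }
  groups[order(vapply(groups, min, numeric(1)))]
}

#' Rigidly separate molecules by scaling the box
#'
#' Scales the cell by `factor` and rigidly translates each molecule so its
#' geometric centroid scales by `factor` while the internal geometry is
#' bit-identical; atom order is preserved. Used so intramolecular models see
#' no foreign atoms within their cutoff.
#'
#' @param cfg a periodic `configuration`.
#' @param partition list of atom-index groups (one per molecule).
#' @param factor expansion factor (> 1), default 10.
#' @param min_sep optional contract check: error if any cross-molecule pair
#'   ends up closer than this distance (A).
#' @return the expanded `configuration`.
#' @export
expand_for_intra <- function(cfg, partition, factor = 10, min_sep = NULL) {
  if (factor <= 1) stop("expansion factor must be > 1")
  if (!any(cfg$pbc)) stop("expand_for_intra requires a periodic configuration")
  out <- cfg
  out$cell <- cfg$cell * factor
  for (grp in partition) {
    centroid <- colMeans(cfg$positions[grp, , drop = FALSE])
    shift <- (factor - 1) * centroid
    out$positions[grp, ] <- sweep(cfg$positions[grp, , drop = FALSE], 2L, shift, "+")
  }
  out$partition <- partition
  if (!is.null(min_sep)) {
    for (a in seq_along(partition)) {
      for (b in seq_along(partition)) {
        if (b <= a) next
        for (i in partition[[a]]) {
          for (j in partition[[b]]) {
            d <- minimum_image_displacement(out, i, j)
            if (sum(d * d) < min_sep^2) {
              stop("expanded box still has cross-molecule contact within cutoff")
            }
          }
        }
      }
    }
  }
  out
}

#' Combine intramolecular and intermolecular models
#'
#' @param intra_models named list mapping molecule-type label (see
#'   [molecule_type()]; the key `"solute"` matches the explicit solute group)
#'   to fitted `gp_model`s.
#' @param inter_model a `gp_model` for the intermolecular residual.
#' @param expansion_factor box-scaling multiplier for intra evaluation.
#' @param bond_scale covalent-radius multiplier for connectivity.
#' @param solute_atoms optional explicit atom-index list overriding
#'   connectivity for the (reactive) solute.
#' @return object of class `composite_potential`.
#' @export
composite_potential <- function(intra_models, inter_model,
                                expansion_factor = 10, bond_scale = 1.2,
                                solute_atoms = NULL) {
  stopifnot(expansion_factor > 1)
  structure(list(intra_models = intra_models, inter_model = inter_model,
                 expansion_factor = expansion_factor, bond_scale = bond_scale,
                 solute_atoms = solute_atoms),
            class = "composite_potential")
}

#' @export
print.composite_potential <- function(x, ...) {
  cat(sprintf("<composite_potential> intra: %s; inter: %s; expansion x%g\n",
              paste(names(x$intra_models), collapse = ","),
              x$inter_model$level_tag, x$expansion_factor))
  invisible(x)
}

## Partition for this configuration: reuse the one carried by the
## configuration lineage (frozen during MD), else infer once.
composite_partition <- function(comp, cfg) {
  if (!is.null(cfg$partition)) return(cfg$partition)
  infer_molecules(cfg, comp$bond_scale, comp$solute_atoms)
}

group_type <- function(comp, grp, cfg) {
  if (!is.null(comp$solute_atoms) &&
      length(grp) == length(comp$solute_atoms) &&
      all(grp == sort(comp$solute_atoms))) {
    return("solute")
  }
  molecule_type(cfg$species[grp])
}

#' Intramolecular part of a composite prediction
#'
#' Each intra model is evaluated with all molecules rigidly separated (in the
#' expanded box for periodic inputs, or as isolated molecules in the gas
#' phase); forces map back to the original atom indices unchanged, since a
#' rigid translation leaves internal gradients identical.
#'
#' @param comp a `composite_potential`.
#' @param cfg a `configuration`.
#' @param forces evaluate forces too?
#' @return `list(energy=, forces=)`.
#' @export
intra_evaluate <- function(comp, cfg, forces = TRUE) {
  part <- composite_partition(comp, cfg)
  n <- n_atoms(cfg)
  energy <- 0
  f <- if (forces) matrix(0, n, 3L) else NULL

  work <- if (any(cfg$pbc)) expand_for_intra(cfg, part, comp$expansion_factor) else cfg

  types <- vapply(part, function(g) group_type(comp, g, cfg), character(1))
  for (ty in unique(types)) {
    model <- comp$intra_models[[ty]]
    if (is.null(model)) stop("no intramolecular model for molecule type ", ty)
    atoms <- unlist(part[types == ty])
    sub <- configuration(species = work$species[atoms],
                         positions = work$positions[atoms, , drop = FALSE],
                         cell = work$cell, pbc = work$pbc)
    out <- gp_eval(model, sub, forces = forces)
    energy <- energy + out$energy
    if (forces) f[atoms, ] <- f[atoms, ] + out$forces
  }
  list(energy = energy, forces = f)
}

#' Subtraction-based intermolecular labels
#'
#' Returns a copy of the configuration whose energy and forces are the total
#' labels minus the intramolecular prediction — the training target for the
#' intermolecular model. The level tag gains an "-inter" suffix.
#'
#' @param cfg a labelled `configuration` (energy and forces present).
#' @param comp a `composite_potential` whose intra models are fitted (the
#'   inter model slot may be `NULL` at this stage).
#' @return the relabelled `configuration`.
#' @export
make_inter_labels <- function(cfg, comp) {
  if (is.null(cfg$energy) || is.null(cfg$forces)) {
    stop("make_inter_labels needs total energy and forces on the configuration")
  }
  intra <- intra_evaluate(comp, cfg, forces = TRUE)
  out <- cfg
  out$energy <- cfg$energy - intra$energy
  out$forces <- cfg$forces - intra$forces
  out$partition <- composite_partition(comp, cfg)
  out$level_tag <- paste0(if (is.null(cfg$level_tag)) "total" else cfg$level_tag,
                          "-inter")
  out
}

#' Combined intra+inter prediction
#'
#' `energy = intra_evaluate + inter model on the original (periodic)
#' configuration`; forces likewise summed, so additivity is exact by
#' construction.
#'
#' @param comp a `composite_potential`.
#' @param cfg a `configuration`.
#' @param forces evaluate forces too?
#' @return `list(energy=, forces=)`.
#' @export
composite_evaluate <- function(comp, cfg, forces = TRUE) {
  cfg$partition <- composite_partition(comp, cfg)
  intra <- intra_evaluate(comp, cfg, forces = forces)
  inter <- gp_eval(comp$inter_model, cfg, forces = forces)
  list(energy = intra$energy + inter$energy,
       forces = if (forces) intra$forces + inter$forces else NULL,
       e_intra = intra$energy, e_inter = inter$energy)
}

#' Save a composite potential archive
#'
#' Bundles the component model archives with the partition-rule metadata in
#' one self-describing JSON file.
#'
#' @param comp a `composite_potential`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
save_composite <- function(comp, path) {
  obj <- list(schema_version = .GP_SCHEMA, class = "composite_potential",
              intra_models = lapply(comp$intra_models, model_to_list),
              inter_model = model_to_list(comp$inter_model),
              expansion_factor = comp$expansion_factor,
              bond_scale = comp$bond_scale,
              solute_atoms = comp$solute_atoms)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' Load a composite archive written by [save_composite()]
#'
#' @param path archive path.
#' @return a `composite_potential`.
#' @export
load_composite <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$schema_version) || raw$schema_version != .GP_SCHEMA) {
    stop("composite archive schema version mismatch (expected ", .GP_SCHEMA, ")")
  }
  if (!identical(raw$class, "composite_potential")) {
    stop("archive does not hold a composite_potential")
  }
  composite_potential(
    intra_models = lapply(raw$intra_models, model_from_list),
    inter_model = model_from_list(raw$inter_model),
    expansion_factor = raw$expansion_factor,
    bond_scale = raw$bond_scale,
    solute_atoms = if (!is.null(raw$solute_atoms)) unlist(raw$solute_atoms))
}
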