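## Sparse Gaussian-process interatomic potential.
##
## Total energy: E(config) = sum_atoms e0[element] +
##   sum_specs sum_{centres} sum_s w_s k(env_centre, env_s)
## with k the (L2-normalised dot product)^zeta for the SOAP power spectrum and
## a squared-exponential over (r) / (r1, r2, cos) feature space for the
## 2-/3-body descriptors. Weights solve the regularised projected-process
## normal equations with one energy row per configuration (noise sigma_E * N)
## and, where labels exist, 3N force rows (noise sigma_F).

#' GP hyperparameters
#'
#' @param sigma_E energy noise, eV per atom.
#' @param sigma_F force noise, eV/A.
#' @param n_sparse sparse environments per descriptor.
#' @param sparse_method `"cur"` or `"random"`.
#' @param jitter diagonal regulariser.
#' @param e0_mode `"fit"` estimates per-element baselines from the training
#'   energies by least squares; `"zero"` fixes them at 0 (appropriate for
#'   residual targets such as intermolecular labels, which vanish for
#'   separated molecules).
#' @return object of class `hyper_params`.
#' @export
hyper_params <- function(sigma_E = 1e-3, sigma_F = 0.05, n_sparse = 200L,
                         sparse_method = c("cur", "random"), jitter = 1e-8,
                         e0_mode = c("fit", "zero")) {
  sparse_method <- match.arg(sparse_method)
  e0_mode <- match.arg(e0_mode)
  stopifnot(sigma_E > 0, sigma_F > 0, jitter > 0, n_sparse >= 1L)
  structure(list(sigma_E = sigma_E, sigma_F = sigma_F,
                 n_sparse = as.integer(n_sparse),
                 sparse_method = sparse_method, jitter = jitter,
                 e0_mode = e0_mode),
            class = "hyper_params")
}

## Per-spec environment pooling ---------------------------------------------

pool_environments <- function(set, spec) {
  rows <- lapply(unclass(set), function(cfg) {
    switch(spec$kind,
      soap = soap_descriptor(cfg, spec)$values,
      two_body = {
        f <- two_body_features(cfg, spec)
        cbind(f$r, f$w)
      },
      three_body = {
        f <- three_body_features(cfg, spec)
        cbind(f$r1, f$r2, f$cos_theta, f$w)
      })
  })
  m <- do.call(rbind, rows)
  if (is.null(m) || nrow(m) == 0L) return(NULL)
  m
}

## Select sparse points from pooled rows; returns the stored sparse
## representation for the spec.
select_sparse <- function(pool, spec, hyper, seed) {
  feat_cols <- switch(spec$kind, soap = seq_len(ncol(pool)),
                      two_body = 1L, three_body = 1:3)
  uniq <- pool[!duplicated(round(pool, 9L)), , drop = FALSE]
  k <- min(if (!is.null(spec$n_sparse)) spec$n_sparse else hyper$n_sparse,
           nrow(uniq))
  feats <- uniq[, feat_cols, drop = FALSE]
  idx <- if (hyper$sparse_method == "random") {
    with_seed(seed, sample.int(nrow(uniq), k))
  } else if (spec$kind == "soap") {
    nrm <- sqrt(rowSums(feats^2))
    cur_select(feats / pmax(nrm, 1e-300), k, seed)
  } else if (spec$kind == "two_body") {
    ## leverage scores degenerate in 1-d: cover the distance range with
    ## evenly spaced quantiles instead (deterministic)
    ord <- order(feats[, 1L], seq_len(nrow(feats)))
    unique(ord[round(seq(1L, length(ord), length.out = k))])
  } else {
    ## 3-body: seeded k-means coverage of (r1, r2, cos), mapped back to the
    ## nearest actual features
    if (k >= nrow(feats)) {
      seq_len(nrow(feats))
    } else {
      sc <- scale(feats)
      sc[, !is.finite(colSums(sc))] <- 0
      centres <- with_seed(seed, {
        tryCatch(stats::kmeans(sc, centers = k, iter.max = 50L,
                               nstart = 1L)$centers,
                 error = function(e) sc[sample.int(nrow(sc), k), , drop = FALSE])
      })
      unique(apply(centres, 1L, function(ct) {
        which.min(colSums((t(sc) - ct)^2))
      }))
    }
  }
  sel <- uniq[idx, , drop = FALSE]
  if (spec$kind == "soap") {
    nrm <- sqrt(rowSums(sel^2))
    list(Phat = sel / pmax(nrm, 1e-300))
  } else if (spec$kind == "two_body") {
    list(r = sel[, 1L], w = sel[, 2L])
  } else {
    list(feat = sel[, 1:3, drop = FALSE], w = sel[, 4L])
  }
}

n_sparse_of <- function(sp, kind) {
  switch(kind, soap = nrow(sp$Phat), two_body = length(sp$r),
         three_body = nrow(sp$feat))
}

## Kernel rows of one configuration against one spec's sparse set.
## Returns K (n_centres x n_s), J (3N x n_s, if grad), kself, centers.
kernel_rows <- function(cfg, spec, sp, grad) {
  a <- cpp_args(cfg, spec)
  if (spec$kind == "soap") {
    out <- cpp_kernel_soap(cfg$positions, a$zcode, a$mask, a$Ldiag, a$pbc,
                           spec$r_c, spec$sigma_atom, spec$n_max, spec$l_max,
                           length(a$elements), sp$Phat, spec$zeta, grad)
    out$kself <- rep(1, nrow(out$K))
    out
  } else if (spec$kind == "two_body") {
    cpp_kernel_2b(cfg$positions, a$zcode, a$mask, a$nbr, a$group, a$Ldiag,
                  a$pbc, spec$r_c, spec$sigma_atom, sp$r, sp$w, grad)
  } else {
    cpp_kernel_3b(cfg$positions, a$zcode, a$mask, a$nbr, a$group, a$Ldiag,
                  a$pbc, spec$r_c, spec$sigma_atom, spec$theta_cos, sp$feat,
                  sp$w, grad)
  }
}

## K_mm between sparse points of one spec.
sparse_gram <- function(spec, sp) {
  if (spec$kind == "soap") {
    d <- sp$Phat %*% t(sp$Phat)
    d * abs(d)^(spec$zeta - 1)
  } else if (spec$kind == "two_body") {
    th2 <- 2 * spec$sigma_atom^2
    outer(sp$w, sp$w) * exp(-outer(sp$r, sp$r, "-")^2 / th2)
  } else {
    th2 <- 2 * spec$sigma_atom^2
    tc2 <- 2 * spec$theta_cos^2
    f <- sp$feat
    e1 <- exp(-(outer(f[, 1], f[, 1], "-")^2 + outer(f[, 2], f[, 2], "-")^2) / th2 -
                outer(f[, 3], f[, 3], "-")^2 / tc2)
    e2 <- exp(-(outer(f[, 1], f[, 2], "-")^2 + outer(f[, 2], f[, 1], "-")^2) / th2 -
                outer(f[, 3], f[, 3], "-")^2 / tc2)
    outer(sp$w, sp$w) * 0.5 * (e1 + e2)
  }
}

## invert a PSD gram matrix, escalating the jitter if needed
safe_gram_inverse <- function(G, jitter) {
  G <- as.matrix(G)
  jit <- jitter * max(diag(G), 1)
  for (try in 1:6) {
    ch <- tryCatch(chol(G + diag(jit, nrow(G))), error = function(e) NULL)
    if (!is.null(ch)) return(chol2inv(ch))
    jit <- jit * 100
  }
  stop(sprintf("gram matrix numerically singular (%d x %d, diag [%g, %g], finite: %s)",
               nrow(G), ncol(G), min(diag(G)), max(diag(G)),
               all(is.finite(G))))
}

element_counts <- function(set, elements) {
  t(vapply(unclass(set), function(cfg) {
    vapply(elements, function(e) sum(cfg$species == e), numeric(1))
  }, numeric(length(elements))))
}

fit_e0 <- function(set, elements) {
  X <- element_counts(set, elements)
  y <- vapply(unclass(set), function(cfg) cfg$energy, numeric(1))
  A <- crossprod(X) + diag(1e-8, ncol(X))
  e0 <- drop(solve(A, crossprod(X, y)))
  names(e0) <- elements
  e0
}

#' Fit a sparse GP potential to labelled configurations
#'
#' @param train a `configuration_set`; every configuration must carry an
#'   energy, forces are used where present.
#' @param specs list of `descriptor_spec`s (their contributions add).
#' @param hyper a `hyper_params`.
#' @param seed integer seed controlling sparse-point selection.
#' @return an object of class `gp_model`.
#' @export
gp_fit <- function(train, specs, hyper = hyper_params(), seed = 0L) {
  train <- configuration_set(train)
  if (length(train) == 0L) stop("empty training set")
  if (inherits(specs, "descriptor_spec")) specs <- list(specs)
  energies <- lapply(unclass(train), function(cfg) cfg$energy)
  if (any(vapply(energies, is.null, logical(1)))) {
    stop("every training configuration must carry an energy label")
  }
  elements <- sort(unique(unlist(lapply(unclass(train), function(c) c$species))))
  specs <- lapply(specs, function(s) { s$elements <- elements; s })

  e0 <- if (identical(hyper$e0_mode, "zero")) {
    stats::setNames(numeric(length(elements)), elements)
  } else {
    fit_e0(train, elements)
  }

  ## descriptors without a single environment in the training data (e.g. a
  ## pair channel whose distances all exceed the cutoff) are dropped
  pools <- lapply(specs, function(sp) pool_environments(train, sp))
  keep <- !vapply(pools, is.null, logical(1))
  if (!any(keep)) {
    stop("no environments found for any descriptor; check centre species and cutoffs")
  }
  specs <- specs[keep]
  pools <- pools[keep]
  sparse <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    sparse[[k]] <- select_sparse(pools[[k]], specs[[k]], hyper, seed + k)
  }
  ns <- vapply(seq_along(specs), function(k) n_sparse_of(sparse[[k]], specs[[k]]$kind),
               numeric(1))
  offs <- c(0, cumsum(ns))
  ntot <- sum(ns)

  ## design rows
  phi_rows <- list(); yv <- c(); wv <- c()
  for (ci in seq_along(unclass(train))) {
    cfg <- train[[ci]]
    n <- n_atoms(cfg)
    has_f <- !is.null(cfg$forces)
    erow <- numeric(ntot)
    frows <- if (has_f) matrix(0, 3 * n, ntot) else NULL
    for (k in seq_along(specs)) {
      kr <- kernel_rows(cfg, specs[[k]], sparse[[k]], has_f)
      cols <- (offs[k] + 1):offs[k + 1]
      erow[cols] <- colSums(kr$K)
      if (has_f) frows[, cols] <- -kr$J
    }
    phi_rows[[length(phi_rows) + 1L]] <- rbind(erow, frows)
    resid <- cfg$energy - sum(e0[cfg$species])
    yv <- c(yv, resid, if (has_f) as.vector(t(cfg$forces)))
    wv <- c(wv, 1 / (hyper$sigma_E * n)^2,
            if (has_f) rep(1 / hyper$sigma_F^2, 3 * n))
  }
  Phi <- do.call(rbind, phi_rows)

  ## the per-spec signal amplitude delta scales the prior variance; in the
  ## weight-space normal equations it appears as K_mm / delta^2
  Kmm <- matrix(0, ntot, ntot)
  for (k in seq_along(specs)) {
    cols <- (offs[k] + 1):offs[k + 1]
    Kmm[cols, cols] <- sparse_gram(specs[[k]], sparse[[k]]) / specs[[k]]$delta^2
  }

  ## solve min ||sqrt(W)(Phi w - y)||^2 + w' (Kmm + jitter I) w in square-root
  ## form via QR: numerically far better conditioned than normal equations.
  ## The symmetric square root of Kmm comes from an eigendecomposition
  ## (roundoff-negative eigenvalues clipped), the jitter from explicit
  ## ridge rows.
  eg <- eigen(Kmm, symmetric = TRUE)
  U <- diag(sqrt(pmax(eg$values, 0)), ntot) %*% t(eg$vectors)
  jit <- hyper$jitter * max(diag(Kmm), 1)
  aug <- rbind(Phi * sqrt(wv), U, diag(sqrt(jit), ntot))
  rhs <- c(sqrt(wv) * yv, numeric(2L * ntot))
  w <- tryCatch(drop(qr.coef(qr(aug, LAPACK = TRUE), rhs)),
                error = function(e) {
    stop(sprintf("normal equations singular after jitter (condition ~ %.3g)",
                 kappa(aug)))
  })
  w[!is.finite(w)] <- 0

  ## variance factor: (K_mm + jitter I)^-1 per spec (unit-amplitude kernel)
  var_inv <- lapply(seq_along(specs), function(k) {
    cols <- (offs[k] + 1):offs[k + 1]
    safe_gram_inverse(Kmm[cols, cols, drop = FALSE] * specs[[k]]$delta^2,
                      hyper$jitter)
  })

  tags <- unique(unlist(lapply(unclass(train), function(c) c$level_tag)))
  structure(list(specs = specs, sparse = sparse, weights = w, offsets = offs,
                 e0 = e0, hyper = hyper, var_inv = var_inv,
                 level_tag = if (length(tags)) tags[1L] else "unlabelled",
                 train_set = train, seed = seed, elements = elements,
                 schema_version = 1L),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("<gp_model> level=%s, %d training configs, %d weights, specs: %s\n",
              x$level_tag, length(x$train_set), length(x$weights),
              paste(vapply(x$specs, function(s) s$kind, ""), collapse = "+")))
  invisible(x)
}

gp_eval <- function(model, cfg, forces = TRUE) {
  n <- n_atoms(cfg)
  unknown <- setdiff(unique(cfg$species), model$elements)
  if (length(unknown)) stop("unknown element(s) for this model: ",
                            paste(unknown, collapse = ", "))
  energy <- sum(model$e0[cfg$species])
  f <- if (forces) matrix(0, n, 3L) else NULL
  for (k in seq_along(model$specs)) {
    spec <- model$specs[[k]]
    cols <- (model$offsets[k] + 1):model$offsets[k + 1]
    w <- model$weights[cols]
    if (spec$kind == "soap") {
      a <- cpp_args(cfg, spec)
      out <- cpp_soap_energy_forces(cfg$positions, a$zcode, a$mask, a$Ldiag,
                                    a$pbc, spec$r_c, spec$sigma_atom,
                                    spec$n_max, spec$l_max, length(a$elements),
                                    model$sparse[[k]]$Phat, w, spec$zeta, forces)
      energy <- energy + out$energy
      if (forces) f <- f + out$forces
    } else {
      kr <- kernel_rows(cfg, spec, model$sparse[[k]], forces)
      energy <- energy + sum(kr$K %*% w)
      if (forces) {
        f <- f - t(matrix(drop(kr$J %*% w), nrow = 3L))
      }
    }
  }
  list(energy = energy, forces = f)
}

#' Predict the total energy of a configuration
#'
#' @param model a `gp_model`.
#' @param cfg a `configuration`.
#' @return energy in eV.
#' @export
predict_energy <- function(model, cfg) {
  evaluate_potential(model, cfg, forces = FALSE)$energy
}

#' Predict forces on every atom
#'
#' Consistent with [predict_energy()]: matches central finite differences of
#' the predicted energy to <= 1e-3 eV/A at h = 1e-4 A.
#'
#' @param model a `gp_model`.
#' @param cfg a `configuration`.
#' @return N x 3 matrix, eV/A.
#' @export
predict_forces <- function(model, cfg) {
  evaluate_potential(model, cfg, forces = TRUE)$forces
}

#' Per-atom GP predictive variance of the local energy
#'
#' For each centre atom, `k(x,x) - k_xm (K_mm + jitter I)^-1 k_mx`: the
#' variance of its local-energy contribution conditional on the sparse
#' environments. Zero (up to jitter) for an environment identical to a sparse
#' environment; approaches the prior `k(x,x)` far from all of them. Atoms
#' that are not centres of any descriptor report 0.
#'
#' @param model a `gp_model`.
#' @param cfg a `configuration`.
#' @return numeric vector of length N, eV^2.
#' @export
predict_atom_variance <- function(model, cfg) {
  v <- numeric(n_atoms(cfg))
  for (k in seq_along(model$specs)) {
    kr <- kernel_rows(cfg, model$specs[[k]], model$sparse[[k]], grad = FALSE)
    if (nrow(kr$K) == 0L) next
    Vi <- model$var_inv[[k]]
    red <- rowSums((kr$K %*% Vi) * kr$K)
    vi <- model$specs[[k]]$delta^2 * pmax(0, kr$kself - red)
    v[kr$centers + 1L] <- v[kr$centers + 1L] + vi
  }
  v
}

#' Refit a model with every retained training configuration relabelled
#'
#' Re-evaluates energies and forces of the retained training set with
#' `new_truth` and refits with the same descriptors, hyperparameters and
#' seed ("uplifting" to a new level of theory). Any evaluator failure aborts
#' before refitting, so no partial model can result.
#'
#' @param model a `gp_model` (retains its training set).
#' @param new_truth a `ground_truth`.
#' @return a new `gp_model` tagged with the new level.
#' @export
uplift <- function(model, new_truth) {
  relabelled <- lapply(unclass(model$train_set), function(cfg) {
    gt_label(new_truth, cfg)
  })
  gp_fit(configuration_set(relabelled), model$specs, model$hyper, model$seed)
}

## ---------------------------------------------------------------------------
## Serialisation: a single self-describing JSON archive (versioned schema).

.GP_SCHEMA <- 1L

config_to_list <- function(cfg) {
  Filter(Negate(is.null), list(
    species = cfg$species, positions = cfg$positions, cell = cfg$cell,
    pbc = cfg$pbc, energy = cfg$energy, forces = cfg$forces,
    velocities = cfg$velocities, partition = cfg$partition,
    level_tag = cfg$level_tag))
}

config_from_list <- function(x) {
  mat <- function(m) if (is.null(m)) NULL else matrix(unlist(m), ncol = 3L, byrow = FALSE)
  configuration(species = unlist(x$species),
                positions = matrix(unlist(x$positions), ncol = 3L),
                cell = if (!is.null(x$cell)) matrix(unlist(x$cell), 3L, 3L) else NULL,
                pbc = unlist(x$pbc),
                energy = x$energy,
                forces = if (!is.null(x$forces)) matrix(unlist(x$forces), ncol = 3L) else NULL,
                velocities = if (!is.null(x$velocities)) matrix(unlist(x$velocities), ncol = 3L) else NULL,
                partition = if (!is.null(x$partition)) lapply(x$partition, unlist) else NULL,
                level_tag = if (!is.null(x$level_tag)) x$level_tag else NULL)
}

model_to_list <- function(model) {
  list(schema_version = .GP_SCHEMA, class = "gp_model",
       specs = lapply(model$specs, unclass),
       sparse = model$sparse, weights = model$weights,
       offsets = model$offsets, e0 = as.list(model$e0),
       hyper = unclass(model$hyper), level_tag = model$level_tag,
       seed = model$seed, elements = model$elements,
       train_set = lapply(unclass(model$train_set), config_to_list))
}

#' Save a fitted model to a self-describing JSON archive
#'
#' @param model a `gp_model`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, digits = I(17),
                       auto_unbox = TRUE, matrix = "columnmajor")
  invisible(path)
}

#' Load a model archive written by [save_model()]
#'
#' Rejects archives whose schema version does not match.
#'
#' @param path archive path.
#' @return a `gp_model`.
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$schema_version) || raw$schema_version != .GP_SCHEMA) {
    stop("model archive schema version mismatch (expected ", .GP_SCHEMA, ")")
  }
  model_from_list(raw)
}

model_from_list <- function(raw) {
  if (!identical(raw$class, "gp_model")) stop("archive does not hold a gp_model")
  specs <- lapply(raw$specs, function(s) {
    descriptor_spec(kind = s$kind, center_species = unlist(s$center_species),
                    r_c = s$r_c, sigma_atom = s$sigma_atom, n_max = s$n_max,
                    l_max = s$l_max, zeta = s$zeta, theta_cos = s$theta_cos,
                    delta = if (is.null(s$delta)) 1 else s$delta,
                    neighbor_species = if (!is.null(s$neighbor_species))
                      unlist(s$neighbor_species),
                    intermolecular = isTRUE(s$intermolecular),
                    n_sparse = s$n_sparse,
                    elements = unlist(s$elements))
  })
  sparse <- lapply(raw$sparse, function(sp) {
    out <- list()
    if (!is.null(sp$Phat)) {
      out$Phat <- do.call(cbind, lapply(sp$Phat, unlist))
    }
    if (!is.null(sp$r)) { out$r <- unlist(sp$r); out$w <- unlist(sp$w) }
    if (!is.null(sp$feat)) {
      out$feat <- do.call(cbind, lapply(sp$feat, unlist))
      out$w <- unlist(sp$w)
    }
    out
  })
  hy <- raw$hyper
  hyper <- hyper_params(sigma_E = hy$sigma_E, sigma_F = hy$sigma_F,
                        n_sparse = hy$n_sparse, sparse_method = hy$sparse_method,
                        jitter = hy$jitter,
                        e0_mode = if (is.null(hy$e0_mode)) "fit" else hy$e0_mode)
  train <- configuration_set(lapply(raw$train_set, config_from_list))
  offsets <- unlist(raw$offsets)
  var_inv <- lapply(seq_along(specs), function(k) {
    safe_gram_inverse(sparse_gram(specs[[k]], sparse[[k]]), hyper$jitter)
  })
  structure(list(specs = specs, sparse = sparse,
                 weights = unlist(raw$weights), offsets = offsets,
                 e0 = stats::setNames(unlist(raw$e0), names(raw$e0)),
                 hyper = hyper, var_inv = var_inv, level_tag = raw$level_tag,
                 train_set = train, seed = raw$seed,
                 elements = unlist(raw$elements),
                 schema_version = raw$schema_version),
            class = "gp_model")
}
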