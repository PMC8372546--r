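## Atomic-environment descriptors and CUR subset selection.

#' Describe an atomic-environment descriptor
#'
#' @param kind one of `"two_body"`, `"three_body"`, `"soap"`.
#' @param center_species element symbols whose atoms act as centres.
#' @param neighbor_species element symbols counted as neighbours for the
#'   2-/3-body descriptors (`NULL` = all; SOAP always sees every atom).
#' @param intermolecular if `TRUE`, 2-/3-body neighbours are restricted to
#'   atoms of a different molecule (the configuration's partition, inferred
#'   when absent) — the natural pair basis for an intermolecular model.
#' @param r_c radial cutoff, Angstrom.
#' @param sigma_atom Gaussian smoothness, Angstrom (also the
#'   squared-exponential length scale of the 2-/3-body kernels).
#' @param n_max radial basis size (soap).
#' @param l_max angular band limit (soap).
#' @param zeta kernel exponent (soap dot-product kernel).
#' @param theta_cos length scale on the cosine dimension of the 3-body kernel.
#' @param delta signal amplitude (energy scale of one local contribution), eV;
#'   scales the GP prior variance of this descriptor's term.
#' @param n_sparse per-descriptor override of the sparse-point count
#'   (`NULL`: use the fit-level `hyper_params` value).
#' @param elements global element set fixing the descriptor width; defaults to
#'   the elements seen at fit time.
#' @return an object of class `descriptor_spec`.
#' @export
descriptor_spec <- function(kind = c("soap", "two_body", "three_body"),
                            center_species, r_c, sigma_atom = 0.5,
                            n_max = 6L, l_max = 4L, zeta = 4,
                            theta_cos = 0.5, delta = 1,
                            neighbor_species = NULL, intermolecular = FALSE,
                            n_sparse = NULL, elements = NULL) {
  kind <- match.arg(kind)
  stopifnot(r_c > 0, sigma_atom > 0, n_max >= 1L, l_max >= 0L, zeta >= 1,
            delta > 0)
  structure(list(kind = kind, center_species = as.character(center_species),
                 r_c = r_c, sigma_atom = sigma_atom, n_max = as.integer(n_max),
                 l_max = as.integer(l_max), zeta = zeta, theta_cos = theta_cos,
                 delta = delta,
                 neighbor_species = if (!is.null(neighbor_species))
                   as.character(neighbor_species),
                 intermolecular = isTRUE(intermolecular),
                 n_sparse = if (!is.null(n_sparse)) as.integer(n_sparse),
                 elements = if (!is.null(elements)) sort(unique(elements)) else NULL),
            class = "descriptor_spec")
}

#' @export
print.descriptor_spec <- function(x, ...) {
  cat(sprintf("<descriptor_spec> %s centres=%s r_c=%.2f A\n", x$kind,
              paste(x$center_species, collapse = ","), x$r_c))
  invisible(x)
}

spec_elements <- function(spec, cfg) {
  if (!is.null(spec$elements)) {
    unknown <- setdiff(unique(cfg$species), spec$elements)
    if (length(unknown)) {
      stop("configuration contains element(s) outside the model's element set: ",
           paste(unknown, collapse = ", "))
    }
    spec$elements
  } else {
    sort(unique(cfg$species))
  }
}

## Shared argument preparation for the compiled kernels. Asserts the
## minimum-image safe regime (orthorhombic, r_c < half the shortest box edge).
cpp_args <- function(cfg, spec) {
  elements <- spec_elements(spec, cfg)
  if (any(cfg$pbc)) {
    L <- assert_orthorhombic(cfg$cell)
    if (spec$r_c >= min(L[cfg$pbc]) / 2) {
      stop(sprintf(
        "periodic cell too small for cutoff: r_c=%.3f must be < %.3f (half the shortest periodic edge)",
        spec$r_c, min(L[cfg$pbc]) / 2))
    }
    Ldiag <- L
  } else {
    Ldiag <- c(1, 1, 1)
  }
  group <- rep(-1L, n_atoms(cfg))
  if (isTRUE(spec$intermolecular)) {
    part <- cfg$partition
    if (is.null(part)) part <- infer_molecules(cfg)
    for (g in seq_along(part)) group[part[[g]]] <- g - 1L
  }
  list(zcode = match(cfg$species, elements) - 1L,
       mask = cfg$species %in% spec$center_species,
       nbr = if (is.null(spec$neighbor_species)) rep(TRUE, n_atoms(cfg))
             else cfg$species %in% spec$neighbor_species,
       group = group,
       Ldiag = Ldiag, pbc = cfg$pbc, elements = elements)
}

soap_width <- function(spec, n_elements) {
  M <- n_elements * spec$n_max
  as.integer(M * (M + 1) / 2 * (spec$l_max + 1))
}

#' SOAP-style power-spectrum descriptors for a configuration
#'
#' One vector per atom of a centre species; the neighbourhood comprises all
#' atoms of any element (including hydrogen) within `r_c` under the minimum
#' image convention. The vector is the species-resolved power spectrum of a
#' Gaussian neighbour density in a radial x angular basis truncated at
#' `(n_max, l_max)` with a smooth radial cutoff; it is invariant to rotation
#' and to permutation of like atoms.
#'
#' @param cfg a `configuration`.
#' @param spec a `descriptor_spec` with `kind = "soap"`.
#' @return object of class `environment_vectors`: list with `values`
#'   (matrix, one row per centre), `center_atom` (1-based indices) and
#'   `center_element`.
#' @export
soap_descriptor <- function(cfg, spec) {
  stopifnot(spec$kind == "soap")
  a <- cpp_args(cfg, spec)
  out <- cpp_soap_vectors(cfg$positions, a$zcode, a$mask, a$Ldiag, a$pbc,
                          spec$r_c, spec$sigma_atom, spec$n_max, spec$l_max,
                          length(a$elements))
  centers <- out$centers + 1L
  structure(list(values = out$P, center_atom = centers,
                 center_element = cfg$species[centers],
                 elements = a$elements),
            class = "environment_vectors")
}

#' Two-body (pair distance) features
#'
#' All centre-neighbour pairs with `r < r_c`; the weight is the smooth cutoff
#' value `f_c(r) = (cos(pi r / r_c) + 1)/2`, which vanishes at `r_c`.
#'
#' @param cfg a `configuration`.
#' @param spec a `descriptor_spec` with `kind = "two_body"`.
#' @return data.frame with columns `center`, `neighbour` (1-based), `r` (A)
#'   and `w`.
#' @export
two_body_features <- function(cfg, spec) {
  stopifnot(spec$kind == "two_body")
  a <- cpp_args(cfg, spec)
  out <- cpp_two_body_features(cfg$positions, a$zcode, a$mask, a$nbr,
                               a$group, a$Ldiag, a$pbc, spec$r_c)
  data.frame(center = out$center + 1L, neighbour = out$neighbour + 1L,
             r = out$r, w = out$w)
}

#' Three-body (two distances and an angle) features
#'
#' All unordered neighbour pairs within `r_c` of a centre, symmetrised so
#' `(r1, r2, cos)` is reported with `r1 <= r2`; weight `f_c(r1) f_c(r2)`.
#'
#' @param cfg a `configuration`.
#' @param spec a `descriptor_spec` with `kind = "three_body"`.
#' @return data.frame with columns `center`, `n1`, `n2`, `r1`, `r2`,
#'   `cos_theta`, `w`.
#' @export
three_body_features <- function(cfg, spec) {
  stopifnot(spec$kind == "three_body")
  a <- cpp_args(cfg, spec)
  out <- cpp_three_body_features(cfg$positions, a$zcode, a$mask, a$nbr,
                                 a$group, a$Ldiag, a$pbc, spec$r_c)
  data.frame(center = out$center + 1L, n1 = out$n1 + 1L, n2 = out$n2 + 1L,
             r1 = out$r1, r2 = out$r2, cos_theta = out$cos, w = out$w)
}

#' Average per-atom descriptors into one configuration-level vector
#'
#' Entrywise arithmetic mean over atoms ("inner" averaging over entries of the
#' expansion-coefficient vector).
#'
#' @param vectors an `environment_vectors` object or a numeric matrix with one
#'   row per atom.
#' @return numeric vector.
#' @export
average_descriptor <- function(vectors) {
  m <- if (inherits(vectors, "environment_vectors")) vectors$values else as.matrix(vectors)
  if (nrow(m) == 0L) stop("cannot average an empty descriptor list")
  colMeans(m)
}

#' CUR row selection by statistical leverage scores
#'
#' Selects `k` distinct rows of `x` with the largest leverage scores computed
#' from the top `min(k, rank)` singular directions; ties broken by lowest row
#' index, so the choice is deterministic. A zero matrix falls back to a
#' seeded uniform random choice.
#'
#' @param x numeric matrix (rows = candidates, e.g. per-configuration averaged
#'   descriptors).
#' @param k number of rows to select.
#' @param seed integer seed (used only for the zero-matrix fallback).
#' @return integer vector of `k` distinct 1-based row indices.
#' @export
cur_select <- function(x, k, seed = 0L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 1L) stop("matrix must have at least one row")
  if (k > n) stop("cannot select more rows than the matrix has")
  if (k == n) return(seq_len(n))
  if (all(x == 0)) {
    return(with_seed(seed, sample.int(n, k)))
  }
  lev <- cur_leverage_scores(x, k)
  order(-lev, seq_len(n))[seq_len(k)]
}

#' Leverage scores used by [cur_select()]
#'
#' @param x numeric matrix.
#' @param k target selection size (caps the number of singular directions).
#' @return numeric vector of per-row leverage scores.
#' @export
cur_leverage_scores <- function(x, k) {
  s <- svd(x)
  tol <- max(dim(x)) * .Machine$double.eps * max(s$d, 0)
  rank <- sum(s$d > tol)
  r <- max(1L, min(k, rank))
  rowSums(s$u[, seq_len(r), drop = FALSE]^2)
}

## Evaluate a deterministic expression under a local RNG seed.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Select diverse configurations via CUR on averaged descriptors
#'
#' Computes the per-configuration average of per-atom SOAP vectors and applies
#' [cur_select()] to the resulting matrix.
#'
#' @param set a `configuration_set`.
#' @param spec a soap `descriptor_spec`.
#' @param k number of configurations to keep.
#' @param seed integer seed.
#' @return integer indices into `set`.
#' @export
select_diverse_configurations <- function(set, spec, k, seed = 0L) {
  mats <- lapply(unclass(set), function(cfg) {
    average_descriptor(soap_descriptor(cfg, spec))
  })
  cur_select(do.call(rbind, mats), k, seed)
}
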