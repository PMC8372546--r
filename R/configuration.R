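## Atomic configurations, configuration sets and trajectories.
##
## A `configuration` is a plain list with class "configuration":
##   species    character(N) element symbols
##   positions  N x 3 matrix, Cartesian, A
##   cell       3 x 3 matrix of lattice row vectors, A (or NULL)
##   pbc        logical(3) per-axis periodicity
##   energy     total energy, eV (or NULL)
##   forces     N x 3 matrix, eV/A (or NULL)
##   velocities N x 3 matrix, A/fs (or NULL)
##   partition  list of disjoint integer vectors (1-based atom groups) or NULL
##   level_tag  free-text label of the ground-truth level (or NULL)
##   info       named list of extra per-frame metadata

#' Create an atomic configuration
#'
#' @param species character vector of element symbols (length N).
#' @param positions N x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @param cell 3 x 3 matrix of lattice vectors (rows), Angstrom, or `NULL`.
#' @param pbc logical vector of length 3 (or a single logical, recycled).
#' @param energy total energy in eV, or `NULL`.
#' @param forces N x 3 matrix in eV/Angstrom, or `NULL`.
#' @param velocities N x 3 matrix in Angstrom/fs, or `NULL`.
#' @param partition list of disjoint 1-based atom-index groups, or `NULL`.
#' @param level_tag free-text label of the ground truth that produced
#'   `energy`/`forces`, or `NULL`.
#' @param info named list of additional metadata.
#' @return an object of class `configuration`.
#' @export
configuration <- function(species, positions, cell = NULL, pbc = FALSE,
                          energy = NULL, forces = NULL, velocities = NULL,
                          partition = NULL, level_tag = NULL, info = list()) {
  positions <- as_n3_matrix(positions, "positions")
  if (length(pbc) == 1L) pbc <- rep(as.logical(pbc), 3L)
  cfg <- structure(list(
    species = as.character(species), positions = positions,
    cell = if (!is.null(cell)) matrix(as.numeric(cell), 3L, 3L) else NULL,
    pbc = as.logical(pbc),
    energy = if (!is.null(energy)) as.numeric(energy)[1L] else NULL,
    forces = if (!is.null(forces)) as_n3_matrix(forces, "forces") else NULL,
    velocities = if (!is.null(velocities)) as_n3_matrix(velocities, "velocities") else NULL,
    partition = partition, level_tag = level_tag, info = info
  ), class = "configuration")
  validate_configuration(cfg)
  cfg
}

as_n3_matrix <- function(x, what) {
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L) stop(what, " must have 3 columns")
    x <- matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop(what, " must have 3 columns")
  dimnames(x) <- NULL
  x
}

validate_configuration <- function(cfg) {
  n <- length(cfg$species)
  if (n < 1L) stop("configuration must contain at least one atom")
  if (!all(is_element_symbol(cfg$species))) {
    stop("unknown element symbol(s): ",
         paste(unique(cfg$species[!is_element_symbol(cfg$species)]), collapse = ", "))
  }
  if (nrow(cfg$positions) != n) stop("positions must have one row per atom")
  if (!all(is.finite(cfg$positions))) stop("positions must be finite")
  for (fld in c("forces", "velocities")) {
    m <- cfg[[fld]]
    if (!is.null(m)) {
      if (nrow(m) != n) stop(fld, " must have one row per atom")
      if (!all(is.finite(m))) stop(fld, " must be finite")
    }
  }
  if (any(cfg$pbc)) {
    if (is.null(cfg$cell)) stop("periodic configuration requires a cell")
    if (abs(det(cfg$cell)) <= 0) stop("cell must have strictly positive volume")
  }
  if (!is.null(cfg$partition)) {
    idx <- unlist(cfg$partition)
    if (length(idx) != length(unique(idx))) stop("partition groups must be disjoint")
    if (any(idx < 1L | idx > n)) stop("partition indices out of range")
  }
  invisible(cfg)
}

#' Number of atoms in a configuration
#' @param cfg a `configuration`.
#' @return integer atom count.
#' @export
n_atoms <- function(cfg) length(cfg$species)

#' @export
print.configuration <- function(x, ...) {
  comp <- table(x$species)
  cat(sprintf("<configuration> %d atoms (%s)%s%s\n", n_atoms(x),
              paste(sprintf("%s%d", names(comp), comp), collapse = " "),
              if (any(x$pbc)) " periodic" else "",
              if (!is.null(x$energy)) sprintf(" E=%.6f eV", x$energy) else ""))
  invisible(x)
}

#' Create an ordered set of configurations
#'
#' @param configs list of `configuration` objects (duplicates permitted).
#' @return an object of class `configuration_set` (order-preserving).
#' @export
configuration_set <- function(configs = list()) {
  if (inherits(configs, "configuration")) configs <- list(configs)
  stopifnot(all(vapply(configs, inherits, logical(1), "configuration")))
  structure(configs, class = "configuration_set")
}

#' @export
length.configuration_set <- function(x) length(unclass(x))

#' @export
`[.configuration_set` <- function(x, i) configuration_set(unclass(x)[i])

#' @export
c.configuration_set <- function(...) {
  parts <- lapply(list(...), function(p) {
    if (inherits(p, "configuration")) list(p) else unclass(p)
  })
  configuration_set(do.call(c, parts))
}

#' @export
print.configuration_set <- function(x, ...) {
  cat(sprintf("<configuration_set> %d frames\n", length(x)))
  invisible(x)
}

#' Create a trajectory (frames plus times)
#'
#' @param frames a `configuration_set`.
#' @param times numeric vector of times in fs, strictly increasing,
#'   one per frame.
#' @param unstable flag set when MD aborted on non-finite energies/forces.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(frames, times, unstable = FALSE) {
  frames <- configuration_set(frames)
  times <- as.numeric(times)
  stopifnot(length(times) == length(frames))
  if (length(times)) {
    if (times[1L] < 0) stop("times must start at >= 0")
    if (length(times) > 1L && any(diff(times) <= 0)) {
      stop("times must be strictly increasing")
    }
  }
  structure(list(frames = frames, times = times, unstable = unstable),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %.1f fs%s\n", length(x$frames),
              if (length(x$times)) max(x$times) else 0,
              if (isTRUE(x$unstable)) " [unstable]" else ""))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Minimum image convention (orthorhombic cells only; asserted, not truncated)

assert_orthorhombic <- function(cell) {
  off <- cell; diag(off) <- 0
  if (max(abs(off)) > 1e-9 * max(abs(diag(cell)))) {
    stop("minimum-image operations require an orthorhombic cell")
  }
  d <- diag(cell)
  if (any(d <= 0)) stop("cell diagonal must be positive")
  d
}

#' Shortest periodic displacement between two atoms
#'
#' Returns the displacement `r_j - r_i` minimised over periodic images
#' (minimum-image convention, exact for orthorhombic cells). Non-periodic
#' configurations return the direct displacement.
#'
#' @param cfg a `configuration`.
#' @param i,j 1-based atom indices.
#' @return numeric length-3 displacement vector in Angstrom.
#' @export
minimum_image_displacement <- function(cfg, i, j) {
  n <- n_atoms(cfg)
  if (i < 1L || i > n || j < 1L || j > n) stop("atom index out of range")
  d <- cfg$positions[j, ] - cfg$positions[i, ]
  if (any(cfg$pbc)) {
    L <- assert_orthorhombic(cfg$cell)
    w <- which(cfg$pbc)
    d[w] <- d[w] - L[w] * round(d[w] / L[w])
  }
  d
}
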