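## Configuration generation (random packed boxes, monomer grids) and the
## episode-scheduled active-learning loop.

#' Gas-phase water molecule template
#'
#' @param r O-H bond length, A.
#' @param theta H-O-H angle, rad.
#' @return a 3-atom `configuration` (O, H, H).
#' @export
water_template <- function(r = 0.96, theta = 1.824) {
  configuration(species = c("O", "H", "H"),
                positions = rbind(c(0, 0, 0),
                                  c(r, 0, 0),
                                  c(r * cos(theta), r * sin(theta), 0)),
                partition = list(1:3))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Randomly pack molecules into a periodic cubic box
#'
#' Molecules are placed with random rigid rotations and positions, rejecting
#' placements with any intermolecular atom-pair (minimum-image) distance below
#' `min_dist`. Deterministic given the seed.
#'
#' @param templates list of molecule `configuration`s (gas-phase geometries).
#' @param counts integer copies of each template.
#' @param box cubic box edge, A.
#' @param min_dist minimum intermolecular atom-pair distance, A.
#' @param seed integer seed.
#' @param max_attempts per-molecule rejection budget.
#' @return a periodic `configuration` with the molecular `partition` set.
#' @export
random_packed_configuration <- function(templates, counts, box,
                                        min_dist = 1.7, seed = 0L,
                                        max_attempts = 2000L) {
  if (inherits(templates, "configuration")) templates <- list(templates)
  stopifnot(length(counts) == length(templates), box > 0)
  with_seed(seed, {
    species <- character(0)
    pos <- matrix(0, 0L, 3L)
    partition <- list()
    cell <- diag(box, 3L)
    for (t in seq_along(templates)) {
      tmpl <- templates[[t]]
      base <- sweep(tmpl$positions, 2L, colMeans(tmpl$positions))
      for (rep in seq_len(counts[t])) {
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          Rt <- random_rotation()
          centre <- stats::runif(3) * box
          cand <- sweep(base %*% t(Rt), 2L, centre, "+")
          ok <- TRUE
          if (nrow(pos)) {
            for (i in seq_len(nrow(cand))) {
              d <- sweep(pos, 2L, cand[i, ], "-")
              d <- d - box * round(d / box)
              if (any(rowSums(d * d) < min_dist^2)) { ok <- FALSE; break }
            }
          }
          if (ok) {
            partition[[length(partition) + 1L]] <-
              nrow(pos) + seq_len(nrow(cand))
            species <- c(species, tmpl$species)
            pos <- rbind(pos, cand)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop(sprintf(paste0("failed to pack molecule %d/%d after %d attempts; ",
                              "reduce counts or min_dist"),
                       rep, counts[t], max_attempts))
        }
      }
    }
    configuration(species = species, positions = pos, cell = cell,
                  pbc = TRUE, partition = partition)
  })
}

#' Grid specification over the water-monomer internal coordinates
#'
#' @param r_OH1,r_OH2,r_HH length-2 lower/upper bounds, A.
#' @param n_per_dim points per dimension (endpoints included).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(r_OH1 = c(0.8, 1.5), r_OH2 = c(0.8, 1.5),
                      r_HH = c(1.0, 2.5), n_per_dim = 8L) {
  stopifnot(r_OH1[1] < r_OH1[2], r_OH2[1] < r_OH2[2], r_HH[1] < r_HH[2],
            n_per_dim >= 2L)
  structure(list(r_OH1 = r_OH1, r_OH2 = r_OH2, r_HH = r_HH,
                 n_per_dim = as.integer(n_per_dim)),
            class = "grid_spec")
}

#' Enumerate water-monomer geometries on an evenly spaced grid
#'
#' Full Cartesian product over `(r_OH1, r_OH2, r_HH)` with endpoints included
#' (`n_per_dim^3` configurations). Each geometry has O at the origin, H1 on
#' +x and H2 in the xy-plane placed by the law of cosines. Triples violating
#' the triangle inequality are flagged infeasible (`info$feasible = FALSE`)
#' but still enumerated.
#'
#' @param spec a `grid_spec`.
#' @return a `configuration_set` of `n_per_dim^3` monomers.
#' @export
grid_monomer_configurations <- function(spec = grid_spec()) {
  seqs <- lapply(list(spec$r_OH1, spec$r_OH2, spec$r_HH), function(rg) {
    seq(rg[1], rg[2], length.out = spec$n_per_dim)
  })
  grid <- expand.grid(r_OH1 = seqs[[1]], r_OH2 = seqs[[2]], r_HH = seqs[[3]],
                      KEEP.OUT.ATTRS = FALSE)
  configs <- lapply(seq_len(nrow(grid)), function(i) {
    r1 <- grid$r_OH1[i]; r2 <- grid$r_OH2[i]; rhh <- grid$r_HH[i]
    ct <- (r1^2 + r2^2 - rhh^2) / (2 * r1 * r2)
    feasible <- abs(ct) <= 1
    ctc <- max(-1, min(1, ct))
    st <- sqrt(max(0, 1 - ctc^2))
    configuration(species = c("O", "H", "H"),
                  positions = rbind(c(0, 0, 0),
                                    c(r1, 0, 0),
                                    c(r2 * ctc, r2 * st, 0)),
                  partition = list(1:3),
                  info = list(feasible = feasible,
                              r_OH1 = r1, r_OH2 = r2, r_HH = rhh))
  })
  configuration_set(configs)
}

#' Keep only geometrically feasible grid configurations
#' @param set a `configuration_set` from [grid_monomer_configurations()].
#' @return the feasible subset.
#' @export
feasible_configurations <- function(set) {
  keep <- vapply(unclass(set), function(c) !isFALSE(c$info$feasible), logical(1))
  set[keep]
}

#' Episode length of the active-learning schedule
#'
#' The exploration MD of evaluation `n` runs for `n^3 + 2` fs.
#'
#' @param n evaluation counter (>= 1).
#' @return episode length in fs.
#' @export
episode_length <- function(n) {
  if (any(n < 1)) stop("evaluation counter must be >= 1")
  n^3 + 2
}

#' Active-learning parameters
#'
#' @param strategy `"diff"` (energy-error acceptance) or `"gp_var"`
#'   (predictive-variance acceptance; the ground truth is evaluated only on
#'   acceptance).
#' @param E_add energy-error acceptance threshold, eV (default 0.043 eV,
#'   about 1 kcal/mol).
#' @param var_add variance threshold, eV^2.
#' @param T_AL exploration temperature, K.
#' @param max_truth_evals ground-truth evaluation budget.
#' @param target_time fs; active learning stops once the episode schedule
#'   reaches this much addition-free exploration.
#' @param max_energy_rise eV; a labelled frame whose reference energy exceeds
#'   the lowest training energy by more than this is discarded instead of
#'   added (guards the fit against unphysical frames from early, unstable
#'   exploration). `Inf` disables the filter.
#' @param seed integer seed.
#' @return object of class `al_params`.
#' @export
al_params <- function(strategy = c("diff", "gp_var"), E_add = 0.043,
                      var_add = 1e-4, T_AL = 300, max_truth_evals = 300L,
                      target_time = 1000, max_energy_rise = Inf, seed = 0L) {
  strategy <- match.arg(strategy)
  stopifnot(E_add > 0, var_add > 0, max_truth_evals >= 1L, target_time > 0,
            max_energy_rise > 0)
  structure(list(strategy = strategy, E_add = E_add, var_add = var_add,
                 T_AL = T_AL, max_truth_evals = as.integer(max_truth_evals),
                 target_time = target_time,
                 max_energy_rise = max_energy_rise, seed = as.integer(seed)),
            class = "al_params")
}

stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 1009 + h * 97 + 1) %% 2147483629)
}

#' Run the episode-scheduled active-learning loop
#'
#' Starting from ground-truth-labelled initial configurations, repeatedly:
#' run model MD at `al$T_AL` from the designated start configuration for
#' `episode_length(n)` fs; score the final frame (`diff`: |E0 - Emodel| with
#' a fresh truth evaluation; `gp_var`: maximum per-atom predictive variance,
#' truth evaluated only on acceptance); add the labelled frame and refit when
#' the score exceeds its threshold (resetting n to 1), otherwise increment n.
#' Stops when `episode_length(n) >= target_time` (model deemed stable) or the
#' truth budget is exhausted (history flagged unconverged).
#'
#' @param truth a `ground_truth`.
#' @param init_configs non-empty `configuration_set` of starting structures.
#' @param specs list of `descriptor_spec`s.
#' @param hyper a `hyper_params`.
#' @param md an `md_params` (temperature is overridden by `al$T_AL`).
#' @param al an `al_params`.
#' @param start the designated episode start `configuration` (default: first
#'   initial configuration).
#' @param refit function `(configuration_set, seed) -> model`; defaults to
#'   [gp_fit()] with `specs` and `hyper`. Supplying a custom refit (plus
#'   `as_potential`) embeds the loop in the intra+inter pipeline.
#' @param as_potential function mapping the fitted model to the potential
#'   that drives exploration MD (default: the model itself).
#' @return list with `model` (final fit) and `history` (an `al_history`).
#' @export
run_active_learning <- function(truth, init_configs, specs,
                                hyper = hyper_params(), md = md_params(),
                                al = al_params(), start = NULL,
                                refit = NULL, as_potential = identity) {
  init_configs <- configuration_set(init_configs)
  if (length(init_configs) == 0L) stop("init_configs must be non-empty")
  if (is.null(refit)) {
    refit <- function(set, seed) gp_fit(set, specs, hyper, seed)
  }

  train <- configuration_set(lapply(unclass(init_configs), function(cfg) {
    gt_label(truth, cfg)
  }))
  evals_used <- length(train)
  model <- refit(train, al$seed)
  if (is.null(start)) start <- init_configs[[1L]]

  records <- list()
  n <- 1L
  episode <- 0L
  converged <- FALSE

  repeat {
    if (episode_length(n) >= al$target_time) { converged <- TRUE; break }
    budget_left <- al$max_truth_evals - evals_used
    if (budget_left < 1L) break
    episode <- episode + 1L
    len_fs <- episode_length(n)
    steps <- max(1L, as.integer(round(len_fs / md$dt)))
    ep_md <- md_params(T = al$T_AL, dt = md$dt, gamma = md$gamma,
                       n_steps = steps, stride = steps,
                       seed = stage_seed(al$seed, paste0("episode", episode)))
    pot <- as_potential(model)
    res <- md_engine(pot, start, ep_md)
    frame <- res$cfg
    frame$velocities <- NULL

    e_floor <- min(vapply(unclass(train), function(c) c$energy, numeric(1)))
    usable <- function(lab) lab$energy - e_floor <= al$max_energy_rise
    added <- FALSE
    if (al$strategy == "diff") {
      labelled <- gt_label(truth, frame)
      evals_used <- evals_used + 1L
      e_model <- evaluate_potential(pot, frame, forces = FALSE)$energy
      metric <- abs(labelled$energy - e_model)
      if ((!is.finite(metric) || metric > al$E_add) && usable(labelled)) {
        train <- c(train, configuration_set(list(labelled)))
        added <- TRUE
      }
    } else {
      metric <- max(predict_atom_variance_composite(model, pot, frame))
      if (!is.finite(metric) || metric > al$var_add) {
        labelled <- gt_label(truth, frame)
        evals_used <- evals_used + 1L
        if (usable(labelled)) {
          train <- c(train, configuration_set(list(labelled)))
          added <- TRUE
        }
      }
    }
    records[[length(records) + 1L]] <- data.frame(
      episode = episode, n = n, time_fs = len_fs, metric = metric,
      added = added, unstable = res$unstable)
    if (added) {
      model <- refit(train, al$seed)
      n <- 1L
    } else {
      n <- n + 1L
    }
  }

  history <- structure(list(
    records = if (length(records)) do.call(rbind, records) else
      data.frame(episode = integer(0), n = integer(0), time_fs = numeric(0),
                 metric = numeric(0), added = logical(0), unstable = logical(0)),
    train_set = train, truth_evals_used = evals_used,
    n_init = length(init_configs), strategy = al$strategy,
    converged = converged), class = "al_history")
  list(model = model, history = history)
}

## gp_var scoring: use the model's own variance; when exploration runs under
## a composite potential the variance of the refitted (inter) model is used.
predict_atom_variance_composite <- function(model, pot, frame) {
  if (inherits(model, "gp_model")) return(predict_atom_variance(model, frame))
  if (inherits(model, "composite_potential")) {
    return(predict_atom_variance(model$inter_model, frame))
  }
  predict_atom_variance(pot, frame)
}

#' @export
print.al_history <- function(x, ...) {
  cat(sprintf(paste0("<al_history> strategy=%s, %d episodes, %d additions, ",
                     "%d truth evals%s\n"),
              x$strategy, nrow(x$records), sum(x$records$added),
              x$truth_evals_used, if (x$converged) "" else " [unconverged]"))
  invisible(x)
}

#' @export
as.data.frame.al_history <- function(x, ...) x$records

#' Write an active-learning history as CSV
#' @param history an `al_history`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history$records, path, row.names = FALSE)
  invisible(path)
}
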