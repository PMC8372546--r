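## Prospective validation: the cumulative-error metric tau_acc, on-trajectory
## error traces, radial distribution functions, parity statistics and
## learning curves.

#' Construct an error trace
#'
#' @param times fs, strictly increasing.
#' @param errors |E0 - Emodel| per evaluation, eV (non-negative, finite).
#' @return object of class `error_trace`.
#' @export
error_trace <- function(times, errors) {
  times <- as.numeric(times); errors <- as.numeric(errors)
  stopifnot(length(times) == length(errors))
  if (length(times) == 0L) stop("empty trace")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(errors)) || any(errors < 0)) {
    stop("errors must be finite and non-negative")
  }
  structure(list(times = times, errors = errors), class = "error_trace")
}

#' Default upper threshold: ten times the lower threshold
#'
#' @param E_l lower error threshold, eV (> 0).
#' @return `10 * E_l`, eV.
#' @export
default_upper_threshold <- function(E_l) {
  stopifnot(E_l > 0)
  10 * E_l
}

#' Cumulative-error time tau_acc from an error trace
#'
#' Only errors above the lower threshold `E_l` contribute to the cumulative
#' error; tau_acc is the earliest time at which the cumulative error strictly
#' exceeds `E_T`. If it never does, tau_acc is the last trace time and the
#' result is censored. `mode = "full"` accumulates the full error of each
#' contributing evaluation; `mode = "excess"` accumulates only the part above
#' `E_l`.
#'
#' @param trace an `error_trace`.
#' @param E_l lower threshold, eV.
#' @param E_T upper (total) threshold, eV; default `10 * E_l`.
#' @param mode accumulation mode.
#' @return object of class `tau_acc_result`: `tau_acc` (fs), `E_l`, `E_T`,
#'   `interval`, `trace`, `censored`, `mode`.
#' @export
tau_acc_from_trace <- function(trace, E_l, E_T = default_upper_threshold(E_l),
                               mode = c("full", "excess")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "error_trace"), E_T > E_l, E_l > 0)
  contrib <- if (mode == "full") {
    ifelse(trace$errors > E_l, trace$errors, 0)
  } else {
    pmax(trace$errors - E_l, 0) * (trace$errors > E_l)
  }
  cum <- cumsum(contrib)
  hit <- which(cum > E_T)
  censored <- length(hit) == 0L
  tau <- if (censored) trace$times[length(trace$times)] else trace$times[hit[1L]]
  dt <- diff(trace$times)
  interval <- if (length(dt) && max(abs(dt - dt[1L])) < 1e-9) dt[1L] else NA_real_
  structure(list(tau_acc = tau, E_l = E_l, E_T = E_T, interval = interval,
                 trace = trace, censored = censored, mode = mode,
                 unstable = FALSE),
            class = "tau_acc_result")
}

#' @export
print.tau_acc_result <- function(x, ...) {
  cat(sprintf("<tau_acc> %.1f fs (E_l=%g eV, E_T=%g eV, mode=%s)%s%s\n",
              x$tau_acc, x$E_l, x$E_T, x$mode,
              if (x$censored) " [censored]" else "",
              if (isTRUE(x$unstable)) " [unstable]" else ""))
  invisible(x)
}

#' Measure tau_acc prospectively along model-driven MD
#'
#' Propagates MD under the model's own dynamics from `start`; every
#' `interval` fs the ground truth is evaluated on the current frame (observer
#' only — it never steers the dynamics), the absolute energy error is
#' appended to the trace, and the run stops as soon as the cumulative rule
#' fires or `t_max` is reached. MD instability truncates the trace at the
#' last completed evaluation and flags the result.
#'
#' @param pot the model potential driving the dynamics.
#' @param truth a `ground_truth` observer.
#' @param start starting `configuration`.
#' @param md an `md_params` (its `n_steps` is ignored; `t_max` rules).
#' @param interval fs between truth evaluations (integer multiple of `md$dt`).
#' @param E_l,E_T thresholds, eV.
#' @param t_max maximum simulated time, fs.
#' @param mode accumulation mode, see [tau_acc_from_trace()].
#' @return a `tau_acc_result`.
#' @export
evaluate_tau_acc <- function(pot, truth, start, md = md_params(),
                             interval = 10, E_l = 0.1,
                             E_T = default_upper_threshold(E_l),
                             t_max = 5000, mode = c("full", "excess")) {
  mode <- match.arg(mode)
  stopifnot(E_T > E_l, E_l > 0)
  k <- interval / md$dt
  if (abs(k - round(k)) > 1e-9) {
    stop("interval must be an integer multiple of the MD timestep")
  }
  k <- as.integer(round(k))
  n_steps <- as.integer(round(t_max / md$dt))
  params <- md_params(T = md$T, dt = md$dt, gamma = md$gamma,
                      n_steps = n_steps, stride = md$stride, seed = md$seed)

  times <- numeric(0); errors <- numeric(0); cum <- 0; fired <- FALSE
  res <- md_engine(pot, start, params, observe = function(step, cfg, e_model) {
    e0 <- gt_evaluate(truth, cfg)$energy
    err <- abs(e0 - e_model)
    times[length(times) + 1L] <<- step * md$dt
    errors[length(errors) + 1L] <<- err
    contrib <- if (mode == "full") {
      if (err > E_l) err else 0
    } else {
      max(err - E_l, 0)
    }
    cum <<- cum + contrib
    if (cum > E_T) { fired <<- TRUE; TRUE } else FALSE
  }, observe_every = k)

  if (length(times) == 0L) {
    stop("no truth evaluation completed before the run ended; reduce interval")
  }
  out <- tau_acc_from_trace(error_trace(times, errors), E_l, E_T, mode)
  if (res$unstable) {
    out$tau_acc <- times[length(times)]
    out$censored <- FALSE
    out$unstable <- TRUE
  }
  out
}

#' Radial distribution function from a periodic trajectory
#'
#' `g_AB(r)`: histogram of minimum-image A-B distances normalised per frame
#' by the ideal-gas expectation `n_pairs * 4 pi r^2 dr / V` (same-species
#' pairs counted once, `N_A (N_A - 1) / 2`).
#'
#' @param traj a `trajectory` of periodic frames.
#' @param pair length-2 character vector of element symbols, e.g. `c("O","O")`.
#' @param r_max histogram range, A (must be below half the box edge).
#' @param bin_width bin width, A (default 0.05).
#' @return object of class `rdf`: data frame fields `r` (bin centres) and
#'   `g`, plus `pair` and `n_frames`.
#' @export
rdf <- function(traj, pair, r_max, bin_width = 0.05) {
  frames <- unclass(traj$frames)
  stopifnot(length(frames) >= 1L)
  n_bins <- as.integer(ceiling(r_max / bin_width))
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  counts <- numeric(n_bins)
  ideal <- numeric(n_bins)
  for (cfg in frames) {
    if (!any(cfg$pbc)) stop("rdf requires periodic frames")
    L <- assert_orthorhombic(cfg$cell)
    if (r_max >= min(L) / 2) {
      stop("r_max must be below half the shortest box edge")
    }
    V <- prod(L)
    ia <- which(cfg$species == pair[1L])
    ib <- which(cfg$species == pair[2L])
    same <- pair[1L] == pair[2L]
    npairs <- if (same) length(ia) * (length(ia) - 1) / 2
              else length(ia) * length(ib)
    if (npairs == 0) stop("no atom pairs of the requested species")
    dists <- c()
    for (i in ia) {
      js <- if (same) ib[ib > i] else ib
      if (!length(js)) next
      d <- sweep(cfg$positions[js, , drop = FALSE], 2L, cfg$positions[i, ], "-")
      d <- d - matrix(L, length(js), 3L, byrow = TRUE) *
        round(d / matrix(L, length(js), 3L, byrow = TRUE))
      dists <- c(dists, sqrt(rowSums(d * d)))
    }
    h <- graphics::hist(dists[dists < r_max], breaks = edges, plot = FALSE)$counts
    counts <- counts + h
    centres <- (edges[-1] + edges[-length(edges)]) / 2
    ideal <- ideal + npairs * 4 * pi * centres^2 * bin_width / V
  }
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(r = centres, g = counts / ideal, pair = pair,
                 n_frames = length(frames)),
            class = "rdf")
}

#' @export
print.rdf <- function(x, ...) {
  cat(sprintf("<rdf> %s-%s over %d frames, r <= %.2f A\n", x$pair[1L],
              x$pair[2L], x$n_frames, max(x$r)))
  invisible(x)
}

#' Parity statistics between predicted and reference energies
#'
#' @param pred,true numeric vectors of equal length, eV.
#' @param band "chemical accuracy" band half-width, eV (default 1 kcal/mol).
#' @return list with `rmse`, `max_abs`, `n_within_band`, `frac_within_band`.
#' @export
parity_stats <- function(pred, true, band = 0.0434) {
  stopifnot(length(pred) == length(true), length(pred) >= 1L)
  err <- pred - true
  list(rmse = sqrt(mean(err^2)), max_abs = max(abs(err)),
       n_within_band = sum(abs(err) <= band),
       frac_within_band = mean(abs(err) <= band))
}

#' Aggregate tau_acc measurements into a learning curve
#'
#' @param tau_by_repeat list (one element per independent repeat) of data
#'   frames with columns `budget` (truth-evaluation count) and `tau_acc`
#'   (fs); all repeats must share the same budget grid.
#' @param floor_fs reporting floor applied to `tau_floored` so curves can be
#'   drawn on a log scale; raw means are retained.
#' @return object of class `learning_curve`: data frame fields `budget`,
#'   `mean_tau`, `sem_tau`, `tau_floored`, and `n_repeats`.
#' @export
learning_curve <- function(tau_by_repeat, floor_fs = 0.1) {
  stopifnot(length(tau_by_repeat) >= 2L)
  budgets <- tau_by_repeat[[1L]]$budget
  for (r in tau_by_repeat) {
    if (!isTRUE(all.equal(r$budget, budgets))) {
      stop("inconsistent budget grids across repeats")
    }
  }
  taus <- vapply(tau_by_repeat, function(r) r$tau_acc,
                 numeric(length(budgets)))
  taus <- matrix(taus, nrow = length(budgets))
  mean_tau <- rowMeans(taus)
  sem_tau <- apply(taus, 1L, stats::sd) / sqrt(ncol(taus))
  structure(list(budget = budgets, mean_tau = mean_tau, sem_tau = sem_tau,
                 tau_floored = pmax(mean_tau, floor_fs),
                 n_repeats = length(tau_by_repeat)),
            class = "learning_curve")
}

#' Write a tau_acc error trace as CSV
#' @param result a `tau_acc_result`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_trace_csv <- function(result, path) {
  utils::write.csv(data.frame(time_fs = result$trace$times,
                              error_eV = result$trace$errors),
                   path, row.names = FALSE)
  invisible(path)
}

#' One-row summary of a tau_acc measurement
#' @param result a `tau_acc_result`.
#' @param tag model label.
#' @return a one-row data.frame.
#' @export
tau_acc_summary <- function(result, tag = "model") {
  data.frame(model = tag, E_l = result$E_l, E_T = result$E_T,
             interval_fs = result$interval, tau_acc_fs = result$tau_acc,
             censored = result$censored, mode = result$mode,
             unstable = isTRUE(result$unstable))
}
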