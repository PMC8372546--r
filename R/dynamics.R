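## Langevin MD (BAOAB), velocity initialisation, local minimisation and
## nudged-elastic-band path relaxation — the consumers of the energy/force
## contract shared by ground truths, GP models and composite potentials.

#' MD run parameters
#'
#' @param T temperature, K.
#' @param dt timestep, fs (default 0.5).
#' @param gamma Langevin friction, 1/fs (0 gives NVE velocity Verlet).
#' @param n_steps number of integration steps.
#' @param stride steps between stored snapshots.
#' @param seed integer seed for the thermal noise (and velocity init).
#' @return object of class `md_params`.
#' @export
md_params <- function(T = 300, dt = 0.5, gamma = 0.02, n_steps = 1000L,
                      stride = 1L, seed = 0L) {
  stopifnot(dt > 0, gamma >= 0, T >= 0, n_steps >= 1L, stride >= 1L)
  structure(list(T = T, dt = dt, gamma = gamma, n_steps = as.integer(n_steps),
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "md_params")
}

#' Kinetic energy of a configuration, eV
#' @param cfg a `configuration` with velocities.
#' @return kinetic energy in eV.
#' @export
kinetic_energy <- function(cfg) {
  if (is.null(cfg$velocities)) return(0)
  m <- atomic_masses(cfg$species)
  0.5 * sum(m * rowSums(cfg$velocities^2)) * .EV_PER_AMU_A2_FS2
}

#' Instantaneous kinetic temperature, K
#' @param cfg a `configuration` with velocities.
#' @param dof degrees of freedom (defaults to 3N).
#' @return temperature in K.
#' @export
instantaneous_temperature <- function(cfg, dof = 3L * n_atoms(cfg)) {
  2 * kinetic_energy(cfg) / (dof * .KB_EV)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Per-component normal draws with variance kT/m, followed by removal of the
#' total linear momentum. Deterministic given the seed.
#'
#' @param cfg a `configuration`.
#' @param T temperature, K.
#' @param seed integer seed.
#' @return the configuration with velocities set (A/fs).
#' @export
maxwell_boltzmann_velocities <- function(cfg, T, seed = 0L) {
  stopifnot(T >= 0)
  n <- n_atoms(cfg)
  m <- atomic_masses(cfg$species)
  v <- with_seed(seed, {
    sd <- sqrt(.KB_EV * T * .ACC_CONV / m)
    matrix(stats::rnorm(3L * n), n, 3L) * sd
  })
  ## remove centre-of-mass momentum
  p <- colSums(v * m)
  v <- sweep(v, 2L, p / sum(m))
  cfg$velocities <- v
  cfg
}

#' Inject relative kinetic energy into one bond
#'
#' Adds anti-parallel velocity components along the i->j axis, partitioned by
#' mass so the total momentum is unchanged and the added relative-motion
#' kinetic energy equals `E_add` exactly (`mu v_rel^2 / 2 = E_add`).
#'
#' @param cfg a `configuration`.
#' @param i,j 1-based atom indices of the (breaking) bond.
#' @param E_add energy to deposit, eV.
#' @return the configuration with modified velocities.
#' @export
inject_bond_energy <- function(cfg, i, j, E_add) {
  stopifnot(i != j, E_add >= 0)
  if (E_add == 0) return(cfg)
  d <- minimum_image_displacement(cfg, i, j)
  r <- sqrt(sum(d * d))
  if (r < 1e-10) stop("cannot inject energy into a bond between coincident atoms")
  u <- d / r
  m <- atomic_masses(cfg$species)
  mu <- m[i] * m[j] / (m[i] + m[j])
  v_rel <- sqrt(2 * E_add * .ACC_CONV / mu)
  if (is.null(cfg$velocities)) cfg$velocities <- matrix(0, n_atoms(cfg), 3L)
  cfg$velocities[i, ] <- cfg$velocities[i, ] - u * v_rel * m[j] / (m[i] + m[j])
  cfg$velocities[j, ] <- cfg$velocities[j, ] + u * v_rel * m[i] / (m[i] + m[j])
  cfg
}

## Core integrator. `observe(step, cfg, energy)` is called after every
## completed step whose index is a multiple of `observe_every`; returning
## TRUE stops the run early. Runs entirely under the seeded RNG.
md_engine <- function(pot, cfg, params, observe = NULL, observe_every = 1L) {
  n <- n_atoms(cfg)
  m <- atomic_masses(cfg$species)
  if (is.null(cfg$velocities)) {
    cfg <- maxwell_boltzmann_velocities(cfg, params$T, params$seed + 1L)
  }
  dt <- params$dt
  c1 <- exp(-params$gamma * dt)
  c2 <- sqrt(pmax(0, 1 - c1^2)) * sqrt(.KB_EV * params$T * .ACC_CONV / m)
  noisy <- params$gamma > 0

  x <- cfg$positions
  v <- cfg$velocities
  ev <- evaluate_potential(pot, cfg, forces = TRUE)
  if (!is.finite(ev$energy) || !all(is.finite(ev$forces))) {
    stop("potential non-finite at the initial configuration")
  }
  a <- ev$forces / m * .ACC_CONV
  stopped <- FALSE
  unstable <- FALSE
  steps_done <- 0L

  with_seed(params$seed, {
    for (step in seq_len(params$n_steps)) {
      v <- v + 0.5 * dt * a                               # B
      x <- x + 0.5 * dt * v                               # A
      if (noisy) {                                        # O
        v <- c1 * v + c2 * matrix(stats::rnorm(3L * n), n, 3L)
      }
      x <- x + 0.5 * dt * v                               # A
      cfg$positions <- x
      ev <- evaluate_potential(pot, cfg, forces = TRUE)
      if (!is.finite(ev$energy) || !all(is.finite(ev$forces))) {
        unstable <- TRUE
        break
      }
      a <- ev$forces / m * .ACC_CONV
      v <- v + 0.5 * dt * a                               # B
      steps_done <- step
      if (!is.null(observe) && step %% observe_every == 0L) {
        cfg$velocities <- v
        if (isTRUE(observe(step, cfg, ev$energy))) { stopped <- TRUE; break }
      }
    }
  })
  cfg$positions <- x
  cfg$velocities <- v
  list(cfg = cfg, energy = ev$energy, steps_done = steps_done,
       unstable = unstable, stopped = stopped)
}

#' Run Langevin (or NVE) molecular dynamics
#'
#' BAOAB-split Langevin integration with friction `gamma` and seeded thermal
#' noise; `gamma = 0` gives plain velocity Verlet with no noise. Frames are
#' stored every `stride` steps with times in fs (`t_k = k * stride * dt`);
#' non-finite energies or forces abort the run, returning the partial
#' trajectory flagged unstable.
#'
#' @param pot an energy/force provider (see [evaluate_potential()]).
#' @param cfg starting `configuration` (velocities initialised at `params$T`
#'   when absent).
#' @param params an `md_params`.
#' @return a `trajectory`.
#' @export
run_md <- function(pot, cfg, params) {
  frames <- list()
  times <- numeric(0)
  e0 <- evaluate_potential(pot, cfg, forces = FALSE)$energy
  start <- cfg
  if (is.null(start$velocities)) {
    start <- maxwell_boltzmann_velocities(start, params$T, params$seed + 1L)
  }
  f0 <- start; f0$energy <- e0
  frames[[1L]] <- f0
  times[1L] <- 0
  res <- md_engine(pot, start, params, observe = function(step, c2, energy) {
    c2$energy <- energy
    frames[[length(frames) + 1L]] <<- c2
    times[length(times) + 1L] <<- step * params$dt
    FALSE
  }, observe_every = params$stride)
  trajectory(frames, times, unstable = res$unstable)
}

## ---------------------------------------------------------------------------
## Local minimisation: steepest descent with Barzilai-Borwein step length and
## Armijo backtracking, so the energy never increases across accepted steps.

#' Minimise a configuration under a potential
#'
#' @param pot an energy/force provider.
#' @param cfg starting `configuration`.
#' @param f_max convergence threshold on the largest force component, eV/A.
#' @param max_steps iteration budget; non-convergence raises an error whose
#'   condition carries the best configuration so far (`$best`).
#' @return the minimised `configuration` with `energy` set.
#' @export
minimise <- function(pot, cfg, f_max = 1e-3, max_steps = 5000L) {
  stopifnot(f_max > 0)
  x <- as.vector(t(cfg$positions))
  cfg2 <- cfg
  ef <- function(xv) {
    cfg2$positions <- matrix(xv, ncol = 3L, byrow = TRUE)
    evaluate_potential(pot, cfg2, forces = TRUE)
  }
  ev <- ef(x)
  g <- -as.vector(t(ev$forces))
  alpha <- 0.05
  for (it in seq_len(max_steps)) {
    if (max(abs(g)) <= f_max) {
      cfg$positions <- matrix(x, ncol = 3L, byrow = TRUE)
      cfg$energy <- ev$energy
      return(cfg)
    }
    accepted <- FALSE
    a <- alpha
    for (ls in 1:40) {
      xn <- x - a * g
      evn <- ef(xn)
      if (is.finite(evn$energy) &&
          evn$energy <= ev$energy - 1e-4 * a * sum(g * g)) {
        gn <- -as.vector(t(evn$forces))
        s <- xn - x; y <- gn - g
        sy <- sum(s * y)
        alpha <- if (sy > 0) max(1e-6, min(0.5, sy / sum(y * y))) else 0.05
        x <- xn; g <- gn; ev <- evn
        accepted <- TRUE
        break
      }
      a <- a / 2
    }
    if (!accepted) {
      cond <- simpleError("minimisation line search stalled before reaching f_max")
      cfg$positions <- matrix(x, ncol = 3L, byrow = TRUE)
      cfg$energy <- ev$energy
      cond$best <- cfg
      stop(cond)
    }
  }
  cond <- simpleError(sprintf("minimisation did not reach f_max=%.3g in %d steps",
                              f_max, max_steps))
  cfg$positions <- matrix(x, ncol = 3L, byrow = TRUE)
  cfg$energy <- ev$energy
  cond$best <- cfg
  stop(cond)
}

## ---------------------------------------------------------------------------
## Nudged elastic band with the improved tangent estimate, relaxed by FIRE.

neb_tangent <- function(R, E, i) {
  ## Henkelman-Jonsson improved tangent for interior image i
  tp <- R[[i + 1L]] - R[[i]]
  tm <- R[[i]] - R[[i - 1L]]
  if (E[i + 1L] > E[i] && E[i] > E[i - 1L]) {
    tau <- tp
  } else if (E[i + 1L] < E[i] && E[i] < E[i - 1L]) {
    tau <- tm
  } else {
    dmax <- max(abs(E[i + 1L] - E[i]), abs(E[i - 1L] - E[i]))
    dmin <- min(abs(E[i + 1L] - E[i]), abs(E[i - 1L] - E[i]))
    tau <- if (E[i + 1L] > E[i - 1L]) tp * dmax + tm * dmin
           else tp * dmin + tm * dmax
  }
  nt <- sqrt(sum(tau^2))
  if (nt < 1e-300) tau else tau / nt
}

#' Relax a nudged elastic band between two endpoints
#'
#' Interior images are initialised by linear interpolation and relaxed with
#' the standard NEB projection (perpendicular true force plus parallel spring
#' force, improved-tangent estimate) using a FIRE optimiser until the largest
#' projected-force component is below `f_max`. Endpoints never move.
#'
#' @param pot an energy/force provider.
#' @param reactant,product endpoint `configuration`s with identical atom
#'   ordering.
#' @param n_images total number of images (>= 3, endpoints included).
#' @param k_spring spring constant, eV/A^2.
#' @param f_max convergence threshold, eV/A.
#' @param max_steps FIRE iteration budget.
#' @param climbing if `TRUE`, the highest image climbs (spring force dropped,
#'   parallel true force inverted).
#' @param init_noise amplitude (A) of a seeded random perpendicular
#'   perturbation of the interior starting images; breaks the symmetry of
#'   exchange paths whose straight-line interpolation lies on a ridge.
#' @param seed seed for `init_noise`.
#' @return object of class `neb_path`: `images` (a `configuration_set` with
#'   energies), `energies`, `k_spring`, `max_force`, `converged`.
#' @export
neb_relax <- function(pot, reactant, product, n_images = 11L, k_spring = 5,
                      f_max = 0.05, max_steps = 2000L, climbing = FALSE,
                      init_noise = 0, seed = 0L) {
  stopifnot(n_images >= 3L)
  if (!identical(reactant$species, product$species)) {
    stop("endpoints must share the same atom ordering")
  }
  n <- n_atoms(reactant)
  R <- lapply(seq_len(n_images), function(k) {
    lam <- (k - 1) / (n_images - 1)
    (1 - lam) * reactant$positions + lam * product$positions
  })
  if (init_noise > 0) {
    R[2:(n_images - 1L)] <- with_seed(seed, {
      lapply(R[2:(n_images - 1L)], function(P) {
        P + matrix(stats::rnorm(length(P), sd = init_noise), nrow(P), 3L)
      })
    })
  }
  probe <- reactant
  probe$velocities <- NULL
  energy_of <- function(P) {
    probe$positions <- P
    evaluate_potential(pot, probe, forces = TRUE)
  }

  degenerate <- max(abs(product$positions - reactant$positions)) == 0

  evals <- lapply(R, energy_of)
  E <- vapply(evals, function(e) e$energy, numeric(1))
  Ftrue <- lapply(evals, function(e) e$forces)

  interior <- 2:(n_images - 1L)
  neb_forces <- function() {
    out <- vector("list", n_images)
    imax <- which.max(E)
    for (i in interior) {
      tau <- neb_tangent(R, E, i)
      Fi <- Ftrue[[i]]
      fpar <- sum(Fi * tau)
      dp <- sqrt(sum((R[[i + 1L]] - R[[i]])^2))
      dm <- sqrt(sum((R[[i]] - R[[i - 1L]])^2))
      if (climbing && i == imax) {
        out[[i]] <- Fi - 2 * fpar * tau
      } else {
        out[[i]] <- (Fi - fpar * tau) + k_spring * (dp - dm) * tau
      }
    }
    out
  }

  make_path <- function(converged, fmax_now) {
    imgs <- lapply(seq_len(n_images), function(k) {
      ck <- reactant
      ck$positions <- R[[k]]
      ck$energy <- E[k]
      ck$info$image <- k - 1L
      ck
    })
    structure(list(images = configuration_set(imgs), energies = E,
                   k_spring = k_spring, max_force = fmax_now,
                   converged = converged),
              class = "neb_path")
  }

  Fn <- neb_forces()
  fmax_now <- max(vapply(interior, function(i) max(abs(Fn[[i]])), numeric(1)))
  if (degenerate || fmax_now <= f_max) return(make_path(TRUE, fmax_now))

  ## FIRE on the concatenated interior coordinates
  dt <- 0.05; dt_max <- 0.4; a <- 0.1; n_up <- 0L
  V <- lapply(interior, function(i) matrix(0, n, 3L))
  for (it in seq_len(max_steps)) {
    Fc <- do.call(rbind, Fn[interior])
    Vc <- do.call(rbind, V)
    P <- sum(Fc * Vc)
    if (P > 0) {
      n_up <- n_up + 1L
      if (n_up > 5L) { dt <- min(dt * 1.1, dt_max); a <- a * 0.99 }
      nf <- sqrt(sum(Fc^2)); nv <- sqrt(sum(Vc^2))
      Vc <- (1 - a) * Vc + a * (if (nf > 0) Fc / nf * nv else 0)
    } else {
      n_up <- 0L; dt <- dt * 0.5; a <- 0.1; Vc <- Vc * 0
    }
    Vc <- Vc + dt * Fc
    step <- dt * Vc
    cap <- max(abs(step))
    if (cap > 0.1) step <- step * (0.1 / cap)
    for (q in seq_along(interior)) {
      i <- interior[q]
      R[[i]] <- R[[i]] + step[((q - 1) * n + 1):(q * n), , drop = FALSE]
      V[[q]] <- Vc[((q - 1) * n + 1):(q * n), , drop = FALSE]
      e <- energy_of(R[[i]])
      E[i] <- e$energy
      Ftrue[[i]] <- e$forces
    }
    Fn <- neb_forces()
    fmax_now <- max(vapply(interior, function(i) max(abs(Fn[[i]])), numeric(1)))
    if (fmax_now <= f_max) return(make_path(TRUE, fmax_now))
  }
  cond <- simpleError(sprintf("NEB did not converge below %.3g eV/A in %d steps",
                              f_max, max_steps))
  cond$path <- make_path(FALSE, fmax_now)
  stop(cond)
}

#' @export
print.neb_path <- function(x, ...) {
  cat(sprintf("<neb_path> %d images, barrier %.4f eV, max|F|=%.3g eV/A%s\n",
              length(x$images), max(x$energies) - x$energies[1L], x$max_force,
              if (x$converged) "" else " [unconverged]"))
  invisible(x)
}
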