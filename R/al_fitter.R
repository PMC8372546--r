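## Incremental refitting for the active-learning loop.
##
## The AL loop refits after every accepted addition. Rebuilding every kernel
## row each time is wasteful: design rows only change when the sparse set
## changes. This fitter caches per-configuration rows and maintains a
## sequentially updated QR factorisation of the weighted design (including
## the prior square-root rows), so each refit after an addition costs one
## small QR update at full numerical stability. The sparse set is
## re-selected only when the environment pool has doubled since the last
## selection, which triggers a full rebuild from the cache. Requires
## `e0_mode = "zero"` (fixed labels); models returned are ordinary
## `gp_model` objects.

make_incremental_fitter <- function(specs, hyper) {
  if (!identical(hyper$e0_mode, "zero")) {
    stop("the incremental fitter requires hyper_params(e0_mode = 'zero')")
  }
  st <- new.env(parent = emptyenv())
  st$n_seen <- 0L
  st$pool <- vector("list", length(specs))
  st$sparse <- NULL
  st$offsets <- NULL
  st$rows <- list()          # per config: list(X = sqrt(W) phi, y = sqrt(W) labels)
  st$R <- NULL               # current upper-triangular factor
  st$z <- NULL               # matching transformed rhs
  st$pool_at_select <- 0L

  config_rows <- function(cfg, specs2, sparse, offs, ntot) {
    n <- n_atoms(cfg)
    has_f <- !is.null(cfg$forces)
    erow <- numeric(ntot)
    frows <- if (has_f) matrix(0, 3 * n, ntot) else NULL
    for (k in seq_along(specs2)) {
      kr <- kernel_rows(cfg, specs2[[k]], sparse[[k]], has_f)
      cols <- (offs[k] + 1):offs[k + 1]
      erow[cols] <- colSums(kr$K)
      if (has_f) frows[, cols] <- -kr$J
    }
    phi <- rbind(erow, frows)
    wv <- c(1 / (hyper$sigma_E * n)^2,
            if (has_f) rep(1 / hyper$sigma_F^2, 3 * n))
    y <- c(cfg$energy, if (has_f) as.vector(t(cfg$forces)))
    list(X = phi * sqrt(wv), y = y * sqrt(wv))
  }

  qr_update <- function(R, z, X, y) {
    ## one sequential least-squares update: qr of [R; X] with the column
    ## pivoting undone, so the maintained m x m factor R~ always satisfies
    ## R~' R~ = A' A in the original column order
    f <- qr(rbind(R, X), LAPACK = TRUE)
    Rnew <- qr.R(f)[, order(f$pivot), drop = FALSE]
    list(R = Rnew, z = qr.qty(f, c(z, y))[seq_len(ncol(X))])
  }

  function(train, seed) {
    train <- configuration_set(train)
    stopifnot(length(train) >= st$n_seen)
    elements <- sort(unique(unlist(lapply(unclass(train), function(c) c$species))))
    specs2 <- lapply(specs, function(s) { s$elements <- elements; s })

    new_idx <- if (st$n_seen < length(train)) (st$n_seen + 1L):length(train) else integer(0)
    for (i in new_idx) {
      cfg <- train[[i]]
      for (k in seq_along(specs2)) {
        add <- pool_environments(configuration_set(list(cfg)), specs2[[k]])
        if (is.null(add)) next
        st$pool[[k]] <- if (k > length(st$pool) || is.null(st$pool[[k]])) add
                        else rbind(st$pool[[k]], add)
      }
    }

    pool_rows <- vapply(st$pool, function(p) if (is.null(p)) 0L else nrow(p), 0L)
    pool_n <- sum(pool_rows)
    reselect <- is.null(st$sparse) || pool_n >= 2L * st$pool_at_select
    if (reselect) {
      ## descriptors still without any pooled environment are left out until
      ## data for them appears
      st$keep <- which(pool_rows > 0L)
      if (!length(st$keep)) stop("no environments found for any descriptor")
      st$sparse <- lapply(st$keep, function(k) {
        select_sparse(st$pool[[k]], specs2[[k]], hyper, seed + k)
      })
      ns <- vapply(seq_along(st$keep), function(j) {
        n_sparse_of(st$sparse[[j]], specs2[[st$keep[j]]]$kind)
      }, numeric(1))
      st$offsets <- c(0, cumsum(ns))
      st$pool_at_select <- pool_n
      st$rows <- list()
      st$R <- NULL
      st$n_seen <- 0L
      new_idx <- seq_along(unclass(train))
    }
    specs_used <- specs2[st$keep]
    ntot <- st$offsets[length(st$offsets)]

    if (is.null(st$R)) {
      ## prior rows: symmetric square root of K_mm/delta^2 plus ridge jitter
      Kmm <- matrix(0, ntot, ntot)
      for (k in seq_along(specs_used)) {
        cols <- (st$offsets[k] + 1):st$offsets[k + 1]
        Kmm[cols, cols] <-
          sparse_gram(specs_used[[k]], st$sparse[[k]]) / specs_used[[k]]$delta^2
      }
      eg <- eigen(Kmm, symmetric = TRUE)
      U <- diag(sqrt(pmax(eg$values, 0)), ntot) %*% t(eg$vectors)
      jit <- hyper$jitter * max(diag(Kmm), 1)
      f <- qr(rbind(U, diag(sqrt(jit), ntot)), LAPACK = TRUE)
      st$R <- qr.R(f)[, order(f$pivot), drop = FALSE]
      st$z <- numeric(ntot)
      st$Kmm <- Kmm
    }

    for (i in new_idx) {
      r <- config_rows(train[[i]], specs_used, st$sparse, st$offsets, ntot)
      st$rows[[i]] <- r
      up <- qr_update(st$R, st$z, r$X, r$y)
      st$R <- up$R
      st$z <- up$z
    }
    st$n_seen <- length(train)

    w <- drop(qr.coef(qr(st$R, LAPACK = TRUE), st$z))
    w[!is.finite(w)] <- 0

    e0 <- stats::setNames(numeric(length(elements)), elements)
    var_inv <- lapply(seq_along(specs_used), function(k) {
      cols <- (st$offsets[k] + 1):st$offsets[k + 1]
      safe_gram_inverse(st$Kmm[cols, cols, drop = FALSE] * specs_used[[k]]$delta^2,
                        hyper$jitter)
    })
    tags <- unique(unlist(lapply(unclass(train), function(c) c$level_tag)))
    structure(list(specs = specs_used, sparse = st$sparse, weights = w,
                   offsets = st$offsets, e0 = e0, hyper = hyper,
                   var_inv = var_inv,
                   level_tag = if (length(tags)) tags[1L] else "unlabelled",
                   train_set = train, seed = seed, elements = elements,
                   schema_version = 1L),
              class = "gp_model")
  }
}
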