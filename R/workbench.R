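## Configuration-file-driven workbench: declarative YAML runs over the
## training, validation and dynamics pipelines, with structured logging,
## a MANIFEST, and seeded reproducibility.

.CONFIG_SCHEMA <- list(
  seed = NULL,
  system = list(kind = NULL, n_molecules = NULL, box = NULL, path = NULL),
  ground_truth = list(name = NULL, params = "free", command = NULL,
                      level_tag = NULL),
  hyper = list(sigma_E = NULL, sigma_F = NULL, n_sparse = NULL,
               sparse_method = NULL, jitter = NULL, e0_mode = NULL),
  md = list(T = NULL, dt = NULL, gamma = NULL, n_steps = NULL, stride = NULL),
  al = list(strategy = NULL, E_add = NULL, var_add = NULL, T_AL = NULL,
            max_truth_evals = NULL, target_time = NULL),
  tau_acc = list(E_l = NULL, E_T = NULL, interval = NULL, t_max = NULL,
                 mode = NULL),
  rdf = list(pair = NULL, r_max = NULL, bin_width = NULL),
  neb = list(n_images = NULL, k_spring = NULL, f_max = NULL, climbing = NULL)
)

validate_config_keys <- function(cfg, schema = .CONFIG_SCHEMA, path = "") {
  if (!is.list(cfg)) return(invisible(TRUE))
  for (key in names(cfg)) {
    full <- paste0(path, key)
    if (!key %in% names(schema)) {
      stop("unknown configuration key: ", full, call. = FALSE)
    }
    sub <- schema[[key]]
    if (is.list(sub)) {
      validate_config_keys(cfg[[key]], sub, paste0(full, "."))
    }
    ## entries marked "free" (e.g. ground-truth parameter lists) are passed
    ## through unchecked
  }
  invisible(TRUE)
}

config_defaults <- function() {
  list(seed = 0L,
       system = list(kind = "water_box", n_molecules = 10L, box = 7),
       ground_truth = list(name = "toy_water", params = list()),
       hyper = list(sigma_E = 1e-4, sigma_F = 0.05, n_sparse = 150L,
                    sparse_method = "cur", jitter = 1e-8, e0_mode = "zero"),
       md = list(T = 300, dt = 0.5, gamma = 0.02, n_steps = 1000L,
                 stride = 10L),
       al = list(strategy = "diff", E_add = 0.01, var_add = 1e-4, T_AL = 300,
                 max_truth_evals = 250L, target_time = 1000),
       tau_acc = list(E_l = 0.01, E_T = NULL, interval = 10, t_max = 5000,
                      mode = "full"),
       rdf = list(pair = c("O", "O"), r_max = 3.4, bin_width = 0.05),
       neb = list(n_images = 11L, k_spring = 5, f_max = 0.05,
                  climbing = FALSE))
}

merge_config <- function(defaults, user) {
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(user[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]])
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a workbench run configuration
#'
#' Reads a YAML file, rejects unknown keys before any computation, and
#' materialises all defaults.
#'
#' @param path YAML file path, or a named list.
#' @return the resolved configuration list.
#' @export
load_run_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(user)) user <- list()
  validate_config_keys(user)
  merge_config(config_defaults(), user)
}

config_truth <- function(cfg) {
  gt <- cfg$ground_truth
  if (identical(gt$name, "toy_water")) {
    do.call(toy_water_params, gt$params)
    params <- do.call(toy_water_params, gt$params)
    toy_water_truth(params)
  } else if (identical(gt$name, "evb")) {
    params <- do.call(evb_params, gt$params)
    evb_truth(params)
  } else if (identical(gt$name, "adapter")) {
    if (is.null(gt$command)) stop("adapter ground truth needs a command")
    external_truth(gt$command,
                   if (is.null(gt$level_tag)) "external" else gt$level_tag)
  } else {
    stop("unknown ground truth: ", gt$name)
  }
}

config_hyper <- function(cfg) {
  h <- cfg$hyper
  hyper_params(sigma_E = h$sigma_E, sigma_F = h$sigma_F,
               n_sparse = h$n_sparse, sparse_method = h$sparse_method,
               jitter = h$jitter, e0_mode = h$e0_mode)
}

config_md <- function(cfg, n_steps = NULL) {
  m <- cfg$md
  md_params(T = m$T, dt = m$dt, gamma = m$gamma,
            n_steps = if (is.null(n_steps)) m$n_steps else n_steps,
            stride = m$stride, seed = stage_seed(cfg$seed, "md"))
}

config_al <- function(cfg) {
  a <- cfg$al
  al_params(strategy = a$strategy, E_add = a$E_add, var_add = a$var_add,
            T_AL = a$T_AL, max_truth_evals = a$max_truth_evals,
            target_time = a$target_time, seed = stage_seed(cfg$seed, "al"))
}

## Run-directory helpers ------------------------------------------------------

run_log <- function(dir) {
  path <- file.path(dir, "run.log")
  function(...) {
    kv <- list(...)
    line <- paste(sprintf("%s=%s", names(kv), unlist(kv)), collapse = " ")
    cat(line, "\n", file = path, append = TRUE, sep = "")
  }
}

write_manifest <- function(dir, artifacts, complete) {
  jsonlite::write_json(list(artifacts = artifacts, complete = complete),
                       file.path(dir, "MANIFEST.json"), auto_unbox = TRUE)
}

prepare_run_dir <- function(cfg, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out, "resolved_config.yaml"))
  writeLines(sprintf("seed=%d", as.integer(cfg$seed)),
             file.path(out, "seeds.txt"))
  c("resolved_config.yaml", "seeds.txt")
}

## Commands -------------------------------------------------------------------

#' Train a potential from a declarative configuration
#'
#' Water-box systems run the full intra+inter pipeline (monomer-grid intra
#' model, then intermolecular active learning); the gas-phase EVB triatomic
#' trains a single model by transition-state-initialised active learning and
#' skips the decomposition.
#'
#' @param config path to a YAML run configuration (or a list).
#' @param out output directory.
#' @return invisibly, the list of artifact file names.
#' @export
cmd_train <- function(config, out) {
  cfg <- load_run_config(config)
  artifacts <- prepare_run_dir(cfg, out)
  log <- run_log(out)
  complete <- FALSE
  on.exit(write_manifest(out, artifacts, complete))

  truth <- config_truth(cfg)
  log(stage = "train", system = cfg$system$kind, seed = cfg$seed)
  if (identical(cfg$system$kind, "water_box")) {
    res <- train_water_composite(
      truth, n_waters = cfg$system$n_molecules, box = cfg$system$box,
      al = config_al(cfg), md = config_md(cfg),
      inter_hyper = config_hyper(cfg), seed = cfg$seed)
    save_composite(res$composite, file.path(out, "model_composite.json"))
    write_history_csv(res$history, file.path(out, "al_history.csv"))
    write_extxyz(res$history$train_set, file.path(out, "train_set.xyz"))
    write_extxyz(configuration_set(list(res$start)),
                 file.path(out, "start.xyz"))
    for (i in seq_len(nrow(res$history$records))) {
      r <- res$history$records[i, ]
      log(episode = r$episode, n = r$n, time_fs = r$time_fs,
          metric = signif(r$metric, 6), added = r$added)
    }
    artifacts <- c(artifacts, "model_composite.json", "al_history.csv",
                   "train_set.xyz", "start.xyz", "run.log")
  } else if (identical(cfg$system$kind, "evb_triatomic")) {
    res <- train_evb_gap(truth, al = config_al(cfg), md = config_md(cfg),
                         seed = cfg$seed)
    save_model(res$model, file.path(out, "model.json"))
    write_history_csv(res$history, file.path(out, "al_history.csv"))
    for (i in seq_len(nrow(res$history$records))) {
      r <- res$history$records[i, ]
      log(episode = r$episode, n = r$n, time_fs = r$time_fs,
          metric = signif(r$metric, 6), added = r$added)
    }
    artifacts <- c(artifacts, "model.json", "al_history.csv", "run.log")
  } else {
    stop("unknown system kind: ", cfg$system$kind)
  }
  complete <- TRUE
  invisible(artifacts)
}

load_any_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(raw$class, "composite_potential")) load_composite(path)
  else load_model(path)
}

system_start <- function(cfg, truth, model_dir = NULL) {
  if (!is.null(cfg$system$path)) {
    return(read_extxyz(cfg$system$path)[[1L]])
  }
  if (!is.null(model_dir) && file.exists(file.path(model_dir, "start.xyz"))) {
    return(read_extxyz(file.path(model_dir, "start.xyz"))[[1L]])
  }
  if (identical(cfg$system$kind, "water_box")) {
    pack <- random_packed_configuration(list(water_template()),
                                        cfg$system$n_molecules,
                                        box = cfg$system$box, min_dist = 1.7,
                                        seed = stage_seed(cfg$seed, "pack"))
    minimise(truth, pack, f_max = 0.05, max_steps = 5000L)
  } else if (identical(cfg$system$kind, "evb_triatomic")) {
    evb_ts_configuration(truth)
  } else {
    stop("system kind ", cfg$system$kind, " needs an explicit path")
  }
}

#' Measure tau_acc for a trained model archive
#'
#' @param config run configuration (YAML path or list).
#' @param model path to a model archive from [cmd_train()].
#' @param out output directory.
#' @return invisibly, the `tau_acc_result`.
#' @export
cmd_tau_acc <- function(config, model, out) {
  cfg <- load_run_config(config)
  artifacts <- prepare_run_dir(cfg, out)
  log <- run_log(out)
  complete <- FALSE
  on.exit(write_manifest(out, artifacts, complete))

  pot <- load_any_model(model)
  truth <- config_truth(cfg)
  start <- system_start(cfg, truth, dirname(model))
  ts <- cfg$tau_acc
  E_T <- if (is.null(ts$E_T)) default_upper_threshold(ts$E_l) else ts$E_T
  res <- evaluate_tau_acc(pot, truth, start, config_md(cfg),
                          interval = ts$interval, E_l = ts$E_l, E_T = E_T,
                          t_max = ts$t_max, mode = ts$mode)
  write_trace_csv(res, file.path(out, "trace.csv"))
  utils::write.csv(tau_acc_summary(res, tag = basename(model)),
                   file.path(out, "tau_acc_summary.csv"), row.names = FALSE)
  log(stage = "tau_acc", tau_acc_fs = res$tau_acc, censored = res$censored)
  artifacts <- c(artifacts, "trace.csv", "tau_acc_summary.csv", "run.log")
  complete <- TRUE
  invisible(res)
}

#' Run MD under a trained model archive
#'
#' @param config run configuration.
#' @param model model archive path.
#' @param out output directory.
#' @return invisibly, the `trajectory`.
#' @export
cmd_md <- function(config, model, out) {
  cfg <- load_run_config(config)
  artifacts <- prepare_run_dir(cfg, out)
  log <- run_log(out)
  complete <- FALSE
  on.exit(write_manifest(out, artifacts, complete))
  pot <- load_any_model(model)
  truth <- config_truth(cfg)
  start <- system_start(cfg, truth, dirname(model))
  traj <- run_md(pot, start, config_md(cfg))
  write_trajectory_extxyz(traj, file.path(out, "trajectory.xyz"))
  log(stage = "md", frames = length(traj$frames),
      unstable = isTRUE(traj$unstable))
  artifacts <- c(artifacts, "trajectory.xyz", "run.log")
  complete <- TRUE
  invisible(traj)
}

#' Compute an RDF from model-driven MD
#'
#' @param config run configuration.
#' @param model model archive path.
#' @param out output directory.
#' @return invisibly, the `rdf`.
#' @export
cmd_rdf <- function(config, model, out) {
  cfg <- load_run_config(config)
  artifacts <- prepare_run_dir(cfg, out)
  log <- run_log(out)
  complete <- FALSE
  on.exit(write_manifest(out, artifacts, complete))
  pot <- load_any_model(model)
  truth <- config_truth(cfg)
  start <- system_start(cfg, truth, dirname(model))
  traj <- run_md(pot, start, config_md(cfg))
  g <- rdf(traj, pair = unlist(cfg$rdf$pair), r_max = cfg$rdf$r_max,
           bin_width = cfg$rdf$bin_width)
  utils::write.csv(data.frame(r = g$r, g = g$g),
                   file.path(out, "rdf.csv"), row.names = FALSE)
  log(stage = "rdf", pair = paste(g$pair, collapse = "-"),
      n_frames = g$n_frames)
  artifacts <- c(artifacts, "rdf.csv", "run.log")
  complete <- TRUE
  invisible(g)
}

#' Relax a nudged elastic band under a trained model
#'
#' Endpoints come from `system.path` (a 2-frame extended-XYZ file) or, for
#' the EVB triatomic, from the surrogate's two minimised wells.
#'
#' @param config run configuration.
#' @param model model archive path.
#' @param out output directory.
#' @return invisibly, the `neb_path`.
#' @export
cmd_neb <- function(config, model, out) {
  cfg <- load_run_config(config)
  artifacts <- prepare_run_dir(cfg, out)
  log <- run_log(out)
  complete <- FALSE
  on.exit(write_manifest(out, artifacts, complete))
  pot <- load_any_model(model)
  if (!is.null(cfg$system$path)) {
    ends <- read_extxyz(cfg$system$path)
    if (length(ends) < 2L) stop("NEB endpoints file needs two frames")
    reactant <- ends[[1L]]; product <- ends[[length(ends)]]
  } else if (identical(cfg$system$kind, "evb_triatomic")) {
    truth <- config_truth(cfg)
    wells <- evb_well_configurations(truth)
    reactant <- wells$reactant; product <- wells$product
  } else {
    stop("NEB needs explicit endpoints for this system")
  }
  nb <- cfg$neb
  path <- neb_relax(pot, reactant, product, n_images = nb$n_images,
                    k_spring = nb$k_spring, f_max = nb$f_max,
                    climbing = isTRUE(nb$climbing))
  imgs <- unclass(path$images)
  write_extxyz(configuration_set(imgs), file.path(out, "neb_path.xyz"))
  utils::write.csv(data.frame(image = seq_along(imgs) - 1L,
                              energy_eV = path$energies),
                   file.path(out, "neb_energies.csv"), row.names = FALSE)
  log(stage = "neb", barrier_eV = max(path$energies) - path$energies[1L],
      converged = path$converged)
  artifacts <- c(artifacts, "neb_path.xyz", "neb_energies.csv", "run.log")
  complete <- TRUE
  invisible(path)
}
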