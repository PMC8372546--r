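## Common energy/force provider interface consumed by MD, minimisation, NEB
## and the validation metrics.

#' Evaluate any potential on a configuration
#'
#' Dispatches over ground truths, fitted GP models, composite (intra+inter)
#' potentials and plain functions returning `list(energy=, forces=)`.
#'
#' @param pot the potential object.
#' @param cfg a `configuration`.
#' @param forces if `FALSE`, implementations may skip force evaluation.
#' @return `list(energy=, forces=)` (forces may be `NULL` when not requested).
#' @export
evaluate_potential <- function(pot, cfg, forces = TRUE) {
  UseMethod("evaluate_potential")
}

#' @export
evaluate_potential.ground_truth <- function(pot, cfg, forces = TRUE) {
  gt_evaluate(pot, cfg)
}

#' @export
evaluate_potential.gp_model <- function(pot, cfg, forces = TRUE) {
  gp_eval(pot, cfg, forces = forces)
}

#' @export
evaluate_potential.composite_potential <- function(pot, cfg, forces = TRUE) {
  composite_evaluate(pot, cfg, forces = forces)
}

#' @export
evaluate_potential.function <- function(pot, cfg, forces = TRUE) {
  pot(cfg)
}

potential_tag <- function(pot) {
  if (inherits(pot, "ground_truth")) pot$level_tag
  else if (inherits(pot, "gp_model")) pot$level_tag
  else if (inherits(pot, "composite_potential")) pot$inter_model$level_tag
  else "potential"
}
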