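# Thin wrapper over the randomized-tree-ensemble learner (ranger). The stage
# models only rely on the bagged-ensemble contract: fit, predict, OOB
# predictions, and split-impurity importances.

# importing (not just ::-calling) ranger guarantees its predict S3 method is
# registered even in sessions that only load fitted models
#' @importFrom ranger ranger
NULL

#' Learner hyperparameters
#'
#' @param ntree number of trees in the bagged ensemble.
#' @param mtry predictors sampled per split (clamped to the schema size at fit
#'   time).
#' @param seed RNG seed for the ensemble.
#' @param min_node minimum terminal-node size. The default of 30 trades a
#'   little tree depth for substantially cheaper fits at the tens-of-thousands
#'   of rows these regressions see, with no measurable loss of out-of-bag
#'   skill.
#' @return a `learner_spec` list.
#' @export
learner_spec <- function(ntree, mtry, seed = 1L, min_node = 30L) {
  if (!is.numeric(ntree) || ntree < 1) stop_field("ntree", "must be >= 1")
  if (!is.numeric(mtry) || mtry < 1) stop_field("mtry", "must be >= 1")
  if (!is.numeric(min_node) || min_node < 1) stop_field("min_node", "must be >= 1")
  structure(list(ntree = as.integer(ntree), mtry = as.integer(mtry),
                 seed = as.integer(seed), min_node = as.integer(min_node)),
            class = "learner_spec")
}

# Fit the ensemble on a named-column data.frame. Returns a fitted_stage_model.
fit_rf <- function(data, target, schema, spec, stage, year,
                   transform = c("identity", "log"), wavelength = NULL) {
  transform <- match.arg(transform)
  stopifnot(all(schema %in% names(data)), length(target) == nrow(data))
  if (anyNA(target)) stop("missing target values", call. = FALSE)
  y <- if (transform == "log") {
    if (any(target <= 0)) stop("nonpositive target under log transform", call. = FALSE)
    log(target)
  } else target
  x <- as.data.frame(data)[, schema, drop = FALSE]
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = spec$ntree,
    mtry = min(spec$mtry, length(schema)),
    seed = spec$seed,
    min.node.size = spec$min_node %||% 30L,
    num.threads = 1L,
    importance = "impurity",
    respect.unordered.factors = "order",
    verbose = FALSE,
    oob.error = TRUE
  )
  structure(list(
    stage = stage, year = as.integer(year), wavelength = wavelength,
    learner = fit, schema = schema, transform = transform,
    spec = spec, oob = fit$predictions, y_train = y, n_train = nrow(x)
  ), class = "fitted_stage_model")
}

#' @export
print.fitted_stage_model <- function(x, ...) {
  cat(sprintf("<fitted_stage_model> stage %s, year %d%s: %d trees, mtry %d, %d predictors, %d rows, %s target\n",
              x$stage, x$year,
              if (!is.null(x$wavelength)) sprintf(", %.2f um", x$wavelength) else "",
              x$spec$ntree, min(x$spec$mtry, length(x$schema)),
              length(x$schema), x$n_train, x$transform))
  invisible(x)
}

# Predict on the model's own scale (log scale for log-transformed targets).
predict_rf <- function(model, data) {
  missing <- setdiff(model$schema, names(data))
  if (length(missing) > 0) {
    stop("predictor schema mismatch; missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(data)[, model$schema, drop = FALSE]
  predict(model$learner, data = x, num.threads = 1L,
          verbose = FALSE)$predictions
}

#' OOB predictions of a fitted stage model on the response scale
#'
#' @param model a `fitted_stage_model`.
#' @return numeric vector aligned to the training rows (back-transformed for
#'   log-target models).
#' @export
oob_predictions <- function(model) {
  if (model$transform == "log") exp(model$oob) else model$oob
}
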