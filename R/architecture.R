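# Two-stage multi-threshold predictor topology: receptive-field
# arithmetic and the stage-1 / stage-2 data flow with pluggable
# per-threshold predictors. No training machinery lives here; predictors
# are injected callables so the flow is testable with mocks.

#' Specification of a stacked convolutional predictor
#'
#' A stack of stride-1 2D convolutions with a common odd square kernel.
#' The reference topology is 7 layers of 5 x 5 filters (6 hidden layers
#' plus the output layer).
#'
#' @param n_layers number of convolutional layers (>= 1)
#' @param kernel odd kernel side length, default 5
#' @return object of class `conv_stack_spec`
#' @export
conv_stack_spec <- function(n_layers, kernel = 5L) {
  n_layers <- as.integer(n_layers)
  kernel <- as.integer(kernel)
  if (is.na(n_layers) || n_layers < 1L) stop("n_layers must be >= 1")
  if (is.na(kernel) || kernel < 1L) stop("kernel must be >= 1")
  if (kernel %% 2L == 0L) stop("kernel must be odd (even kernels have no centre cell)")
  structure(list(n_layers = n_layers, kernel = kernel, stride = 1L),
            class = "conv_stack_spec")
}

#' @export
print.conv_stack_spec <- function(x, ...) {
  cat(sprintf("<conv_stack_spec> %d layers of %dx%d filters (receptive field %dx%d)\n",
              x$n_layers, x$kernel, x$kernel,
              receptive_field(x), receptive_field(x)))
  invisible(x)
}

#' Receptive field of a stacked convolution
#'
#' For stride-1 convolutions with kernel side `k`, each layer widens the
#' set of input cells that can influence one output cell by `k - 1`, so
#' `n` layers see a square of side `1 + n * (k - 1)`. A 7-layer stack of
#' 5 x 5 filters sees 29 x 29; a 13-layer stack sees 53 x 53. The wider
#' the field, the more global the predictor: it can exploit correlations
#' between contacts (e.g. a whole beta-sheet ladder), not just one pair.
#'
#' @param stack a [conv_stack_spec]
#' @return side length of the square receptive field, in input cells
#' @examples
#' receptive_field(conv_stack_spec(7, 5))   # 29
#' receptive_field(conv_stack_spec(13, 5))  # 53
#' @export
receptive_field <- function(stack) {
  stopifnot(inherits(stack, "conv_stack_spec"))
  1L + stack$n_layers * (stack$kernel - 1L)
}

#' Compose two convolutional stacks
#'
#' Feeding one stack's output into another concatenates the layers:
#' layer counts add and the kernel must match.
#'
#' @param stage1,stage2 [conv_stack_spec]s with equal kernels
#' @return the composed [conv_stack_spec]
#' @export
compose_stages <- function(stage1, stage2) {
  stopifnot(inherits(stage1, "conv_stack_spec"), inherits(stage2, "conv_stack_spec"))
  if (stage1$kernel != stage2$kernel) stop("stacked stages must share the kernel size")
  conv_stack_spec(stage1$n_layers + stage2$n_layers, stage1$kernel)
}

#' Two-stage multi-threshold predictor specification
#'
#' Stage 1 holds one model per distance threshold (five by default: 6,
#' 7.5, 8, 8.5, 10 A), producing the discretised distance distribution.
#' Stage 2 holds a single model that consumes the stage-1 stack together
#' with the original features and emits the final 8 A contact map. Each
#' model defaults to the reference 7-layer, 5 x 5 topology.
#'
#' @param thresholds stage-1 distance thresholds in Angstrom, strictly
#'   increasing
#' @param stage2_threshold threshold of the final map, default 8.0
#' @param stack per-model [conv_stack_spec]
#' @return object of class `two_stage_spec`
#' @export
two_stage_spec <- function(thresholds = stage1_thresholds(),
                           stage2_threshold = 8.0,
                           stack = conv_stack_spec(7L, 5L)) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  if (!stage2_threshold %in% thresholds) {
    stop("stage2_threshold should be one of the stage-1 thresholds")
  }
  stopifnot(inherits(stack, "conv_stack_spec"))
  structure(list(thresholds = thresholds,
                 stage2_threshold = as.numeric(stage2_threshold),
                 stack = stack,
                 n_models = length(thresholds) + 1L),
            class = "two_stage_spec")
}

# Validate a predictor's raw output and coerce it into a contact_map:
# must be a numeric L x L matrix in [0, 1]; symmetrised as (M + t(M)) / 2.
as_predicted_map <- function(m, L, threshold, what) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must return a numeric matrix")
  }
  if (nrow(m) != L || ncol(m) != L) {
    stop(sprintf("%s returned a %d x %d matrix, expected %d x %d",
                 what, nrow(m), ncol(m), L, L))
  }
  if (anyNA(m) || min(m) < 0 || max(m) > 1) {
    stop(what, " returned probabilities outside [0, 1]")
  }
  contact_map((m + t(m)) / 2, threshold = threshold)
}

#' Run the two-stage prediction flow
#'
#' Orchestrates the data flow only: each stage-1 predictor maps the
#' feature object to an `L x L` probability matrix at its threshold; the
#' stage-2 predictor receives the (monotonised if requested) stage-1
#' stack plus the original features and returns the final map. The
#' orchestrator is agnostic to whether predictors are trained networks
#' or mocks; it validates shapes and ranges and symmetrises outputs.
#'
#' @param features arbitrary feature object shared by all predictors;
#'   must carry the chain length as `features$L`
#' @param predictors list of `length(spec$thresholds) + 1` functions.
#'   Stage-1 predictors are called as `f(features)`; the last entry is
#'   the stage-2 predictor, called as `f(stack, features)`.
#' @param spec a [two_stage_spec]
#' @param monotonise apply [monotone_project()] to the stage-1 stack
#'   before handing it to stage 2, default `TRUE`
#' @return list with `stack` (the stage-1 [threshold_stack]) and `final`
#'   (the stage-2 [contact_map])
#' @export
run_two_stage <- function(features, predictors, spec = two_stage_spec(),
                          monotonise = TRUE) {
  stopifnot(inherits(spec, "two_stage_spec"))
  if (length(predictors) != spec$n_models) {
    stop(sprintf("expected %d predictors (%d stage-1 + 1 stage-2), got %d",
                 spec$n_models, spec$n_models - 1L, length(predictors)))
  }
  if (!all(vapply(predictors, is.function, logical(1L)))) {
    stop("predictors must be functions")
  }
  L <- features$L
  if (is.null(L)) stop("features must carry the chain length as features$L")
  maps <- lapply(seq_along(spec$thresholds), function(k) {
    as_predicted_map(predictors[[k]](features), L, spec$thresholds[k],
                     sprintf("stage-1 predictor %d (%g A)", k, spec$thresholds[k]))
  })
  stack <- threshold_stack(maps)
  if (monotonise) stack <- monotone_project(stack)
  final_raw <- predictors[[spec$n_models]](stack, features)
  final <- as_predicted_map(final_raw, L, spec$stage2_threshold,
                            "stage-2 predictor")
  list(stack = stack, final = final)
}
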