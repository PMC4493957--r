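# Scoring measures: normalized bias, percentage error, model separation,
# and the model-selection decision rule.

#' Normalized bias of a parameter estimate
#'
#' \code{100 * |estimate - true| / true}, per parameter; at study level the
#' summary is the median of this quantity over noise realizations.
#'
#' @param estimate estimated value(s).
#' @param true_value generating ("true") value(s); must be nonzero.
#' @return Percent bias, vectorized over the inputs.
#' @examples
#' normalized_bias(1.31, 1.0)  # 31
#' @export
normalized_bias <- function(estimate, true_value) {
  if (any(true_value == 0)) stop("true_value must be nonzero")
  abs(estimate - true_value) / abs(true_value) * 100
}

pe_single <- function(values, predicted) {
  denom <- sum(values^2)
  if (denom == 0) stop("all-zero validation subset: percentage error undefined")
  100 * sum((values - predicted)^2) / denom
}

has_values <- function(x) is.list(x) && !is.null(x$values)

#' Percentage prediction error on validation data
#'
#' Per validation subset, the ratio of the prediction-error sum of squares
#' to the data sum of squares, times 100; the scheme-level measure is the
#' mean of the per-subset values over the I validation subsets.
#'
#' @param validation a single \code{odem_subset} or list of subsets.
#' @param predictions matching predicted values: a numeric vector for a
#'   single subset, or a list (matched by position or by subset id) of
#'   numeric vectors or of objects with a \code{values} element.
#' @return A list with \code{per_subset} (named numeric) and \code{mean}.
#' @examples
#' s <- list(id = "a", values = c(3, 4), times = c(0, 1))
#' percentage_error(list(s), list(c(3, 0)))$mean   # 64
#' @export
percentage_error <- function(validation, predictions) {
  if (has_values(validation)) {
    validation <- list(validation)
    predictions <- list(predictions)
  }
  if (length(validation) == 0) stop("at least one validation subset required")
  if (length(validation) != length(predictions))
    stop("one prediction per validation subset required")
  pe <- vapply(seq_along(validation), function(i) {
    pred <- predictions[[i]]
    if (has_values(pred)) pred <- pred$values
    if (length(pred) != length(validation[[i]]$values))
      stop("prediction/data length mismatch for subset ",
           validation[[i]]$id)
    pe_single(validation[[i]]$values, pred)
  }, numeric(1))
  names(pe) <- vapply(validation, function(s)
    if (is.null(s$id)) "" else s$id, "")
  list(per_subset = pe, mean = mean(pe))
}

#' Wrong model-selection decision
#'
#' Model selection between the true and the simplified structure is wrong
#' when the true structure has the larger percentage error
#' (\code{pe_true > pe_simplified}), i.e. the simplified model predicts the
#' validation data better and would be selected.  Ties count as correct.
#'
#' @param pe_true,pe_simplified percentage errors of the two structures.
#' @return Logical, vectorized.
#' @export
wrong_decision <- function(pe_true, pe_simplified) {
  if (any(!is.finite(pe_true)) || any(!is.finite(pe_simplified)))
    stop("percentage errors must be finite")
  pe_true > pe_simplified
}

#' Model separation between two prediction curves
#'
#' The trapezoid-rule area between the Hog1PP curves predicted by the true
#' and the simplified structure, normalized by the maximum of the measured
#' (noisy) values of the corresponding validation subset.  Large separation
#' means the competing structures are easy to tell apart on that subset.
#'
#' @param pred_true,pred_simplified predictions on a common (dense) time
#'   grid: lists with \code{times} and \code{values}, or numeric vectors
#'   (then \code{times} must be given).
#' @param validation the validation \code{odem_subset} providing the
#'   normalizer \code{max(values)}, which must be positive.
#' @param times optional time grid when predictions are plain vectors.
#' @return Normalized area (scalar).
#' @export
model_separation <- function(pred_true, pred_simplified, validation,
                             times = NULL) {
  if (has_values(pred_true)) {
    times <- pred_true$times
    if (has_values(pred_simplified) &&
        !is.null(pred_simplified$times) &&
        !isTRUE(all.equal(times, pred_simplified$times)))
      stop("predictions must share the same time grid")
    pred_true <- pred_true$values
  }
  if (has_values(pred_simplified))
    pred_simplified <- pred_simplified$values
  if (is.null(times)) stop("a time grid is required")
  if (length(pred_true) != length(times) ||
      length(pred_simplified) != length(times))
    stop("predictions and time grid must have equal length")
  mx <- max(validation$values)
  if (mx <= 0) stop("validation subset maximum must be positive")
  pracma::trapz(times, abs(pred_true - pred_simplified)) / mx
}

#' Mean model separation over validation subsets
#'
#' @param pred_true,pred_simplified lists of predictions (one per subset);
#'   plain numeric vectors are taken to be evaluated at the corresponding
#'   validation subset's times.
#' @param validation list of validation subsets.
#' @return A list with \code{per_subset} and \code{mean}.
#' @export
model_separation_mean <- function(pred_true, pred_simplified, validation) {
  dts <- vapply(seq_along(validation), function(i)
    model_separation(pred_true[[i]], pred_simplified[[i]], validation[[i]],
                     times = validation[[i]]$times),
    numeric(1))
  names(dts) <- vapply(validation, function(s)
    if (is.null(s$id)) "" else s$id, "")
  list(per_subset = dts, mean = mean(dts))
}
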