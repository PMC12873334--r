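#' Forecast accuracy metrics: MAE, RMSE, SMAPE
#'
#' Computes the three evaluation metrics over paired actual/predicted values:
#' mean absolute error, root mean squared error, and symmetric mean absolute
#' percentage error, which normalises each absolute error by the mean of
#' `|actual|` and `|predicted|` (in percent, bounded by 200). A term with
#' both actual and predicted equal to zero contributes zero to SMAPE.
#'
#' @param data Data frame holding the paired values.
#' @param truth,estimate Columns of `data` with the actual and predicted
#'   values (bare names or strings).
#' @return One-row tibble with columns `mae`, `rmse`, `smape`, `n`.
#' @examples
#' compute_metrics(data.frame(y = 100, yhat = 50), y, yhat)
#' @export
compute_metrics <- function(data, truth, estimate) {
  y <- data[[rlang::as_name(rlang::ensym(truth))]]
  yhat <- data[[rlang::as_name(rlang::ensym(estimate))]]
  if (length(y) == 0L || length(y) != length(yhat)) {
    kgd_abort("truth and estimate must have equal, non-zero length",
      class = "kgd_error_shape"
    )
  }
  tibble(
    mae = mean(abs(y - yhat)),
    rmse = sqrt(mean((y - yhat)^2)),
    smape = smape_vec(y, yhat),
    n = length(y)
  )
}

# SMAPE in percent with the 0/0 -> 0 convention.
smape_vec <- function(y, yhat) {
  denom <- (abs(y) + abs(yhat)) / 2
  term <- ifelse(denom == 0, 0, abs(y - yhat) / denom)
  100 * mean(term)
}
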