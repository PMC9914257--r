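#' Coefficient of determination
#'
#' `R2 = 1 - SSE / SST` with the total sum of squares taken about the mean of
#' the observed series.
#'
#' @param predicted,observed Equal-length numeric vectors; the observed
#'   values must not all be equal.
#' @return Scalar R-squared.
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("lengths differ")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("R-squared undefined: observed values are constant")
  1 - sum((predicted - observed)^2) / sst
}

#' Adjusted coefficient of determination
#'
#' `adjR2 = 1 - (1 - R2) (D - 1) / (D - (n + 1))`, penalizing the `n + 1`
#' estimated polynomial coefficients so fits of different order are
#' comparable.
#'
#' @param R2 Coefficient of determination.
#' @param D Number of observations (must exceed `n + 1`).
#' @param n Polynomial order.
#' @return Adjusted R-squared.
#' @export
adjusted_r_squared <- function(R2, D, n) {
  if (D <= n + 1) stop("adjusted R-squared requires D > n + 1")
  1 - (1 - R2) * (D - 1) / (D - (n + 1))
}

#' Root-mean-square error
#'
#' @param predicted,observed Equal-length numeric vectors (nonempty).
#' @return `sqrt(mean((predicted - observed)^2))`; equals `sqrt(J)` of the
#'   fitness at the same coefficients.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("lengths differ")
  if (length(predicted) < 1L) stop("empty series")
  sqrt(mean((predicted - observed)^2))
}

#' Fit metrics for one candidate order
#'
#' @param predicted,observed Equal-length series.
#' @param n Polynomial order of the candidate.
#' @return List with `n`, `D`, `R2`, `adjR2`, `RMSE`.
#' @export
fit_metrics <- function(predicted, observed, n) {
  D <- length(observed)
  R2 <- r_squared(predicted, observed)
  list(n = as.integer(n), D = D, R2 = R2,
       adjR2 = adjusted_r_squared(R2, D, n),
       RMSE = rmse(predicted, observed))
}

#' Select the polynomial order
#'
#' Picks the candidate with the largest adjusted R-squared; ties go to the
#' smaller order (parsimony), then to the smaller RMSE.
#'
#' @param metrics `data.frame` (or list of lists) with columns/fields `n`,
#'   `adjR2`, `RMSE`.
#' @return The chosen order (integer).
#' @export
select_order <- function(metrics) {
  if (is.data.frame(metrics)) {
    df <- metrics
  } else {
    df <- do.call(rbind, lapply(metrics, function(m)
      data.frame(n = m$n, adjR2 = m$adjR2, RMSE = m$RMSE)))
  }
  if (nrow(df) < 1L) stop("no candidate fits")
  ord <- order(-df$adjR2, df$n, df$RMSE)
  as.integer(df$n[ord[1L]])
}

#' Fit several polynomial orders and compare them
#'
#' Fits each order with [mlffpe_fit()] (seeding each fit from `cfg$seed +
#' order` so candidates are independent but reproducible), computes R2,
#' adjusted R2 and RMSE on the training data, and applies [select_order()].
#'
#' @param S,MR Training series.
#' @param orders Integer vector of candidate orders (default `1:3`).
#' @param cfg An [evolution_config()].
#' @return List with `fits` (named by order), `metrics` (`data.frame`
#'   mirroring the usual report table: n, coefficients, R2, adjR2, RMSE),
#'   and `selected` (the chosen order).
#' @export
fit_orders <- function(S, MR, orders = 1:3, cfg = evolution_config()) {
  fits <- list()
  rows <- list()
  for (n in orders) {
    cfg_n <- cfg
    if (!is.null(cfg$seed)) cfg_n$seed <- cfg$seed + as.integer(n)
    fit <- mlffpe_fit(S, MR, n, cfg_n)
    m <- fit_metrics(predict_mr(fit$coefficients, S), MR, n)
    fits[[as.character(n)]] <- fit
    rows[[as.character(n)]] <- data.frame(
      n = as.integer(n),
      coefficients = paste(sprintf("%.4f", fit$coefficients), collapse = " "),
      R2 = m$R2, adjR2 = m$adjR2, RMSE = m$RMSE)
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(fits = fits, metrics = metrics, selected = select_order(metrics))
}

#' Plain-text report table of candidate fits
#'
#' @param metrics The `metrics` data.frame from [fit_orders()].
#' @param digits Decimal places for the metric columns (default 4, the usual
#'   reporting precision).
#' @return Character vector of report lines (also printed).
#' @export
format_report <- function(metrics, digits = 4) {
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  lines <- c(
    sprintf("%-3s %-45s %-8s %-8s %-8s", "n", "coefficients (a0..an)", "R2", "adjR2", "RMSE"),
    sprintf("%-3d %-45s %-8s %-8s %-8s", metrics$n, metrics$coefficients,
            fmt(metrics$R2), fmt(metrics$adjR2), fmt(metrics$RMSE)))
  cat(lines, sep = "\n")
  invisible(lines)
}
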