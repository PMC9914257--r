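#' Dry-basis moisture content
#'
#' `MC = (m - m_d) / m_d`, grams of water per gram of dry matter.
#'
#' @param m Sample mass in grams (vectorized).
#' @param m_d Dry-matter mass in grams (> 0).
#' @return Moisture content in g/g (dry basis).
#' @export
moisture_content <- function(m, m_d) {
  if (m_d <= 0) stop("dry-matter mass must be positive")
  if (any(m < m_d)) stop("mass below dry-matter mass gives negative moisture")
  (m - m_d) / m_d
}

#' Moisture ratio from a moisture-content series
#'
#' `MR(t) = MC(t) / MC(0)`: dimensionless, exactly 1 at the first sample,
#' invariant to rescaling all moisture contents by a positive constant.
#'
#' @param mc Numeric vector of dry-basis moisture contents, `mc[1] > 0`.
#' @return Numeric vector of moisture ratios.
#' @export
moisture_ratio <- function(mc) {
  if (length(mc) < 1L) stop("empty moisture-content series")
  if (mc[1L] <= 0) stop("initial moisture content must be positive")
  mc / mc[1L]
}

#' Information (regressor) vector of the polynomial model
#'
#' The moisture ratio is modelled as an order-`n` polynomial in shrinkage,
#' so each observation contributes the regressor `[1, S, S^2, ..., S^n]`.
#'
#' @param S Shrinkage value (scalar).
#' @param n Polynomial order (>= 1).
#' @return Numeric vector of length `n + 1`.
#' @export
phi <- function(S, n) {
  if (n < 1L) stop("polynomial order must be >= 1")
  S^(0:n)
}

# D x (n+1) design matrix [1, S, ..., S^n] for a shrinkage vector
design_matrix <- function(S, n) {
  outer(S, 0:n, `^`)
}

#' Predict moisture ratio from shrinkage
#'
#' Evaluates `MR_hat = a0 + a1 S + ... + an S^n` by Horner's scheme.
#'
#' @param alpha Coefficient vector `(a0, ..., an)`, lowest order first.
#' @param S Shrinkage values (vectorized).
#' @return Predicted moisture ratios.
#' @export
predict_mr <- function(alpha, S) {
  if (length(alpha) < 2L) stop("coefficient vector must have length >= 2 (order >= 1)")
  acc <- rep(alpha[length(alpha)], length(S))
  for (q in rev(seq_len(length(alpha) - 1L))) {
    acc <- acc * S + alpha[q]
  }
  acc
}

#' Read a drying series CSV
#'
#' Expected columns: `time_min`, optionally `mass_g`, `shrinkage` and/or
#' `moisture_ratio` (extra columns pass through).
#'
#' @param path CSV path.
#' @param require Character vector of column names that must be present.
#' @return `data.frame`.
#' @export
read_series <- function(path, require = c("time_min")) {
  if (!file.exists(path)) stop("series file not found: ", path)
  df <- utils::read.csv(path)
  missing_cols <- setdiff(require, names(df))
  if (length(missing_cols)) {
    stop("series file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), " (schema error)")
  }
  df
}

#' Write a drying series CSV
#' @param df `data.frame` of the series.
#' @param path Output path.
#' @export
write_series <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a fitted model file
#'
#' JSON with the polynomial order, coefficients, fit metrics and provenance
#' (seed and evolution settings), so a fit can be reloaded for prediction.
#'
#' @param fit An `mlffpe_fit` (see [mlffpe_fit()]).
#' @param path Output JSON path.
#' @param metrics Optional named list of fit metrics to embed.
#' @export
write_model <- function(fit, path, metrics = NULL) {
  obj <- list(
    order = fit$order,
    coefficients = fit$coefficients,
    J = fit$J,
    sigma2 = fit$sigma2,
    metrics = metrics,
    config = fit$config[c("population_size", "max_generations", "scale_factor",
                          "crossover_rate", "init_low", "init_high", "seed")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a fitted model file
#' @param path JSON path written by [write_model()].
#' @return List with `order`, `coefficients`, `J`, `sigma2`, `metrics`, `config`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$order) || is.null(obj$coefficients)) {
    stop("model file ", path, " lacks order/coefficients")
  }
  if (length(obj$coefficients) != obj$order + 1L) {
    stop("model file ", path, ": coefficient count ", length(obj$coefficients),
         " does not match order ", obj$order)
  }
  obj
}
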