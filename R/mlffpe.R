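#' Configuration of the population-evolution fitter
#'
#' The estimator evolves a population of candidate coefficient vectors by
#' differential mutation, binomial crossover and greedy selection under the
#' maximum-likelihood fitness (mean squared residual). The scale factor and
#' crossover rate follow standard differential-evolution practice
#' (`F = 0.5`, `CR = 0.9`); population size 30 and 20 generations are the
#' drying-study defaults, though many more generations are needed to reach
#' the least-squares optimum tightly.
#'
#' @param population_size Individuals per generation `P` (>= 4; mutation
#'   needs three donors distinct from the target).
#' @param max_generations Number of evolution generations (>= 1).
#' @param scale_factor Mutation scale `F` > 0.
#' @param crossover_rate Crossover probability `CR` in \[0, 1\].
#' @param init_low,init_high Bounds of the uniform initialization range.
#'   Mutants may leave this range (no clamping), but greedy selection loses
#'   population diversity while migrating, so reliable convergence requires
#'   the range to cover the plausible coefficient scale. Fitted drying
#'   cubics have coefficients of magnitude up to ~12, hence the default
#'   \[-15, 15); the narrow \[0, 1) unit-uniform initialization some studies
#'   quote is available but prone to premature population collapse at
#'   `F = 0.5` when the optimum lies far outside it.
#' @param seed Optional integer seed making a fit reproducible.
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(population_size = 30L, max_generations = 20L,
                             scale_factor = 0.5, crossover_rate = 0.9,
                             init_low = -15, init_high = 15, seed = NULL) {
  if (population_size < 4L) {
    stop("population_size must be >= 4 (mutation draws three distinct donors)")
  }
  if (max_generations < 1L) stop("max_generations must be >= 1")
  if (scale_factor <= 0) stop("scale_factor must be positive")
  if (crossover_rate < 0 || crossover_rate > 1) stop("crossover_rate must lie in [0, 1]")
  if (init_high < init_low) stop("init_high must be >= init_low")
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 scale_factor = scale_factor, crossover_rate = crossover_rate,
                 init_low = init_low, init_high = init_high,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "evolution_config")
}

#' Initialize the population matrix
#'
#' Draws a `P x Q` matrix of i.i.d. uniforms on
#' `[init_low, init_high)` (use `init_low = 0, init_high = 1` for the
#' classic unit-uniform start) from the current RNG stream (set the seed before
#' calling, or use [mlffpe_fit()] which seeds once and documents the draw
#' order). The matrix is filled column-major from a single `runif(P * Q)`
#' call.
#'
#' @param cfg An [evolution_config()].
#' @param Q Number of coefficients (polynomial order + 1).
#' @return `P x Q` numeric matrix; one row per individual.
#' @export
init_population <- function(cfg, Q) {
  stopifnot(inherits(cfg, "evolution_config"), Q >= 1L)
  if (cfg$init_low == cfg$init_high) {
    warning("degenerate initialization range: constant population")
  }
  matrix(stats::runif(cfg$population_size * Q, cfg$init_low, cfg$init_high),
         nrow = cfg$population_size, ncol = Q)
}

#' Differential mutation of three donor individuals
#'
#' `mutant = x1 + F * (x2 - x3)`. No bound handling: mutants may leave the
#' initialization range, which is how the search reaches coefficients far
#' outside \[0, 1) (the fitted drying cubics have coefficients of magnitude
#' ~4--12).
#'
#' @param x1,x2,x3 Donor coefficient vectors of equal length.
#' @param F Scale factor > 0 (or 0, which returns `x1`).
#' @return Mutant vector.
#' @export
de_mutate <- function(x1, x2, x3, F) {
  x1 + F * (x2 - x3)
}

# Draw (r1, r2, r3): uniform on {1..P}, mutually distinct and != p,
# by rejection from the current RNG stream.
draw_donor_indices <- function(P, p) {
  repeat {
    r <- sample.int(P, 3L, replace = TRUE)
    if (r[1L] != r[2L] && r[1L] != r[3L] && r[2L] != r[3L] && all(r != p)) return(r)
  }
}

#' Binomial crossover of target and mutant
#'
#' Entry `q` of the trial vector comes from the mutant when `u[q] < CR` or
#' `q == q_rand`, else from the target; `q_rand` guarantees the trial
#' inherits at least one mutant coordinate.
#'
#' @param target,mutant Vectors of equal length `Q`.
#' @param CR Crossover rate in \[0, 1\].
#' @param q_rand Guaranteed mutant index in `1..Q`.
#' @param u Uniform draws of length `Q`; by default taken from the current
#'   RNG stream (exposed as an argument for testing).
#' @return Trial vector.
#' @export
crossover <- function(target, mutant, CR, q_rand,
                      u = stats::runif(length(target))) {
  Q <- length(target)
  stopifnot(length(mutant) == Q, length(u) == Q, q_rand >= 1L, q_rand <= Q)
  take <- u < CR
  take[q_rand] <- TRUE
  ifelse(take, mutant, target)
}

#' Maximum-likelihood fitness of a coefficient vector
#'
#' `J(alpha) = mean((MR - Phi alpha)^2)`: the mean squared residual of the
#' polynomial model. Under i.i.d. zero-mean Gaussian observation noise,
#' minimizing `J` maximizes the Gaussian likelihood, so this mean square is
#' the fitness the evolution minimizes.
#'
#' @param alpha Coefficient vector `(a0, ..., an)`.
#' @param S,MR Equal-length shrinkage and moisture-ratio series.
#' @return Scalar fitness `J >= 0`.
#' @export
mlff <- function(alpha, S, MR) {
  if (length(S) != length(MR)) stop("S and MR must have equal length")
  if (length(S) < 1L) stop("empty series")
  mean((MR - predict_mr(alpha, S))^2)
}

#' Greedy selection between target and trial
#'
#' The trial replaces the target only when its fitness is strictly smaller;
#' ties keep the incumbent.
#'
#' @param target,trial Coefficient vectors.
#' @param J_target,J_trial Their fitness values on the same data.
#' @return The surviving vector.
#' @export
de_select <- function(target, trial, J_target, J_trial) {
  if (J_trial < J_target) trial else target
}

#' Maximum-likelihood estimate of the noise variance
#'
#' The residual variance that maximizes the Gaussian log-likelihood is the
#' mean squared residual, identical to [mlff()] at the same coefficients.
#'
#' @param residuals Numeric vector of residuals.
#' @return `sigma2_hat = mean(residuals^2)`.
#' @export
sigma2_mle <- function(residuals) {
  if (length(residuals) < 1L) stop("empty residual vector")
  mean(residuals^2)
}

#' Profiled Gaussian log-likelihood up to a constant
#'
#' After profiling out the noise variance, the log-likelihood is
#' `const - (D/2) log J`; the constant is dropped, so returned values are
#' comparable across coefficient vectors on the same data only.
#'
#' @param J Mean squared residual (> 0; `J = 0` returns `Inf` with attribute
#'   `perfect_fit = TRUE`).
#' @param D Number of observations.
#' @return Relative log-likelihood `-(D/2) * log(J)`.
#' @export
log_likelihood <- function(J, D) {
  if (J < 0) stop("J must be nonnegative")
  if (J == 0) return(structure(Inf, perfect_fit = TRUE))
  -(D / 2) * log(J)
}

#' Fit the polynomial moisture-ratio model by population evolution
#'
#' Runs `max_generations` generations of differential mutation, binomial
#' crossover and greedy selection over the whole population, minimizing the
#' maximum-likelihood fitness [mlff()]. Generations are synchronous: donors
#' and targets all come from the previous generation's population. The best
#' individual is recomputed over the final population, not kept in a
#' separate archive.
#'
#' RNG draw order per generation, per individual `p = 1..P`: donor indices by
#' rejection, then `q_rand`, then `Q` crossover uniforms; initialization uses
#' one `runif(P * Q)` call before the first generation. With a fixed
#' `cfg$seed` the whole fit is bit-reproducible.
#'
#' @param S,MR Equal-length shrinkage and moisture-ratio vectors (finite).
#' @param n Polynomial order (>= 1).
#' @param cfg An [evolution_config()].
#' @return An `mlffpe_fit` list: `coefficients`, `J`, `sigma2` (= `J`),
#'   `trace` (best fitness per generation, length `max_generations + 1`
#'   including the initial population), `order`, `D`, `config`.
#' @export
mlffpe_fit <- function(S, MR, n, cfg = evolution_config()) {
  stopifnot(inherits(cfg, "evolution_config"))
  if (length(S) != length(MR)) stop("S and MR must have equal length")
  if (!all(is.finite(S)) || !all(is.finite(MR))) stop("non-finite data rejected")
  D <- length(S)
  Q <- n + 1L
  if (D < Q) warning("fewer observations (", D, ") than parameters (", Q,
                     "): under-determined fit")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  P <- cfg$population_size
  Phi <- design_matrix(S, n)
  pop <- init_population(cfg, Q)
  J_pop <- colMeans((MR - tcrossprod(Phi, pop))^2)
  trace <- numeric(cfg$max_generations + 1L)
  trace[1L] <- min(J_pop)
  for (gen in seq_len(cfg$max_generations)) {
    new_pop <- pop
    new_J <- J_pop
    for (p in seq_len(P)) {
      r <- draw_donor_indices(P, p)
      mutant <- de_mutate(pop[r[1L], ], pop[r[2L], ], pop[r[3L], ], cfg$scale_factor)
      q_rand <- sample.int(Q, 1L)
      trial <- crossover(pop[p, ], mutant, cfg$crossover_rate, q_rand)
      J_trial <- mean((MR - drop(Phi %*% trial))^2)
      if (J_trial < J_pop[p]) {
        new_pop[p, ] <- trial
        new_J[p] <- J_trial
      }
    }
    pop <- new_pop
    J_pop <- new_J
    trace[gen + 1L] <- min(J_pop)
  }
  best <- which.min(J_pop)
  structure(list(coefficients = pop[best, ], J = J_pop[best], sigma2 = J_pop[best],
                 trace = trace, order = as.integer(n), D = D, config = cfg),
            class = "mlffpe_fit")
}

#' @export
print.mlffpe_fit <- function(x, ...) {
  cat("Polynomial moisture-ratio model (population-evolution fit)\n")
  cat("  order:       ", x$order, "\n")
  cat("  coefficients:", paste(sprintf("%.4f", x$coefficients), collapse = ", "), "\n")
  cat("  J (MSE):     ", format(x$J, digits = 6), " over D =", x$D, "samples\n")
  invisible(x)
}
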