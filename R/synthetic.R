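#' Specification of a synthetic drying experiment
#'
#' Describes the desk-scale fixtures the package tests itself on: a
#' microwave-drying run of six 25 mm cylindrical slices photographed from
#' above every 30 s for about 41 minutes (83 samples), with the moisture
#' ratio decaying exponentially from 1 to the stopping value and shrinkage
#' tied to moisture ratio through a known monotone cubic.
#'
#' The default cubic was built from a strictly positive derivative,
#' `p'(S) = 10 (S - 0.35)^2 + 0.103`, integrated and anchored so that
#' `p(1) = 1` exactly (initial condition `MR(0) = S(0) = 1`) and
#' `p(0.35)` equals the final moisture ratio: shrinkage therefore spans
#' about \[0.35, 1\] over the run, the curve is steep near `S = 1` and flat
#' near the floor (the shape drying studies report), and the order-3 design
#' on the simulated shrinkage stays well-conditioned. The generator rejects
#' any `true_alpha` that is not strictly increasing on `[s_floor, 1]`, whose
#' `p(1)` differs from 1, or whose value at `s_floor` exceeds the final
#' moisture ratio (the inversion bracket would fail).
#'
#' @param duration Drying time in minutes (default 41).
#' @param sample_period Sampling period in minutes (default 0.5, i.e. 30 s);
#'   the series has `duration / sample_period + 1` samples (83 by default).
#' @param mr_final Final moisture ratio; default `0.176 / 9.87` (stopping
#'   moisture content over initial moisture content, both dry basis).
#' @param true_alpha Coefficients `(a0..an)` of the monotone polynomial
#'   linking moisture ratio to shrinkage, `MR = p(S)`.
#' @param noise_sigma Standard deviation of the additive zero-mean Gaussian
#'   observation noise on MR (default 0.02, in MR units).
#' @param canvas Image size `c(rows, cols)` in pixels (default 280 x 400).
#' @param radius0 Initial slice radius in pixels (default 40, i.e. 3.2 px/mm
#'   for a 12.5 mm slice radius; the scale is arbitrary since shrinkage is a
#'   ratio, but larger disks keep the rasterized area ratio within a fraction
#'   of a percent of the true one).
#' @param centers 6 x 2 matrix of disk centers `(row, col)`; defaults to a
#'   2 x 3 grid with ample spacing. Disks may never touch.
#' @param fg,bg Foreground/background intensities (default 200 / 40).
#' @param pixel_noise_sigma Gaussian luminance noise on rendered frames, in
#'   intensity units (default 0: clean frames).
#' @param per_disk_scale Optional length-6 positive multipliers of the
#'   initial radius (mild slice-size heterogeneity; all 1 by default).
#' @param s_floor Lower bracket of the polynomial inversion (default 0.3).
#' @param seed Integer seed driving all randomness (default 1).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(duration = 41, sample_period = 0.5,
                            mr_final = 0.176 / 9.87,
                            true_alpha = c(-0.1610, 1.3277, -3.5000, 3.3333),
                            noise_sigma = 0.02,
                            canvas = c(280L, 400L), radius0 = 40,
                            centers = NULL, fg = 200L, bg = 40L,
                            pixel_noise_sigma = 0,
                            per_disk_scale = rep(1, 6),
                            s_floor = 0.3, seed = 1L) {
  if (duration < 0 || sample_period <= 0) stop("invalid duration/sample_period")
  if (mr_final <= 0 || mr_final >= 1) stop("mr_final must lie in (0, 1)")
  if (length(true_alpha) < 2L) stop("true_alpha must describe an order >= 1 polynomial")
  if (s_floor <= 0 || s_floor >= 1) stop("s_floor must lie in (0, 1)")
  # boundary and monotonicity checks on the MR--S link
  p1 <- predict_mr(true_alpha, 1)
  if (abs(p1 - 1) > 1e-8) {
    stop("true polynomial must satisfy p(1) = 1 (got p(1) = ", signif(p1, 6),
         "); shift the intercept so MR(0) = S(0) = 1")
  }
  grid <- seq(s_floor, 1, length.out = 2048L)
  deriv <- derivative_coefficients(true_alpha)
  if (any(predict_mr_any(deriv, grid) <= 0)) {
    stop("true polynomial is not strictly increasing on [", s_floor,
         ", 1] (monotonicity error)")
  }
  if (predict_mr(true_alpha, s_floor) >= mr_final) {
    stop("p(s_floor) must fall below mr_final so the inversion brackets the root")
  }
  if (is.null(centers)) {
    centers <- as.matrix(expand.grid(row = c(70, 210), col = c(70, 200, 330)))
  }
  if (nrow(centers) != 6L) stop("expected 6 disk centers")
  if (length(per_disk_scale) != 6L || any(per_disk_scale <= 0)) {
    stop("per_disk_scale must be 6 positive multipliers")
  }
  rmax <- radius0 * max(per_disk_scale)
  d <- as.matrix(stats::dist(centers))
  diag(d) <- Inf
  if (min(d) <= 2 * rmax + 2) stop("disks would overlap (layout error)")
  if (any(centers[, 1] < rmax + 2) || any(centers[, 1] > canvas[1] - rmax - 1) ||
      any(centers[, 2] < rmax + 2) || any(centers[, 2] > canvas[2] - rmax - 1)) {
    stop("disks would leave the canvas (layout error)")
  }
  structure(list(duration = duration, sample_period = sample_period,
                 mr_final = mr_final, true_alpha = true_alpha,
                 noise_sigma = noise_sigma, canvas = as.integer(canvas),
                 radius0 = radius0, centers = centers,
                 fg = as.integer(fg), bg = as.integer(bg),
                 pixel_noise_sigma = pixel_noise_sigma,
                 per_disk_scale = per_disk_scale,
                 s_floor = s_floor, seed = as.integer(seed)),
            class = "simulation_spec")
}

# coefficients of p'(x) given coefficients of p(x), lowest order first
derivative_coefficients <- function(alpha) {
  n <- length(alpha) - 1L
  alpha[-1L] * seq_len(n)
}

# Horner evaluation tolerating length-1 coefficient vectors (predict_mr
# insists on order >= 1 for the user-facing model).
predict_mr_any <- function(alpha, x) {
  if (length(alpha) == 1L) return(rep(alpha, length(x)))
  predict_mr(alpha, x)
}

# invert MR = p(S) for one MR value by bisection on [lo, 1]
invert_polynomial <- function(alpha, mr, lo, tol = 1e-10) {
  hi <- 1
  f_lo <- predict_mr(alpha, lo) - mr
  f_hi <- predict_mr(alpha, hi) - mr
  if (f_lo > 0 || f_hi < 0) stop("moisture ratio outside the invertible range")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (predict_mr(alpha, mid) - mr <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a drying run with ground truth
#'
#' The true moisture ratio follows `MR(t) = exp(-k t)` with `k` chosen so the
#' run ends at `mr_final` after `duration` minutes; the true shrinkage is
#' obtained by inverting the monotone polynomial `MR = p(S)` (bisection to
#' 1e-10); the observed moisture ratio adds seeded zero-mean Gaussian noise.
#'
#' @param spec A [simulation_spec()].
#' @return A `drying_truth` list: `series` (`data.frame` with `time_min`,
#'   `s_true`, `mr_true`, `mr_noisy`), `true_alpha`, `spec`.
#' @export
simulate_series <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  times <- seq(0, spec$duration, by = spec$sample_period)
  k <- if (spec$duration > 0) -log(spec$mr_final) / spec$duration else 0
  mr_true <- exp(-k * times)
  s_true <- vapply(mr_true, function(mr)
    invert_polynomial(spec$true_alpha, mr, spec$s_floor), numeric(1))
  s_true[1L] <- 1   # p(1) = 1 holds by construction; pin the boundary exactly
  set.seed(spec$seed)
  mr_noisy <- mr_true + stats::rnorm(length(times), 0, spec$noise_sigma)
  structure(list(series = data.frame(time_min = times, s_true = s_true,
                                     mr_true = mr_true, mr_noisy = mr_noisy),
                 true_alpha = spec$true_alpha, spec = spec),
            class = "drying_truth")
}

# paint one disk into an integer canvas matrix
paint_disk <- function(canvas, cy, cx, r, value) {
  rows <- max(1L, floor(cy - r)):min(nrow(canvas), ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(ncol(canvas), ceiling(cx + r))
  inside <- outer((rows - cy)^2, (cols - cx)^2, `+`) <= r^2
  sub <- canvas[rows, cols]
  sub[inside] <- value
  canvas[rows, cols] <- sub
  canvas
}

#' Render the image stack of a simulated run
#'
#' Each frame shows six rasterized disks (no anti-aliasing) on a dark
#' background; disk radii scale with the square root of the true shrinkage so
#' summed pixel areas track the true area ratio. Optional Gaussian luminance
#' noise is added after rasterization (seeded from `spec$seed + 1`).
#'
#' @param truth A `drying_truth` from [simulate_series()].
#' @param rgb If `TRUE`, frames are `h x w x 3` arrays with identical
#'   channels (the 24-bit camera format); default grayscale matrices.
#' @return List with `frames` (list of integer images) and `areas`
#'   (clean rendered pixel counts per frame).
#' @export
render_frames <- function(truth, rgb = FALSE) {
  stopifnot(inherits(truth, "drying_truth"))
  spec <- truth$spec
  set.seed(spec$seed + 1L)
  s <- truth$series$s_true
  base <- matrix(spec$bg, spec$canvas[1L], spec$canvas[2L])
  frames <- vector("list", length(s))
  areas <- integer(length(s))
  for (i in seq_along(s)) {
    canvas <- base
    radii <- spec$radius0 * spec$per_disk_scale * sqrt(s[i])
    if (any(radii <= 1)) stop("disk radius collapsed below 1 px; increase radius0")
    for (d in 1:6) {
      canvas <- paint_disk(canvas, spec$centers[d, 1L], spec$centers[d, 2L],
                           radii[d], spec$fg)
    }
    areas[i] <- sum(canvas == spec$fg)
    if (spec$pixel_noise_sigma > 0) {
      canvas <- canvas + round(stats::rnorm(length(canvas), 0, spec$pixel_noise_sigma))
      canvas <- pmin(pmax(canvas, 0L), 255L)
    }
    storage.mode(canvas) <- "integer"
    if (rgb) {
      canvas <- array(rep(canvas, 3L), dim = c(dim(canvas), 3L))
      storage.mode(canvas) <- "integer"
    }
    frames[[i]] <- canvas
  }
  list(frames = frames, areas = areas)
}

#' Write a rendered fixture to disk
#'
#' Produces a directory with `frames/frame_NNNN.png`, a `manifest.csv`
#' (`time_min`, `filename`), a fit-ready `truth.csv` (`time_min`,
#' `shrinkage` = true S, `moisture_ratio` = noisy MR, `mr_true`, `area_px`)
#' and a `spec.json` echo. Reruns with the same spec are byte-identical.
#'
#' @param truth A `drying_truth`.
#' @param out_dir Output directory (created if needed).
#' @param frames Optional pre-rendered result of [render_frames()]; rendered
#'   on the fly when `NULL`.
#' @return The manifest `data.frame`, invisibly.
#' @export
write_fixture <- function(truth, out_dir, frames = NULL) {
  stopifnot(inherits(truth, "drying_truth"))
  if (is.null(frames)) frames <- render_frames(truth)
  dir.create(file.path(out_dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  fnames <- sprintf("frames/frame_%04d.png", seq_along(frames$frames))
  for (i in seq_along(frames$frames)) {
    png::writePNG(frames$frames[[i]] / 255, file.path(out_dir, fnames[i]))
  }
  manifest <- data.frame(time_min = truth$series$time_min, filename = fnames)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  truth_df <- data.frame(time_min = truth$series$time_min,
                         shrinkage = truth$series$s_true,
                         moisture_ratio = truth$series$mr_noisy,
                         mr_true = truth$series$mr_true,
                         area_px = frames$areas)
  utils::write.csv(truth_df, file.path(out_dir, "truth.csv"), row.names = FALSE)
  spec_echo <- truth$spec
  spec_echo$centers <- apply(spec_echo$centers, 1, function(rc) list(row = rc[1], col = rc[2]))
  jsonlite::write_json(unclass(spec_echo), file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
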