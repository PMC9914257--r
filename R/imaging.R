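#' Convert an RGB frame to 8-bit grayscale
#'
#' Averages the three colour planes and rounds the exact mean to the nearest
#' integer (round-half-to-even), clipping to \[0, 255\]. This mirrors the
#' plain channel average used by machine-vision toolkits rather than a
#' luma-weighted conversion.
#'
#' @param img An integer array of dimension `height x width x 3` with values
#'   in \[0, 255\].
#' @return An integer matrix (`height x width`) of grayscale intensities in
#'   \[0, 255\].
#' @examples
#' px <- array(c(10, 20, 31), dim = c(1, 1, 3))
#' to_grayscale(px) # 20
#' @export
to_grayscale <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L) {
    stop("to_grayscale() expects a height x width x 3 RGB array; got ",
         paste(dim(img), collapse = " x "), " (channel-count error)")
  }
  if (min(img) < 0 || max(img) > 255) {
    stop("RGB intensities must lie in [0, 255]")
  }
  g <- round((img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3)
  g <- matrix(pmin(pmax(g, 0), 255), dim(img)[1L], dim(img)[2L])
  storage.mode(g) <- "integer"
  g
}

# 256-bin histogram of an integer grayscale matrix (bins 0..255)
gray_histogram <- function(img) {
  tabulate(as.integer(img) + 1L, nbins = 256L)
}

#' Automatic clustering threshold of a grayscale image
#'
#' Computes a global integer threshold on the intensity histogram.
#' The default `"intermeans"` method is the Ridler--Calvard iterative
#' intermeans (two-cluster histogram k-means) fixed point: starting from the
#' overall mean, the threshold is repeatedly replaced by the rounded mean of
#' the two class means (classes `<= T` and `> T`) until it stops changing.
#' `"otsu"` instead maximizes the between-class variance over all integer
#' split points, taking the smallest maximizer on ties.
#'
#' @param img Integer grayscale matrix with values in \[0, 255\].
#' @param method `"intermeans"` (default) or `"otsu"`.
#' @return An integer threshold in \[0, 255\]. For a constant image the
#'   constant intensity is returned with a degenerate-histogram warning.
#' @export
cluster_threshold <- function(img, method = c("intermeans", "otsu")) {
  method <- match.arg(method)
  if (length(img) < 1L) stop("image must contain at least one pixel")
  h <- gray_histogram(img)
  levels <- 0:255
  if (sum(h > 0) == 1L) {
    warning("degenerate histogram: constant image; returning the constant intensity")
    return(which(h > 0) - 1L)
  }
  if (method == "otsu") return(otsu_threshold(h))
  total <- sum(as.numeric(h))
  thr <- as.integer(round(sum(levels * h) / total))
  for (it in 1:256) {
    lo <- levels <= thr
    n1 <- sum(h[lo]); n2 <- total - n1
    if (n1 == 0 || n2 == 0) {
      # all mass on one side of the split; nudge toward the data
      thr <- as.integer(round(sum(levels * h) / total))
      break
    }
    m1 <- sum(levels[lo] * h[lo]) / n1
    m2 <- sum(levels[!lo] * h[!lo]) / n2
    new_thr <- as.integer(round((m1 + m2) / 2))
    if (new_thr == thr) break
    thr <- new_thr
  }
  thr
}

# Otsu on a 256-bin histogram: argmax over t of between-class variance for the
# split (<= t, > t); smallest t on ties.
otsu_threshold <- function(h) {
  levels <- 0:255
  total <- sum(as.numeric(h))
  w1 <- cumsum(h) / total
  mu1 <- cumsum(levels * h) / total            # unnormalized class-1 mean * w1
  mu_tot <- mu1[256L]
  w2 <- 1 - w1
  valid <- w1 > 0 & w2 > 0
  sigma_b <- rep(-Inf, 256L)
  sigma_b[valid] <- (mu_tot * w1[valid] - mu1[valid])^2 / (w1[valid] * w2[valid])
  as.integer(which.max(sigma_b) - 1L)
}

#' Binarize a grayscale image at a threshold
#'
#' With `bright_foreground = TRUE` (the default: lit slices on a dark cavity
#' floor) foreground pixels are those *strictly greater* than the threshold;
#' otherwise foreground is `<= thr`. The strict inequality matters because
#' clustering thresholds are integers.
#'
#' @param img Integer grayscale matrix.
#' @param thr Integer threshold in \[0, 255\].
#' @param bright_foreground Logical; polarity of the foreground.
#' @return Logical matrix (`TRUE` = foreground).
#' @export
binarize <- function(img, thr, bright_foreground = TRUE) {
  if (thr < 0 || thr > 255) stop("threshold must lie in [0, 255]")
  if (bright_foreground) img > thr else img <= thr
}

#' Fill holes in a binary mask
#'
#' A hole is a background region not 4-connected to the image border.
#' All such regions become foreground; foreground pixels are never removed,
#' so the operation is monotone and idempotent.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  storage.mode(mask) <- "logical"
  if (!any(!mask)) return(mask)
  bg <- EBImage::bwlabel(!mask)   # 4-connectivity components of the background
  border_labels <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

# 8-connectivity labeling: EBImage::bwlabel (4-connectivity) followed by a
# union-find merge of diagonally adjacent label pairs. Final labels are
# consecutive integers ordered by each component's first pixel in R's
# column-major scan.
label_particles <- function(mask) {
  storage.mode(mask) <- "logical"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab > 1L) {
    n <- nrow(lab); m <- ncol(lab)
    a1 <- lab[-n, -m]; b1 <- lab[-1L, -1L]   # down-right diagonal
    a2 <- lab[-n, -1L]; b2 <- lab[-1L, -m]   # down-left diagonal
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs)) {
      parent <- seq_len(nlab)
      find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
      for (i in seq_len(nrow(pairs))) {
        ra <- find(pairs[i, 1L]); rb <- find(pairs[i, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  # relabel consecutively in first-appearance (column-major scan) order
  nz <- lab[lab > 0L]
  if (length(nz)) {
    first_seen <- unique(nz)
    lab[lab > 0L] <- match(nz, first_seen)
  }
  lab
}

#' Keep the k largest particles of a binary mask
#'
#' Labels connected components with 8-connectivity and retains the `k`
#' largest by pixel count; slices typically yield six particles, so
#' `k = 6` by default. A tie at rank `k` is broken in favour of the
#' earlier-labelled component (column-major scan order) with a warning.
#'
#' @param mask Logical matrix.
#' @param k Number of particles to keep (default 6).
#' @return A `particle_set`: list with `labels` (integer matrix, labels
#'   `1..m` in scan order of the kept components), `areas` (pixel counts,
#'   same order), and `k`.
#' @export
filter_top_particles <- function(mask, k = 6L) {
  if (k < 1L) stop("k must be >= 1")
  lab <- label_particles(mask)
  nlab <- max(lab)
  if (nlab == 0L) {
    warning("empty foreground: no particles found")
    return(structure(list(labels = lab, areas = integer(0), k = as.integer(k)),
                     class = "particle_set"))
  }
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  ord <- order(-areas, seq_len(nlab))
  keep <- ord[seq_len(min(k, nlab))]
  if (nlab > k && areas[ord[k]] == areas[ord[k + 1L]]) {
    warning("tie at rank ", k, ": keeping the earlier-labelled particle")
  }
  keep <- sort(keep)                       # preserve scan order in the output
  newlab <- integer(nlab)
  newlab[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0L] <- newlab[lab[lab > 0L]]
  structure(list(labels = out, areas = areas[keep], k = as.integer(k)),
            class = "particle_set")
}

#' Total foreground area of a particle set
#'
#' @param ps A `particle_set` from [filter_top_particles()].
#' @return Total pixel count (0 for an empty set).
#' @export
total_area <- function(ps) {
  stopifnot(inherits(ps, "particle_set"))
  sum(ps$areas)
}

#' Shrinkage series from per-frame areas
#'
#' Shrinkage is the projected-area ratio `S(t) = A(t) / A(0)`; it equals 1 at
#' the first frame by construction and is scale-free, so no pixel-to-mm
#' calibration is needed.
#'
#' @param areas Numeric vector of per-frame pixel counts (first must be > 0).
#' @param times Numeric vector of frame times in minutes (same length).
#' @return `data.frame` with columns `time_min`, `area_px`, `shrinkage`.
#' @export
shrinkage_series <- function(areas, times) {
  if (length(areas) != length(times)) stop("areas and times must have equal length")
  if (any(areas < 0)) stop("negative area encountered")
  if (areas[1L] <= 0) stop("A(0) must be positive (division by zero)")
  data.frame(time_min = times, area_px = areas, shrinkage = areas / areas[1L])
}

#' Read a PNG or TIFF frame as an 8-bit integer image
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer matrix (grayscale) or `height x width x 3` array (RGB)
#'   with values in \[0, 255\]; an alpha channel, if present, is dropped.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported frame format: .", ext, " (use PNG or TIFF)")
  )
  if (length(dim(img)) == 3L && dim(img)[3L] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (length(dim(img)) == 3L) {
    img <- img[, , 1L]
  }
  out <- round(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' Run the full segmentation pipeline on one frame
#'
#' Grayscale conversion (if RGB), clustering threshold, binarization,
#' hole filling, and largest-`k` particle filtering, returning the summed
#' particle area.
#'
#' @param frame Integer matrix or `h x w x 3` array in \[0, 255\].
#' @param threshold_method `"intermeans"` or `"otsu"`.
#' @param bright_foreground Foreground polarity (default bright).
#' @param k Particles to keep (default 6).
#' @return List with `area` (pixel count), `threshold`, `n_particles`.
#' @export
frame_area <- function(frame, threshold_method = "intermeans",
                       bright_foreground = TRUE, k = 6L) {
  gray <- if (length(dim(frame)) == 3L) to_grayscale(frame) else frame
  thr <- cluster_threshold(gray, method = threshold_method)
  mask <- binarize(gray, thr, bright_foreground = bright_foreground)
  mask <- fill_holes(mask)
  ps <- filter_top_particles(mask, k = k)
  list(area = total_area(ps), threshold = thr, n_particles = length(ps$areas))
}

#' Extract a shrinkage series from an image stack
#'
#' @param frames List of in-memory frames (integer matrices or RGB arrays) or
#'   a character vector of file paths.
#' @param times Frame times in minutes, same length as `frames`.
#' @param threshold_method,bright_foreground,k Passed to [frame_area()].
#' @param allow_empty If `FALSE` (default), a frame with empty foreground is
#'   an error naming the frame.
#' @param verbose Log per-frame threshold and particle count via `message()`.
#' @return `data.frame` with `time_min`, `area_px`, `shrinkage`; the integer
#'   thresholds used are attached as `attr(, "thresholds")`.
#' @export
extract_shrinkage <- function(frames, times, threshold_method = "intermeans",
                              bright_foreground = TRUE, k = 6L,
                              allow_empty = FALSE, verbose = FALSE) {
  if (length(frames) != length(times)) stop("frames and times must have equal length")
  areas <- numeric(length(frames))
  thresholds <- integer(length(frames))
  for (i in seq_along(frames)) {
    frame <- frames[[i]]
    name <- if (is.character(frame)) frame else paste0("frame ", i)
    if (is.character(frame)) {
      frame <- tryCatch(read_frame(frame),
                        error = function(e) stop("failed to read ", name, ": ",
                                                 conditionMessage(e)))
    }
    res <- withCallingHandlers(
      frame_area(frame, threshold_method, bright_foreground, k),
      warning = function(w) {
        if (grepl("empty foreground", conditionMessage(w)) && !allow_empty) {
          stop("empty foreground in ", name)
        }
        invokeRestart("muffleWarning")
      }
    )
    if (verbose) {
      message(sprintf("%s: threshold=%d particles=%d area=%d",
                      name, res$threshold, res$n_particles, res$area))
    }
    areas[i] <- res$area
    thresholds[i] <- res$threshold
  }
  out <- shrinkage_series(areas, times)
  attr(out, "thresholds") <- thresholds
  out
}
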