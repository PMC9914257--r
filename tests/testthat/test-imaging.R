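test_that("grayscale conversion averages channels with banker's rounding", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(to_grayscale(px(60, 60, 60))[1, 1], 60L)
  expect_equal(to_grayscale(px(0, 0, 0))[1, 1], 0L)
  expect_equal(to_grayscale(px(10, 20, 31))[1, 1], 20L)  # mean 20.33
  expect_equal(to_grayscale(px(10, 20, 32))[1, 1], 21L)  # mean 20.67
  # whole-image conversion keeps shape and range
  set.seed(1)
  img <- array(sample(0:255, 2 * 30 * 40 * 3, replace = TRUE), dim = c(30, 40, 3))
  g <- to_grayscale(img)
  expect_identical(dim(g), c(30L, 40L))
  expect_true(all(g >= 0 & g <= 255))
  expect_equal(g[3, 7], as.integer(round(mean(img[3, 7, ]))))
  expect_error(to_grayscale(matrix(0, 3, 3)), "channel")
  expect_error(to_grayscale(array(0, c(2, 2, 4))), "channel")
})

test_that("intermeans threshold matches the fixed point of the class means", {
  two_spike <- matrix(c(rep(50L, 60), rep(200L, 60)), 10, 12)
  expect_equal(cluster_threshold(two_spike), 125L)
  expect_warning(thr <- cluster_threshold(matrix(100L, 4, 4)), "degenerate")
  expect_equal(thr, 100L)
  # random bimodal images: result must satisfy the brute-force fixed-point
  # condition scanned over all 256 candidates
  for (s in 1:5) {
    set.seed(s)
    img <- matrix(as.integer(c(pmax(0, pmin(255, round(rnorm(300, 60, 12)))),
                               pmax(0, pmin(255, round(rnorm(200, 190, 15)))))),
                  25, 20)
    expect_true(cluster_threshold(img) %in% intermeans_fixed_points(img))
  }
})

test_that("otsu threshold equals the exhaustive between-class-variance maximizer", {
  for (s in 1:5) {
    set.seed(10 + s)
    img <- matrix(as.integer(c(pmax(0, pmin(255, round(rnorm(250, 70, 20)))),
                               pmax(0, pmin(255, round(rnorm(250, 180, 10)))))),
                  25, 20)
    expect_equal(cluster_threshold(img, method = "otsu"), otsu_oracle(img))
  }
})

test_that("binarization uses a strict > threshold for bright foreground", {
  img <- matrix(200L, 5, 5)
  expect_true(all(binarize(img, 125)))
  expect_false(any(binarize(img, 200)))       # boundary: strictly greater
  expect_true(all(binarize(img, 200, bright_foreground = FALSE)))
  checker <- matrix(c(50L, 200L), 6, 6)
  expect_identical(binarize(checker, 125), checker == 200L)
  expect_error(binarize(img, 300), "\\[0, 255\\]")
})

test_that("hole filling fills enclosed background and nothing else", {
  annulus <- disk_mask(21, 21, 11, 11, 8) & !disk_mask(21, 21, 11, 11, 4)
  expect_identical(fill_holes(annulus), disk_mask(21, 21, 11, 11, 8))
  solid <- disk_mask(15, 15, 8, 8, 5)
  expect_identical(fill_holes(solid), solid)   # no enclosed background
  # property: equals the border flood-fill oracle; idempotent; monotone
  for (s in 1:8) {
    set.seed(20 + s)
    mask <- matrix(runif(30 * 25) < 0.45, 30, 25)
    filled <- fill_holes(mask)
    expect_identical(filled, fill_holes_oracle(mask))
    expect_identical(fill_holes(filled), filled)
    expect_true(all(filled[mask]))             # foreground never removed
  }
})

test_that("particle filtering keeps the k largest 8-connected components", {
  img <- matrix(FALSE, 60, 200)
  radii <- c(3, 4, 5, 6, 7, 8, 9, 10)
  for (i in seq_along(radii)) {
    img <- img | disk_mask(60, 200, 30, 12 + 24 * (i - 1), radii[i])
  }
  ps <- filter_top_particles(img, k = 6)
  expect_length(ps$areas, 6)
  areas_all <- sort(sapply(radii, function(r) sum(disk_mask(60, 200, 30, 30, r))),
                    decreasing = TRUE)
  expect_setequal(ps$areas, areas_all[1:6])
  # fewer particles than k: all retained
  ps4 <- filter_top_particles(disk_mask(40, 40, 20, 20, 6), k = 6)
  expect_length(ps4$areas, 1)
  # output foreground is a subset of the input's
  expect_true(all(img[ps$labels > 0]))
})

test_that("diagonally touching pixels form one particle", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  ps <- filter_top_particles(m, k = 6)
  expect_length(ps$areas, 1)
  expect_equal(ps$areas, 2)
})

test_that("a tie at rank k keeps the earlier-labelled particle with a warning", {
  m <- matrix(FALSE, 10, 40)
  m[2:3, 2:3] <- TRUE      # area 4, first in scan order
  m[6:8, 10:12] <- TRUE    # area 9
  m[2:3, 30:31] <- TRUE    # area 4, later in scan order
  expect_warning(ps <- filter_top_particles(m, k = 2), "tie")
  expect_equal(sort(ps$areas), c(4, 9))
  expect_true(any(ps$labels[2:3, 2:3] > 0))    # earlier square kept
  expect_false(any(ps$labels[2:3, 30:31] > 0)) # later square dropped
})

test_that("empty foreground yields an empty particle set with warning", {
  expect_warning(ps <- filter_top_particles(matrix(FALSE, 5, 5)), "empty")
  expect_equal(total_area(ps), 0)
})

test_that("total area sums component areas and a disk approximates pi r^2", {
  ps <- structure(list(labels = NULL, areas = c(100, 50, 25), k = 6L),
                  class = "particle_set")
  expect_equal(total_area(ps), 175)
  disk <- disk_mask(60, 60, 30, 30, 20)
  got <- total_area(filter_top_particles(disk, k = 1))
  expect_equal(got, sum(disk))
  expect_lt(abs(got / (pi * 20^2) - 1), 0.02)
})

test_that("shrinkage series normalizes to the first area", {
  s <- shrinkage_series(c(100, 80, 60), c(0, 0.5, 1))
  expect_equal(s$shrinkage, c(1.0, 0.8, 0.6))
  expect_equal(shrinkage_series(c(200, 150), c(0, 1))$shrinkage, c(1, 0.75))
  expect_equal(shrinkage_series(rep(70, 4), 0:3)$shrinkage, rep(1, 4))
  expect_error(shrinkage_series(c(0, 10), c(0, 1)), "positive")
  expect_error(shrinkage_series(c(10, -1), c(0, 1)), "negative")
  expect_error(shrinkage_series(1:3, 1:2), "equal length")
})

test_that("total area is invariant to integer translation of the scene", {
  base <- disk_scene()
  shifted <- matrix(40L, 80, 120)
  shifted[11:80, 6:120] <- base[1:70, 1:115]
  a1 <- frame_area(base)$area
  a2 <- frame_area(shifted)$area
  # the shifted scene crops nothing (disks sit in rows <= 60, cols <= 100)
  expect_equal(a1, a2)
})

test_that("pipeline recovers disk areas within 2% under mild pixel noise", {
  set.seed(99)
  truth <- simulate_series(simulation_spec(pixel_noise_sigma = 10, seed = 5))
  fr <- render_frames(truth)
  idx <- round(seq(1, length(fr$frames), length.out = 9))
  ext <- extract_shrinkage(fr$frames[idx], truth$series$time_min[idx])
  expect_true(all(abs(ext$shrinkage / truth$series$s_true[idx] - 1) < 0.02))
})
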