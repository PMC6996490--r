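test_that("blob pixel count matches area / pixel-area arithmetic", {
  tr <- make_manual_trace(rep(110, 3), position = rep(-1, 3))
  tr$area_um2 <- c(12, 12, 12)
  mp <- movie_params()
  mv <- render_movie(tr, mp)
  npx <- sum(mv[, , 1] > (mp$background_au + 5) / mp$au_max)
  expect_lte(abs(npx - 48), 4) # 12 um2 at 0.5 um/px -> 48 px
})

test_that("absent frames render no blob", {
  tr <- make_manual_trace(c(110, NA, 110), position = c(-1, NA, -1),
                          present = c(TRUE, FALSE, TRUE))
  mp <- movie_params()
  mv <- render_movie(tr, mp)
  expect_equal(sum(mv[, , 2] > (mp$background_au + 5) / mp$au_max), 0)
})

test_that("a frame too small for the blob is a geometry error", {
  tr <- make_manual_trace(rep(110, 2), position = rep(-1, 2))
  tr$area_um2 <- rep(500, 2)
  expect_error(render_movie(tr, movie_params(width = 16, height = 40,
                                             boundary_row = 20)),
               "frame too small")
  expect_error(movie_params(height = 40), "boundary_row")
})

test_that("noise-free render/track round-trip recovers the trace", {
  sim <- simulate_axon("dmso", 7, noise_sd = 0)
  tr <- sim$trace[41:110, ] # dwell-and-events segment
  mp <- movie_params()
  mv <- render_movie(tr, mp)
  rec <- track(mv, mp)
  pr <- tr$present
  expect_equal(rec$present, pr)
  expect_lte(max(abs(rec$area_um2[pr] - tr$area_um2[pr])),
             mp$pixel_size_um^2) # within one pixel area
  expect_lte(max(abs(rec$intensity_au[pr] - tr$intensity_au[pr])), 1e-8)
  expect_lte(max(abs(rec$position_um[pr] - tr$position_um[pr])),
             mp$pixel_size_um) # within one pixel pitch
})

test_that("a stack of identical frames tracks to a constant trace", {
  tr <- make_manual_trace(rep(110, 5), position = rep(-2, 5))
  mp <- movie_params()
  rec <- track(render_movie(tr, mp), mp)
  expect_equal(length(unique(rec$area_um2)), 1)
  expect_equal(length(unique(rec$position_um)), 1)
})

test_that("terminus rows convert to signed boundary distances", {
  # rows 40, 38, 36 at 0.5 um/px with boundary at row 30 -> -5, -4, -3 um
  mp <- movie_params(width = 32, height = 64, boundary_row = 30)
  mv <- array(0.05, dim = c(64, 32, 3))
  for (i in 1:3) {
    top <- c(40, 38, 36)[i]
    mv[top:(top + 3), 14:17, i] <- 0.5
  }
  rec <- track(mv, mp)
  expect_equal(rec$position_um, c(-5, -4, -3))
})

test_that("segmentation picks the component nearest the prior terminus", {
  frame <- matrix(10, 80, 60)
  frame[20:23, 30:33] <- 100 # dorsal blob
  frame[60:63, 30:33] <- 100 # ventral blob
  # oracle: exhaustive component enumeration via labelling
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(frame > 50)))
  expect_equal(max(lab), 2)
  m_dorsal <- segment_growth_cone(frame, prior = c(25, 31))
  expect_true(all(which(m_dorsal, arr.ind = TRUE)[, 1] <= 23))
  m_ventral <- segment_growth_cone(frame, prior = c(58, 31))
  expect_true(all(which(m_ventral, arr.ind = TRUE)[, 1] >= 60))
})

test_that("noise-only and constant frames give empty, flagged masks", {
  withr::with_seed(3, noisy <- matrix(rnorm(80 * 60, 10, 1), 80, 60))
  m1 <- segment_growth_cone(noisy)
  expect_false(any(m1))
  expect_true(attr(m1, "empty"))
  m2 <- segment_growth_cone(matrix(7, 40, 40))
  expect_false(any(m2))
  expect_true(attr(m2, "empty"))
})

test_that("16-bit TIFF round-trip preserves the stack", {
  tr <- make_manual_trace(rep(110, 4), position = rep(-1, 4))
  mv <- render_movie(tr, movie_params())
  path <- withr::local_tempfile(fileext = ".tiff")
  write_movie_tiff(mv, path)
  mv2 <- read_movie_tiff(path)
  expect_equal(dim(mv2), dim(mv))
  expect_lt(max(abs(mv2 - mv)), 2 / 65535)
})

test_that("track rejects stacks with fewer than two frames", {
  expect_error(track(array(0.1, dim = c(20, 20, 1))), "2 frames")
})
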