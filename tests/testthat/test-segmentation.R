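test_that("histograms count every value exactly", {
  h <- compute_histogram(matrix(7L, 2, 5))
  expect_equal(h$counts[8], 10)
  expect_equal(sum(h$counts), 10)

  h2 <- compute_histogram(matrix(c(0L, 255L), 1, 2))
  expect_equal(h2$counts[c(1, 256)], c(1, 1))
  expect_equal(sum(h2$counts), 2)

  set.seed(4)
  img <- matrix(sample(0:255, 300, replace = TRUE), 15, 20)
  h3 <- compute_histogram(img)
  # recount by direct iteration
  direct <- vapply(0:255, function(v) sum(img == v), numeric(1))
  expect_equal(h3$counts, direct)
  expect_error(compute_histogram(matrix(1.5, 2, 2)), "8-bit")
  expect_error(compute_histogram(matrix(300L, 2, 2)), "8-bit")
})

test_that("a single threshold separates a bimodal histogram", {
  img <- matrix(c(rep(50L, 40), rep(200L, 60)), 10, 10)
  ts <- select_thresholds(img, 1)
  expect_equal(ts$n, 1L)
  expect_gt(ts$thresholds, 50)
  expect_lte(ts$thresholds, 200)
  seg <- reconstruct(img, ts)$segments
  expect_true(all(seg[img == 50] == 0))
  expect_true(all(seg[img == 200] == 1))
})

test_that("requested thresholds are strictly increasing and distinct on small histograms", {
  cases <- list(
    c(0L, 128L, 255L),
    c(100L, 101L, 102L),
    c(0L, 1L),
    c(10L, 20L, 30L, 40L, 250L),
    c(5L, 9L, 13L, 80L, 81L, 82L, 200L)
  )
  for (vals in cases) {
    img <- matrix(rep(vals, each = 4))
    for (n in seq_len(length(vals) - 1L)) {
      ts <- select_thresholds(img, n)
      expect_equal(ts$n, n)
      expect_equal(ts$thresholds, sort(unique(ts$thresholds)))
      expect_true(all(diff(ts$thresholds) >= 1))
    }
  }
})

test_that("w = 0 subdivides intervals at their occupancy-weighted means", {
  img <- matrix(c(rep(40L, 50), rep(200L, 50)))
  ts <- select_thresholds(img, 1, w = 0)
  expect_equal(ts$thresholds, 120L) # round(mean) of equal masses at 40 and 200
})

test_that("constant images are rejected as degenerate", {
  expect_error(select_thresholds(matrix(9L, 5, 5), 1), "degenerate")
})

test_that("reconstruction saturates to the original when every value has its own segment", {
  img <- matrix(c(rep(10L, 5), rep(90L, 3), rep(230L, 4)))
  ts <- select_thresholds(img, 2)
  rec <- reconstruct(img, ts)
  expect_equal(rec$reconstructed, matrix(as.numeric(img), nrow(img)))
  expect_equal(ts$psnr_db, Inf)
})

test_that("single-segment reconstruction is the global mean; a split hits both values", {
  img <- matrix(c(rep(60L, 30), rep(180L, 10)))
  rec0 <- reconstruct(img, integer(0))
  expect_true(all(rec0$reconstructed == mean(img)))
  rec1 <- reconstruct(img, 100L)
  expect_equal(sort(unique(as.vector(rec1$reconstructed))), c(60, 180))
})

test_that("PSNR follows its closed form with an infinite sentinel", {
  a <- matrix(100, 8, 8)
  expect_equal(psnr(a, a), Inf)
  expect_equal(psnr(a, matrix(110, 8, 8)), 20 * log10(25.5), tolerance = 1e-12)
  expect_equal(psnr(matrix(0, 1, 1), matrix(255, 1, 1)), 0)
  expect_error(psnr(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
})

test_that("PSNR is invariant to joint spatial translation", {
  set.seed(11)
  a <- matrix(sample(0:255, 400, TRUE), 20, 20)
  b <- matrix(pmin(255, a + sample(0:9, 400, TRUE)), 20, 20)
  roll <- function(m) m[c(6:20, 1:5), c(11:20, 1:10)]
  expect_equal(psnr(a, b), psnr(roll(a), roll(b)))
})

test_that("adding a threshold never increases reconstruction RMSE", {
  rmse <- function(img, thr) {
    sqrt(mean((img - reconstruct(img, thr)$reconstructed)^2))
  }
  set.seed(20)
  for (i in 1:30) {
    img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
    thr <- sort(sample(1:255, sample(1:8, 1)))
    extra <- sample(setdiff(1:255, thr), 1)
    expect_lte(rmse(img, sort(c(thr, extra))), rmse(img, thr) + 1e-9)
  }
})

test_that("segment means are monotone non-decreasing with segment index", {
  set.seed(21)
  for (i in 1:10) {
    img <- matrix(sample(0:255, 500, TRUE), 25, 20)
    ts <- select_thresholds(img, sample(2:8, 1))
    occupied <- unique(as.vector(reconstruct(img, ts)$segments))
    repr <- reconstruct(img, ts)$repr
    expect_true(all(diff(repr) >= 0))
  }
})

test_that("the PSNR elbow picks a saturating n for few-valued images and n = 0 for constants", {
  img3 <- matrix(c(rep(0L, 30), rep(120L, 40), rep(250L, 30)), 10, 10)
  ts <- choose_optimal_n(img3, n_range = 1:6)
  expect_lte(ts$n, 2)
  expect_equal(ts$psnr_db, Inf)

  expect_warning(ts0 <- choose_optimal_n(matrix(5L, 6, 6)), "degenerate")
  expect_equal(ts0$n, 0L)
  curve <- attr(ts, "psnr_curve")
  expect_true(is.data.frame(curve) && nrow(curve) >= 2)
})

test_that("the chosen n lies within the searched range on a realistic rendered fixture", {
  m <- default_cortical_model()
  s <- simulate_clones(m, sim_params(n_clones = 15, clone_sizes = 3,
                                     noise_sd = 5, seed = 55))
  img <- render_image(s$cells, render_config())
  ts <- choose_optimal_n(img[, , 1], n_range = 2:15)
  expect_gte(ts$n, 2)
  expect_lte(ts$n, 15)
})

test_that("detect_cells finds nothing on blank images and drops speckles below min_area", {
  blank <- array(3L, dim = c(30, 30, 2))
  expect_equal(nrow(detect_cells(blank)), 0L)

  sp <- matrix(0L, 30, 30)
  sp[10, 10] <- 200L # single-pixel speckle
  expect_equal(nrow(detect_cells(sp, thresholds = list(c(100L)), min_area = 2)),
               0L)
  expect_equal(nrow(detect_cells(sp, thresholds = list(c(100L)), min_area = 1)),
               1L)
})

test_that("detect_cells recovers well-separated somata with 1 px centroid accuracy", {
  cells <- data.frame(cell_id = 1:5,
                      x_um = c(15, 50, 85, 25, 70),
                      y_um = c(15, 20, 15, 55, 55),
                      ch1 = c(229, 178, 127, 229, 178),
                      ch2 = c(76, 229, 25, 127, 229))
  img <- render_image(cells, render_config(field_um = c(100, 70)))
  det <- detect_cells(img)
  expect_equal(nrow(det), 5L)
  nn <- match_to_truth(det, cells)
  expect_setequal(nn, 1:5)
  expect_lt(max(abs(det$x_um - cells$x_um[nn])), 1)
  expect_lt(max(abs(det$y_um - cells$y_um[nn])), 1)
  # core-mean intensities decode to the nominal levels
  enc <- encode_cells(det)
  truth_enc <- encode_cells(cells)
  expect_equal(enc$code, truth_enc$code[nn])
})

test_that("detected cell count is invariant to channel order permutation", {
  m <- tiny_model()
  s <- simulate_clones(m, sim_params(n_clones = 8, clone_sizes = 2,
                                     noise_sd = 0, seed = 66))
  img <- render_image(s$cells, render_config())
  det <- detect_cells(img)
  perm <- img[, , c(3, 1, 4, 2)]
  det_perm <- detect_cells(perm)
  expect_equal(nrow(det_perm), nrow(det))
  expect_equal(det_perm$x_um, det$x_um)
  # and the code permutes identically with the channels
  expect_equal(encode_cells(det_perm)$code_ch1, encode_cells(det)$code_ch3)
})
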