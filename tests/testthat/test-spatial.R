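test_that("pair tables classify relatedness, layer and distance correctly", {
  cells <- data.frame(cell_id = 1:2, x_um = c(0, 3), y_um = c(0, 4),
                      layer = "L4", clone = 1L)
  pt <- pair_distances(cells)
  expect_equal(nrow(pt), 1L)
  expect_equal(pt$relatedness, "related")
  expect_equal(pt$layer_class, "same")
  expect_equal(pt$distance_um, 5)

  # no self pairs: distinct-pair distances are all positive here
  cells3 <- data.frame(cell_id = 1:3, x_um = c(0, 3, 40), y_um = c(0, 4, 0),
                       layer = c("L4", "L4", "L5"), clone = c(1L, 1L, 2L))
  pt3 <- pair_distances(cells3)
  expect_equal(nrow(pt3), 3L)
  expect_true(all(pt3$distance_um > 0))
  expect_equal(sum(pt3$relatedness == "related"), 1L)
  expect_equal(sum(pt3$layer_class == "different"), 2L)

  # fewer than 2 usable cells -> empty table
  expect_equal(nrow(pair_distances(cells[0, ])), 0L)
  one <- data.frame(cell_id = 1L, x_um = 0, y_um = 0, layer = "L4", clone = 1L)
  expect_equal(nrow(pair_distances(one)), 0L)
})

test_that("cross-section pairs are never formed and matched sampling balances counts", {
  cells <- data.frame(cell_id = 1:4, x_um = c(0, 10, 0, 10), y_um = 0,
                      layer = "L4", clone = c(1L, 2L, 3L, 4L),
                      section = c(1L, 1L, 2L, 2L))
  pt <- pair_distances(cells)
  expect_equal(nrow(pt), 2L) # only within-section pairs

  m <- default_cortical_model()
  s <- simulate_clones(m, sim_params(n_clones = 20, clone_sizes = 2,
                                     noise_sd = 0, seed = 51))
  cl <- s$cells; cl$clone <- cl$clone_id
  set.seed(1)
  ptm <- pair_distances(cl, sampling_policy = "matched")
  expect_equal(sum(ptm$relatedness == "unrelated"),
               sum(ptm$relatedness == "related"))
})

test_that("dispersion summaries match hand arithmetic and are rigid-motion invariant", {
  pt <- data.frame(cell_a = 1:5, cell_b = 6:10,
                   relatedness = c("related", "related", "related",
                                   "unrelated", "unrelated"),
                   layer_class = c("same", "same", "different",
                                   "same", "different"),
                   distance_um = c(30, 50, 120, 45, 300))
  s <- summarize_dispersion(pt)$summary
  pick <- function(r, l) s[s$relatedness == r & s$layer_class == l, ]
  expect_equal(pick("related", "same")$mean_um, 40)
  expect_equal(pick("related", "same")$sd_um, sd(c(30, 50)))
  expect_equal(pick("related", "total")$mean_um, mean(c(30, 50, 120)))
  expect_equal(pick("unrelated", "different")$n, 1L)
  expect_equal(pick("unrelated", "different")$sd_um, 0)

  # identical distances give SD 0
  same2 <- data.frame(relatedness = "related", layer_class = "same",
                      distance_um = c(10, 10))
  expect_equal(summarize_dispersion(same2)$summary[1, "sd_um"], 0)

  # rigid translation + rotation of coordinates leaves the summary unchanged
  cells <- data.frame(cell_id = 1:6, x_um = c(0, 30, 80, 10, 90, 55),
                      y_um = c(0, 40, 10, 70, 30, 60),
                      layer = c("L4", "L4", "L5", "L5", "L4", "L5"),
                      clone = c(1L, 1L, 2L, 2L, 3L, 3L))
  th <- 0.7
  rot <- data.frame(cell_id = cells$cell_id,
                    x_um = cos(th) * cells$x_um - sin(th) * cells$y_um + 500,
                    y_um = sin(th) * cells$x_um + cos(th) * cells$y_um - 200,
                    layer = cells$layer, clone = cells$clone)
  s1 <- summarize_dispersion(pair_distances(cells))$summary
  s2 <- summarize_dispersion(pair_distances(rot))$summary
  expect_equal(s1$mean_um, s2$mean_um)
  expect_equal(s1$sd_um, s2$sd_um)
})

test_that("exact Mann-Whitney matches hand enumeration and handles ties", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 2 / 6)
  # identical multisets -> p = 1 two-sided
  expect_equal(mann_whitney(c(5, 7), c(5, 7))$p.value, 1)
})

test_that("exact Mann-Whitney agrees with brute-force enumeration for all small splits", {
  set.seed(61)
  shapes <- list(c(2, 2), c(3, 3), c(4, 4), c(2, 6), c(5, 3))
  for (sh in shapes) {
    for (rep in 1:3) {
      a <- sample(1:6, sh[1], replace = TRUE) # replace=TRUE forces ties
      b <- sample(1:6, sh[2], replace = TRUE)
      for (alt in c("two.sided", "greater", "less")) {
        expect_equal(mann_whitney(a, b, alternative = alt)$p.value,
                     brute_mann_whitney_p(a, b, alternative = alt),
                     info = paste(alt, paste(a, collapse = ","), "|",
                                  paste(b, collapse = ",")))
      }
    }
  }
})

test_that("exact p values match wilcox.test on tie-free data", {
  set.seed(62)
  a <- sample(seq(1, 99, 2), 5)  # odd values only
  b <- sample(seq(2, 100, 2), 6) # even values only: no ties possible
  w <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(mann_whitney(a, b)$p.value, w$p.value)
  expect_equal(mann_whitney(a, b)$statistic, unname(w$statistic))
})

test_that("large-sample approximation matches wilcox.test and detects separation", {
  set.seed(63)
  a <- rnorm(40, 0, 1)
  b <- rnorm(45, 0.2, 1)
  w <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mann_whitney(a, b)$p.value, w$p.value, tolerance = 1e-10)
  # well-separated samples give vanishing p
  a2 <- rnorm(50, 0, 1)
  b2 <- rnorm(50, 5, 1)
  expect_lt(mann_whitney(a2, b2)$p.value, 1e-4)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Sidak adjustment follows its closed form and is monotone in m", {
  expect_equal(sidak_adjust(0.2, m = 1), 0.2)
  expect_equal(sidak_adjust(0, m = 7), 0)
  expect_equal(sidak_adjust(0.01, m = 3), 1 - 0.99^3, tolerance = 1e-15)
  p <- c(0.001, 0.05, 0.5, 1)
  expect_true(all(sidak_adjust(p) >= p))
  adj <- vapply(1:6, function(m) sidak_adjust(0.04, m = m), numeric(1))
  expect_true(all(diff(adj) > 0))
  expect_error(sidak_adjust(1.2), "0, 1")
})

test_that("layer-count comparison reports Welch tests with Sidak correction", {
  g1 <- list(L4 = c(100, 110, 105), L5 = c(60, 62, 58))
  # identical groups: zero change, p = 1 after adjustment
  same <- compare_layer_counts(g1, g1)
  expect_equal(same$percent_change, c(0, 0))
  expect_equal(same$p_sidak, c(1, 1))

  # exact 0.57x scaling in one layer gives -43%
  g2 <- g1
  g2$L4 <- 0.57 * g1$L4
  cmp <- compare_layer_counts(g1, g2)
  expect_equal(cmp$percent_change[cmp$layer == "L4"], -43)

  # doubling both groups leaves t and p unchanged
  cmp2 <- compare_layer_counts(lapply(g1, `*`, 2), lapply(g2, `*`, 2))
  expect_equal(cmp2$t, cmp$t)
  expect_equal(cmp2$p_value, cmp$p_value)

  # Welch matches stats::t.test and Sidak uses m = number of layers
  tt <- stats::t.test(g2$L4, g1$L4, var.equal = FALSE)
  expect_equal(cmp$p_value[cmp$layer == "L4"], tt$p.value)
  expect_equal(cmp$p_sidak, sidak_adjust(cmp$p_value, m = 2))
  expect_error(compare_layer_counts(list(L4 = 1), list(L4 = c(1, 2))),
               "replicates")
})

test_that("laminar contributions compute per-layer and aggregate fractions", {
  lc <- laminar_contribution(c(A = 40, B = 30), c(A = 100, B = 100),
                             layer_groups = list())
  expect_equal(lc$per_layer$fraction, c(0.40, 0.30))
  expect_equal(lc$aggregates$fraction, 0.35)

  # labeled = total everywhere -> all fractions 1
  lc1 <- laminar_contribution(c(A = 5, B = 9), c(A = 5, B = 9),
                              layer_groups = list())
  expect_true(all(lc1$per_layer$fraction == 1))

  # aggregate equals the count-weighted mean of per-layer fractions
  lab <- c("L2/3" = 402, "L4" = 313, "L5" = 198, "L6" = 290, "SP" = 272)
  tot <- c("L2/3" = 1000, "L4" = 1000, "L5" = 1000, "L6" = 1000, "SP" = 1000)
  lc2 <- laminar_contribution(lab, tot)
  agg <- lc2$aggregates
  supra <- agg[agg$group == "supragranular", ]
  expect_equal(supra$fraction,
               weighted.mean(lab[c("L2/3", "L4")] / tot[c("L2/3", "L4")],
                             tot[c("L2/3", "L4")]))
  expect_equal(agg$fraction[agg$group == "total"], sum(lab) / sum(tot))
  expect_error(laminar_contribution(c(A = 10), c(A = 5)), "exceeds")
})

test_that("the excitatory-fraction arithmetic matches its closed form", {
  expect_equal(excitatory_fraction(0.30, 0.64, 0.25), 0.625, tolerance = 1e-15)
  expect_equal(excitatory_fraction(0.2, 1, 0), 0.2)
  expect_equal(excitatory_fraction(0.20, 0.50, 0.20), 0.50)
  expect_warning(excitatory_fraction(0.9, 0.64, 0.25), "> 1")
  expect_error(excitatory_fraction(0.3, 0, 0.25), "zero")
  expect_error(excitatory_fraction(1.3, 0.64, 0.25), "fractions")
})
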