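#' Pairwise distances between clonally related and unrelated cells
#'
#' Builds the pair table of a dispersion analysis: every within-clone pair is
#' a related pair; unrelated pairs are cross-clone pairs within the same
#' tissue section, either all of them (default) or a random subsample matched
#' in count to the related pairs. Each pair is classified by whether its two
#' cells occupy the same cortical layer, and its Euclidean distance is
#' computed over all supplied coordinate dimensions (um). Unlabeled cells
#' (clone NA) are excluded; cells are never paired with themselves.
#'
#' @param cells Cell table with coordinates (`x_um`, `y_um`, optional `z_um`),
#'   a `layer` column, a clone assignment column (`clone`, or `clone_id` as
#'   fallback), and optionally `section`.
#' @param sampling_policy `"all"` or `"matched"` (subsample unrelated pairs to
#'   the related-pair count; uses the current RNG stream).
#' @return A `pair_table` data.frame: `cell_a, cell_b, relatedness,
#'   layer_class, distance_um`. Fewer than 2 usable cells give an empty table.
#' @export
pair_distances <- function(cells, sampling_policy = c("all", "matched")) {
  sampling_policy <- match.arg(sampling_policy)
  clone <- cells$clone %||% cells$clone_id
  if (is.null(clone)) stop("cells need a `clone` (or `clone_id`) column")
  if (is.null(cells$layer)) stop("cells need a `layer` column")
  section <- cells$section %||% rep(1L, nrow(cells))
  use <- which(!is.na(clone))
  empty <- data.frame(cell_a = integer(0), cell_b = integer(0),
                      relatedness = character(0), layer_class = character(0),
                      distance_um = numeric(0))
  class(empty) <- c("pair_table", "data.frame")
  if (length(use) < 2L) return(empty)
  pieces <- lapply(split(use, section[use]), function(idx) {
    if (length(idx) < 2L) return(NULL)
    cc <- cell_coords(cells[idx, , drop = FALSE])
    d <- as.matrix(stats::dist(cc))
    pr <- which(upper.tri(d), arr.ind = TRUE)
    ia <- idx[pr[, 1L]]; ib <- idx[pr[, 2L]]
    data.frame(
      cell_a = cells$cell_id[ia] %||% ia,
      cell_b = cells$cell_id[ib] %||% ib,
      relatedness = ifelse(clone[ia] == clone[ib], "related", "unrelated"),
      layer_class = ifelse(cells$layer[ia] == cells$layer[ib],
                           "same", "different"),
      distance_um = d[upper.tri(d)]
    )
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  rownames(out) <- NULL
  if (sampling_policy == "matched") {
    rel <- which(out$relatedness == "related")
    unr <- which(out$relatedness == "unrelated")
    if (length(unr) > length(rel)) {
      unr <- sort(sample(unr, length(rel)))
    }
    out <- out[sort(c(rel, unr)), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Dispersion summary of a pair table
#'
#' Mean and SD of pair distance per (relatedness x layer class) category plus
#' pooled ("total") rows, and Mann-Whitney comparisons of related vs unrelated
#' distances within each layer class and pooled. Empty categories are reported
#' with `n = 0` and NA moments rather than NaN arithmetic; tests are only run
#' when both samples are non-empty.
#'
#' @param pairs A `pair_table` from [pair_distances()] or
#'   [simulate_pair_distances()].
#' @param alternative Alternative hypothesis for the Mann-Whitney tests.
#' @return List of class `dispersion_summary`: `summary` (data.frame
#'   `relatedness, layer_class, n, mean_um, sd_um`) and `tests` (data.frame
#'   `layer_class, U, p_value`).
#' @export
summarize_dispersion <- function(pairs, alternative = "two.sided") {
  if (is.null(pairs) || nrow(pairs) == 0L) stop("empty pair table")
  cats <- expand.grid(relatedness = c("related", "unrelated"),
                      layer_class = c("same", "different", "total"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cats)), function(i) {
    sel <- pairs$relatedness == cats$relatedness[i] &
      (cats$layer_class[i] == "total" | pairs$layer_class == cats$layer_class[i])
    d <- pairs$distance_um[sel]
    data.frame(relatedness = cats$relatedness[i],
               layer_class = cats$layer_class[i],
               n = length(d),
               mean_um = if (length(d)) mean(d) else NA_real_,
               sd_um = if (length(d) > 1L) stats::sd(d) else
                 if (length(d) == 1L) 0 else NA_real_)
  })
  summary <- do.call(rbind, rows)
  tests <- do.call(rbind, lapply(c("same", "different", "total"), function(lc) {
    sel <- lc == "total" | pairs$layer_class == lc
    a <- pairs$distance_um[sel & pairs$relatedness == "related"]
    b <- pairs$distance_um[sel & pairs$relatedness == "unrelated"]
    if (length(a) == 0L || length(b) == 0L) {
      return(data.frame(layer_class = lc, U = NA_real_, p_value = NA_real_))
    }
    mw <- mann_whitney(a, b, alternative = alternative)
    data.frame(layer_class = lc, U = mw$statistic, p_value = mw$p.value)
  }))
  structure(list(summary = summary, tests = tests),
            class = "dispersion_summary")
}

#' @export
print.dispersion_summary <- function(x, ...) {
  cat("Pairwise distance dispersion (um):\n")
  s <- x$summary
  s$mean_um <- round(s$mean_um, 1)
  s$sd_um <- round(s$sd_um, 1)
  print(s, row.names = FALSE)
  cat("Mann-Whitney related vs unrelated:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. For small problems
#' (`length(a) + length(b) <= exact_limit`, default 12) the null distribution
#' of U is enumerated exactly over all group-label assignments (ties handled
#' by half-counting), and the two-sided p value is twice the smaller tail
#' probability, capped at 1. Larger problems use the normal approximation
#' with tie-corrected variance and continuity correction.
#'
#' @param a,b Non-empty numeric samples. `U` counts pairs where `a` exceeds
#'   `b` (ties count 1/2), so `alternative = "greater"` means `a` tends
#'   larger.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @param exact_limit Maximum pooled size for exact enumeration.
#' @return List with `statistic` (U of sample `a`), `p.value`, `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p.value # exact: 2/6
#' @export
mann_whitney <- function(a, b, alternative = c("two.sided", "greater", "less"),
                         exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  na <- as.numeric(length(a)); nb <- as.numeric(length(b))
  # rank-based U (midranks count ties as 1/2): U = R_a - na(na+1)/2
  u_stat <- function(r_x, n_x) sum(r_x) - n_x * (n_x + 1) / 2
  r_pooled <- rank(c(a, b))
  u <- u_stat(r_pooled[seq_len(na)], na)
  if (na + nb <= exact_limit) {
    splits <- utils::combn(na + nb, na)
    us <- apply(splits, 2L, function(i) u_stat(r_pooled[i], na))
    p_ge <- mean(us >= u - 1e-12)
    p_le <- mean(us <= u + 1e-12)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    return(list(statistic = u, p.value = p, method = "exact enumeration"))
  }
  n <- na + nb
  r <- rank(c(a, b))
  ties <- table(r)
  mu <- na * nb / 2
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  sigma <- sqrt(sigma2)
  if (sigma == 0) { # complete ties
    p <- if (alternative == "two.sided") 1 else 1
    return(list(statistic = u, p.value = p, method = "normal approximation"))
  }
  z_upper <- (u - mu - 0.5) / sigma
  z_lower <- (u - mu + 0.5) / sigma
  p <- switch(alternative,
              greater = stats::pnorm(z_upper, lower.tail = FALSE),
              less = stats::pnorm(z_lower),
              two.sided = min(1, 2 * min(stats::pnorm(z_upper, lower.tail = FALSE),
                                         stats::pnorm(z_lower))))
  list(statistic = u, p.value = p,
       method = "normal approximation with tie correction")
}

#' Sidak correction for multiple comparisons
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to [0, 1].
#'
#' @param p_values Numeric vector of raw p values in [0, 1].
#' @param m Number of comparisons (default `length(p_values)`).
#' @return Adjusted p values.
#' @examples
#' sidak_adjust(0.01, m = 3) # 1 - 0.99^3
#' @export
sidak_adjust <- function(p_values, m = length(p_values)) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p values must be in [0, 1]")
  }
  if (m < 1) stop("`m` must be >= 1")
  pmin(1, pmax(0, 1 - (1 - p_values)^m))
}

#' Layer-wise comparison of cell counts between two groups
#'
#' Per-layer Welch (unequal-variance) two-sample t-tests of replicate counts,
#' Sidak-adjusted across layers, with the relative change of group 2 vs
#' group 1 reported as `(mean2 - mean1) / mean1`.
#'
#' @param counts_group1,counts_group2 Named lists (or data.frames) mapping
#'   layer name to a numeric vector of replicate counts; at least 2 replicates
#'   per group per layer are required.
#' @param layers Layers to compare (default: those present in both groups, in
#'   group-1 order).
#' @return Data.frame `layer, mean1, mean2, percent_change, t, df, p_value,
#'   p_sidak` (percent_change in %).
#' @export
compare_layer_counts <- function(counts_group1, counts_group2, layers = NULL) {
  g1 <- as.list(counts_group1); g2 <- as.list(counts_group2)
  if (is.null(layers)) layers <- intersect(names(g1), names(g2))
  if (length(layers) == 0L) stop("no common layers to compare")
  rows <- lapply(layers, function(ln) {
    x <- as.numeric(g1[[ln]]); y <- as.numeric(g2[[ln]])
    if (length(x) < 2L || length(y) < 2L) {
      stop("layer ", ln, ": need >= 2 replicates per group (single values ",
           "cannot be tested)")
    }
    tt <- stats::t.test(y, x, var.equal = FALSE)
    data.frame(layer = ln, mean1 = mean(x), mean2 = mean(y),
               percent_change = 100 * (mean(y) - mean(x)) / mean(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_sidak <- sidak_adjust(out$p_value, m = nrow(out))
  out
}

#' Laminar contribution fractions
#'
#' Fraction of labeled cells per layer, plus aggregate fractions over layer
#' groups (default supragranular / infragranular) and over all layers; an
#' aggregate fraction is the count-weighted value `sum(labeled) / sum(total)`
#' over its member layers.
#'
#' @param labeled_counts,total_counts Named numeric vectors (layer -> count);
#'   `labeled <= total` per layer.
#' @param layer_groups Named list of layer-name groups
#'   (default [default_layer_groups()]).
#' @return List of class `laminar_contribution`: `per_layer` (data.frame
#'   `layer, labeled, total, fraction`) and `aggregates` (data.frame `group,
#'   labeled, total, fraction` including a `"total"` row over all layers).
#' @export
laminar_contribution <- function(labeled_counts, total_counts,
                                 layer_groups = default_layer_groups()) {
  labeled <- unlist(labeled_counts); total <- unlist(total_counts)
  if (is.null(names(labeled)) || is.null(names(total))) {
    stop("counts must be named by layer")
  }
  layers <- names(labeled)
  if (!all(layers %in% names(total))) stop("layers missing from total counts")
  total <- total[layers]
  if (any(total < 0) || any(labeled < 0)) stop("counts must be non-negative")
  if (any(labeled > total)) {
    bad <- layers[labeled > total][1L]
    stop("labeled count exceeds total in layer ", bad)
  }
  per_layer <- data.frame(layer = layers, labeled = unname(labeled),
                          total = unname(total),
                          fraction = unname(labeled / total))
  agg_row <- function(name, members) {
    members <- intersect(members, layers)
    data.frame(group = name, labeled = sum(labeled[members]),
               total = sum(total[members]),
               fraction = if (length(members))
                 sum(labeled[members]) / sum(total[members]) else NA_real_)
  }
  aggregates <- do.call(rbind, c(
    lapply(names(layer_groups), function(g) agg_row(g, layer_groups[[g]])),
    list(agg_row("total", layers))
  ))
  structure(list(per_layer = per_layer, aggregates = aggregates),
            class = "laminar_contribution")
}

#' @export
print.laminar_contribution <- function(x, ...) {
  p <- x$per_layer; p$fraction <- sprintf("%.1f%%", 100 * p$fraction)
  a <- x$aggregates; a$fraction <- sprintf("%.1f%%", 100 * a$fraction)
  cat("Laminar contribution:\n"); print(p, row.names = FALSE)
  cat("Aggregates:\n"); print(a, row.names = FALSE)
  invisible(x)
}

#' Fraction of excitatory neurons derived from a labeled lineage
#'
#' Converts a lineage's share of ALL cortical cells into its share of
#' excitatory neurons: with `f_all` the labeled fraction of all cells,
#' `p_neuron` the neuronal fraction of all cells, and `p_interneuron` the
#' interneuron fraction of neurons, the excitatory-neuron fraction is
#' `f_all / (p_neuron * (1 - p_interneuron))` (labeled cells are assumed
#' neuronal and non-GABAergic). For example, a lineage producing 30% of all
#' cells in a cortex with 64% neurons of which 25% are interneurons accounts
#' for 0.30 / 0.48 = 62.5% of excitatory neurons. (When the labeled share is
#' instead expressed relative to glutamatergic cells directly, slightly
#' different figures such as 67.5% can arise; this function implements the
#' all-cells arithmetic.)
#'
#' @param f_all Labeled fraction of all cortical cells, in [0, 1].
#' @param p_neuron Neuronal fraction of all cortical cells, in [0, 1].
#' @param p_interneuron Interneuron fraction of neurons, in [0, 1].
#' @return Fraction of excitatory neurons attributable to the lineage (warns
#'   if the arithmetic exceeds 1).
#' @examples
#' excitatory_fraction(0.30, 0.64, 0.25) # 0.625
#' @export
excitatory_fraction <- function(f_all, p_neuron, p_interneuron) {
  vals <- c(f_all = f_all, p_neuron = p_neuron, p_interneuron = p_interneuron)
  if (any(vals < 0 | vals > 1)) stop("all inputs must be fractions in [0, 1]")
  denom <- p_neuron * (1 - p_interneuron)
  if (denom <= 0) stop("excitatory denominator p_neuron * (1 - p_interneuron) is zero")
  out <- f_all / denom
  if (out > 1) {
    warning("labeled fraction exceeds the excitatory population (result > 1)")
  }
  out
}
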