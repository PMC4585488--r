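#' Simulation parameters for combinatorial clone labeling
#'
#' Bundles and validates the parameters of the clone simulator. Defaults are
#' the study conditions the analysis is designed around: 4 fluorescence
#' channels quantized into 5 levels (a code space of 5^4 - 1 = 624 non-zero
#' combinations), clone-mate separations of 36.8 +/- 20.5 um within a layer
#' and 142.1 +/- 76.8 um across layers, and clone sizes drawn from the three
#' size classes 1-8 / 9-16 / 17-32 with the larger classes more frequent.
#'
#' @param n_clones Number of clones to simulate (>= 0).
#' @param clone_sizes Either a single positive integer (all clones that size),
#'   an integer vector of length `n_clones`, or a function `f(n)` returning
#'   `n` sizes. Default: [clone_size_sampler()].
#' @param channels Number of fluorophore channels (1-4).
#' @param levels Quantizer levels per channel (default 5).
#' @param noise_sd SD (intensity units) of the Gaussian noise added to each
#'   cell's per-channel bin-center intensity; >= 0.
#' @param same_layer_sep_mean,same_layer_sep_sd Mean/SD (um) of the anchor-mate
#'   separation for clone mates staying in the anchor's layer.
#' @param cross_layer_sep_mean,cross_layer_sep_sd Mean/SD (um) for mates placed
#'   in a different layer.
#' @param cross_layer_frac Probability that a clone mate jumps to a different
#'   layer (default 0.45, so roughly half of clone-mate pairs span layers,
#'   consistent with the dispersion means used as defaults).
#' @param labeled_fraction Optional named vector/list mapping layer name to the
#'   fraction of that layer's cells carrying the label, all in (0, 1]; unlabeled
#'   filler cells are added per layer so the labeled fraction matches. `NULL`
#'   (default) adds no unlabeled cells.
#' @param min_separation_um Hard-core minimum distance between any two cell
#'   centroids (um); defaults to 15 um, about one soma diameter, so rendered
#'   somata do not fuse.
#' @param edge_margin_um Cells are kept at least this far from the slab faces.
#' @param unique_codes If TRUE (default) clone codes are drawn without
#'   replacement from the non-zero code space (error if impossible); if FALSE
#'   codes are drawn independently and clones may collide on a code.
#' @param seed Integer master seed; all randomness derives from it.
#' @return Validated list of class `sim_params`.
#' @export
sim_params <- function(n_clones = 50L,
                       clone_sizes = clone_size_sampler(),
                       channels = 4L,
                       levels = 5L,
                       noise_sd = 0,
                       same_layer_sep_mean = 36.8, same_layer_sep_sd = 20.5,
                       cross_layer_sep_mean = 142.1, cross_layer_sep_sd = 76.8,
                       cross_layer_frac = 0.45,
                       labeled_fraction = NULL,
                       min_separation_um = 15,
                       edge_margin_um = 8,
                       unique_codes = TRUE,
                       seed = 1L) {
  if (length(n_clones) != 1L || is.na(n_clones) || n_clones < 0) {
    stop("`n_clones` must be a single non-negative integer")
  }
  if (channels < 1L || channels > 4L) stop("`channels` must be 1..4")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (cross_layer_frac < 0 || cross_layer_frac > 1) {
    stop("`cross_layer_frac` must be in [0,1]")
  }
  if (same_layer_sep_mean <= 0 || cross_layer_sep_mean <= 0 ||
      same_layer_sep_sd < 0 || cross_layer_sep_sd < 0) {
    stop("separation means must be positive and SDs non-negative")
  }
  if (!is.null(labeled_fraction)) {
    lf <- unlist(labeled_fraction)
    if (is.null(names(lf)) || any(lf <= 0 | lf > 1)) {
      stop("`labeled_fraction` must be named fractions in (0, 1]")
    }
  }
  if (min_separation_um < 0) stop("`min_separation_um` must be >= 0")
  if (same_layer_sep_mean <= min_separation_um ||
      cross_layer_sep_mean <= min_separation_um) {
    stop("separation means must exceed `min_separation_um`")
  }
  structure(as.list(environment()), class = "sim_params")
}

#' Default clone-size sampler
#'
#' Samples clone sizes from three size classes (1-8, 9-16, 17-32 cells,
#' uniform within a class) with class probabilities 0.20 / 0.36 / 0.44, so
#' clones larger than 8 cells are roughly twice as frequent as smaller ones
#' and the largest class is the most frequent.
#'
#' @param class_probs Probabilities of the three size classes (sum to 1).
#' @return A function `f(n)` returning `n` integer clone sizes.
#' @export
clone_size_sampler <- function(class_probs = c(0.20, 0.36, 0.44)) {
  stopifnot(length(class_probs) == 3L, all(class_probs >= 0))
  ranges <- list(1:8, 9:16, 17:32)
  function(n) {
    cls <- sample.int(3L, n, replace = TRUE, prob = class_probs)
    vapply(cls, function(k) sample(ranges[[k]], 1L), integer(1))
  }
}

#' Layer-wise labeled-fraction preset for mouse S1
#'
#' Labeled fractions per layer matching the laminar contribution profile the
#' default analysis targets (L2/3 40.2%, L4 31.3%, L5 19.8%, L6 29.0%,
#' SP 27.2%). L1 is omitted (essentially cell-free of labeled neurons).
#'
#' @return Named numeric vector of fractions.
#' @export
laminar_fractions_s1 <- function() {
  c("L2/3" = 0.402, "L4" = 0.313, "L5" = 0.198, "L6" = 0.290, "SP" = 0.272)
}

# Location-calibrated truncated normal: draws from N(mu, sd) truncated to
# (lower, Inf) with mu solved so that the truncated mean equals `mean`. This
# makes the EXPECTED separation equal to the requested one despite truncation.
#' @keywords internal
rtnorm_mean <- function(n, mean, sd, lower = 0) {
  if (mean <= lower) stop("truncated-normal target mean must exceed the lower bound")
  if (sd <= 0) return(rep(mean, n))
  mu <- tnorm_location(mean, sd, lower)
  p0 <- stats::pnorm(lower, mu, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mu, sd)
}

#' @keywords internal
tnorm_location <- function(target, sd, lower = 0) {
  tmean <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a)) - target
  }
  stats::uniroot(tmean, c(target - 4 * sd, target), extendInt = "upX",
                 tol = 1e-10)$root
}

# index in 1..levels^channels-1 -> level digits (least-significant = channel 1)
#' @keywords internal
code_digits <- function(idx, channels, levels) {
  vapply(seq_len(channels), function(k) {
    as.integer((idx %/% levels^(k - 1L)) %% levels)
  }, integer(length(idx)))
}

#' Simulate combinatorially coded clones in a laminated slab
#'
#' Generates a ground-truthed cell table emulating CLoNe-style combinatorial
#' fluorophore labeling. Each clone receives one non-zero fluorophore code
#' (level per channel); the clone's anchor cell is placed uniformly in the
#' slab and each further member is displaced from the anchor by a separation
#' drawn from a location-calibrated truncated normal — tangentially for
#' same-layer mates, with a layer-jump for cross-layer mates — so that expected
#' separations match the requested means. Per-channel cell intensities are the
#' quantizer bin centers of the code levels plus Gaussian noise, clipped to
#' [0, 255]. A hard-core minimum distance keeps somata from overlapping. The
#' whole simulation is reproducible from `params$seed`.
#'
#' @param model A [cortical_model()].
#' @param params A [sim_params()].
#' @return List of class `clone_sim`: `cells` (data.frame `cell_id, x_um, y_um,
#'   z_um, layer, clone_id, ch1..chK`; `y_um` is depth from the pia; unlabeled
#'   filler cells have `clone_id = NA`), `truth` (data.frame `cell_id,
#'   clone_id, code`), plus the `model` and `params` used.
#' @export
simulate_clones <- function(model, params = sim_params()) {
  stopifnot(inherits(model, "cortical_model"), inherits(params, "sim_params"))
  p <- params
  set.seed(as.integer(p$seed %% .Machine$integer.max))

  n_code_space <- p$levels^p$channels - 1
  if (p$n_clones > n_code_space) {
    if (p$unique_codes) {
      stop("code space (", n_code_space, ") too small for ", p$n_clones,
           " distinct clone codes")
    }
    warning("code space smaller than clone count; code collisions are forced")
  }
  if (p$n_clones == 0) {
    return(empty_clone_sim(model, p))
  }

  sizes <- resolve_clone_sizes(p)
  code_idx <- sample.int(n_code_space, p$n_clones, replace = !p$unique_codes)
  codes <- code_digits(code_idx, p$channels, p$levels)
  if (p$n_clones == 1L) codes <- matrix(codes, nrow = 1L)

  W <- model$slab_width_um
  Tt <- model$thickness_um
  m <- min(p$edge_margin_um, W / 4, Tt / 4)
  placed <- matrix(numeric(0), ncol = 2L)
  sep_ok <- function(pos) {
    nrow(placed) == 0L || p$min_separation_um == 0 ||
      min(sqrt((placed[, 1L] - pos[1L])^2 + (placed[, 2L] - pos[2L])^2)) >=
        p$min_separation_um
  }
  layer_bounds <- function(depth) {
    i <- findInterval(depth, model$boundaries, rightmost.closed = TRUE)
    c(model$boundaries[i], model$boundaries[i + 1L])
  }
  crowded <- 0L

  cell_x <- cell_y <- numeric(0)
  cell_clone <- integer(0)
  for (ci in seq_len(p$n_clones)) {
    # mate specs drawn before anchor so anchor feasibility can honor them
    n_mates <- sizes[ci] - 1L
    cross <- if (n_mates) stats::runif(n_mates) < p$cross_layer_frac else logical(0)
    d <- numeric(n_mates)
    # separations respect the hard-core distance; the truncated draw is
    # location-calibrated so the expected separation still equals the target
    if (any(cross)) d[cross] <- rtnorm_mean(sum(cross), p$cross_layer_sep_mean,
                                            p$cross_layer_sep_sd,
                                            lower = p$min_separation_um)
    if (any(!cross)) d[!cross] <- rtnorm_mean(sum(!cross), p$same_layer_sep_mean,
                                              p$same_layer_sep_sd,
                                              lower = p$min_separation_um)
    reach <- if (any(cross)) min(d[cross]) else Inf

    # anchor: uniform, but within `reach` of some other layer if a cross mate
    # exists, so the drawn cross distances stay realizable (keeps their mean
    # calibrated instead of re-drawing distances)
    anchor <- NULL
    for (try in seq_len(2000L)) {
      a <- c(stats::runif(1, m, W - m), stats::runif(1, m, Tt - m))
      if (!sep_ok(a)) next
      if (is.finite(reach)) {
        lb <- layer_bounds(a[2L])
        gap <- min(if (lb[1L] > 0) a[2L] - lb[1L] else Inf,
                   if (lb[2L] < Tt) lb[2L] - a[2L] else Inf)
        if (gap > reach) next
      }
      anchor <- a
      break
    }
    if (is.null(anchor)) stop("could not place clone anchor; slab too crowded")
    placed <- rbind(placed, anchor)
    cell_x <- c(cell_x, anchor[1L]); cell_y <- c(cell_y, anchor[2L])
    cell_clone <- c(cell_clone, ci)

    for (j in seq_len(n_mates)) {
      pos <- place_mate(anchor, d[j], cross[j], model, m, sep_ok, layer_bounds)
      rounds <- 0L
      while (is.null(pos) && rounds < 25L) {
        # ring at the drawn distance is blocked (large clones pack it):
        # redraw the separation from its own distribution and retry
        dj <- if (cross[j]) {
          rtnorm_mean(1L, p$cross_layer_sep_mean, p$cross_layer_sep_sd,
                      lower = p$min_separation_um)
        } else {
          rtnorm_mean(1L, p$same_layer_sep_mean, p$same_layer_sep_sd,
                      lower = p$min_separation_um)
        }
        pos <- place_mate(anchor, dj, cross[j], model, m, sep_ok, layer_bounds)
        rounds <- rounds + 1L
      }
      if (is.null(pos)) { # crowded: accept best-effort tangential placement
        crowded <- crowded + 1L
        s <- anchor[1L] + d[j] * sample(c(-1, 1), 1L)
        pos <- c(min(max(s, m), W - m), anchor[2L])
      }
      placed <- rbind(placed, pos)
      cell_x <- c(cell_x, pos[1L]); cell_y <- c(cell_y, pos[2L])
      cell_clone <- c(cell_clone, ci)
    }
  }

  # unlabeled filler cells to hit per-layer labeled fractions
  unl_x <- unl_y <- numeric(0)
  if (!is.null(p$labeled_fraction)) {
    lf <- unlist(p$labeled_fraction)
    lay <- layer_of(model, cell_y)
    for (ln in names(lf)) {
      n_lab <- sum(lay == ln, na.rm = TRUE)
      n_unl <- round(n_lab * (1 - lf[[ln]]) / lf[[ln]])
      if (n_unl <= 0) next
      i <- match(ln, model$layer_names)
      lo <- max(model$boundaries[i], m)
      hi <- min(model$boundaries[i + 1L], Tt - m)
      k <- 0L
      while (k < n_unl) {
        got <- FALSE
        for (try in seq_len(500L)) {
          u <- c(stats::runif(1, m, W - m), stats::runif(1, lo, hi))
          if (sep_ok(u)) { got <- TRUE; break }
        }
        if (!got) { crowded <- crowded + 1L } # place anyway
        placed <- rbind(placed, u)
        unl_x <- c(unl_x, u[1L]); unl_y <- c(unl_y, u[2L])
        k <- k + 1L
      }
    }
  }
  if (crowded > 0L) {
    warning(crowded, " cells placed without honoring the minimum separation ",
            "(slab too crowded)")
  }

  x <- c(cell_x, unl_x)
  y <- c(cell_y, unl_y)
  n_total <- length(x)
  n_labeled <- length(cell_x)
  clone_id <- c(cell_clone, rep(NA_integer_, length(unl_x)))
  z <- if (model$slab_z_um > 0) stats::runif(n_total, 0, model$slab_z_um)
       else rep(0, n_total)

  # intensity draws last, in one block, so the underlying standard normals are
  # identical across noise_sd settings under the same seed
  lev <- matrix(0L, n_total, p$channels)
  lev[seq_len(n_labeled), ] <- codes[cell_clone, , drop = FALSE]
  centers <- matrix(level_center(lev, p$levels), n_total, p$channels)
  noise <- matrix(stats::rnorm(n_total * p$channels), n_total, p$channels) * p$noise_sd
  intens <- pmin(pmax(centers + noise, 0), 255)

  cells <- data.frame(
    cell_id = seq_len(n_total),
    x_um = x, y_um = y, z_um = z,
    layer = layer_of(model, y),
    clone_id = clone_id
  )
  for (k in seq_len(p$channels)) cells[[paste0("ch", k)]] <- intens[, k]
  truth <- data.frame(
    cell_id = seq_len(n_labeled),
    clone_id = cell_clone,
    code = apply(codes[cell_clone, , drop = FALSE], 1L, paste0, collapse = "")
  )
  structure(list(cells = cells, truth = truth, model = model, params = p),
            class = "clone_sim")
}

#' @keywords internal
empty_clone_sim <- function(model, p) {
  cells <- data.frame(cell_id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), layer = character(0),
                      clone_id = integer(0))
  for (k in seq_len(p$channels)) cells[[paste0("ch", k)]] <- numeric(0)
  truth <- data.frame(cell_id = integer(0), clone_id = integer(0),
                      code = character(0))
  structure(list(cells = cells, truth = truth, model = model, params = p),
            class = "clone_sim")
}

#' @keywords internal
resolve_clone_sizes <- function(p) {
  s <- p$clone_sizes
  sizes <- if (is.function(s)) s(p$n_clones)
  else if (length(s) == 1L) rep(as.integer(s), p$n_clones)
  else as.integer(s)
  if (length(sizes) != p$n_clones || any(sizes < 1L)) {
    stop("clone sizes must be >= 1 and one per clone")
  }
  sizes
}

# Place one clone mate at exact distance d from `anchor`, tangential direction
# random, vertical component sampled uniformly over the depths that satisfy
# the layer condition (same layer vs different layer) and the slab bounds.
# Returns NULL if no placement satisfies the hard-core separation.
#' @keywords internal
place_mate <- function(anchor, d, cross, model, m, sep_ok, layer_bounds) {
  Tt <- model$thickness_um
  W <- model$slab_width_um
  lb <- layer_bounds(anchor[2L])
  for (try in seq_len(400L)) {
    if (!cross) {
      smin <- max(-1, (lb[1L] - anchor[2L]) / d, (m - anchor[2L]) / d)
      smax <- min(1, (lb[2L] - 1e-9 - anchor[2L]) / d, (Tt - m - anchor[2L]) / d)
      if (smin > smax) return(NULL)
      s <- stats::runif(1, smin, smax)
    } else {
      smin <- max(-1, (m - anchor[2L]) / d)
      smax <- min(1, (Tt - m - anchor[2L]) / d)
      if (smin >= smax) return(NULL)
      s <- stats::runif(1, smin, smax)
      depth <- anchor[2L] + d * s
      if (depth >= lb[1L] && depth < lb[2L]) next # still in anchor's layer
    }
    depth <- anchor[2L] + d * s
    h <- d * sqrt(max(0, 1 - s^2)) * sample(c(-1, 1), 1L)
    x <- anchor[1L] + h
    if (x < m || x > W - m) x <- anchor[1L] - h
    if (x < m || x > W - m) next
    pos <- c(x, depth)
    if (sep_ok(pos)) return(pos)
  }
  NULL
}

#' @export
print.clone_sim <- function(x, ...) {
  cat("Simulated clones:", max(0, x$params$n_clones), "clones,",
      nrow(x$truth), "labeled cells,",
      nrow(x$cells) - nrow(x$truth), "unlabeled cells\n")
  invisible(x)
}

#' Simulate a pair-distance table at the dispersion-study level
#'
#' Draws clonally related / unrelated cell-pair distances per (relatedness x
#' layer-class) category directly from location-calibrated truncated normals,
#' emulating the pair-level readout of a clonal dispersion study. Defaults are
#' the four study categories: related pairs 36.8 +/- 20.5 um (same layer) and
#' 142.1 +/- 76.8 um (different layers); unrelated pairs 41.8 +/- 17.3 um and
#' 294.9 +/- 105.4 um.
#'
#' @param n_per_category Number of pairs per category (scalar or length 4, in
#'   the order related/same, related/different, unrelated/same,
#'   unrelated/different).
#' @param related_same,related_diff,unrelated_same,unrelated_diff Numeric
#'   `c(mean, sd)` (um) per category.
#' @param seed Optional integer seed.
#' @return A `pair_table` data.frame: `cell_a, cell_b, relatedness,
#'   layer_class, distance_um`.
#' @export
simulate_pair_distances <- function(n_per_category = 200,
                                    related_same = c(36.8, 20.5),
                                    related_diff = c(142.1, 76.8),
                                    unrelated_same = c(41.8, 17.3),
                                    unrelated_diff = c(294.9, 105.4),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  n <- rep_len(n_per_category, 4L)
  spec <- list(
    list(rel = "related", lay = "same", par = related_same, n = n[1L]),
    list(rel = "related", lay = "different", par = related_diff, n = n[2L]),
    list(rel = "unrelated", lay = "same", par = unrelated_same, n = n[3L]),
    list(rel = "unrelated", lay = "different", par = unrelated_diff, n = n[4L])
  )
  out <- do.call(rbind, lapply(spec, function(s) {
    if (s$n == 0L) return(NULL)
    data.frame(relatedness = s$rel, layer_class = s$lay,
               distance_um = rtnorm_mean(s$n, s$par[1L], s$par[2L]))
  }))
  out$cell_a <- seq_len(2L * nrow(out))[c(TRUE, FALSE)]
  out$cell_b <- out$cell_a + 1L
  structure(out[c("cell_a", "cell_b", "relatedness", "layer_class",
                  "distance_um")],
            class = c("pair_table", "data.frame"))
}
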