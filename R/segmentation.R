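#' Exact intensity histogram of an 8-bit channel
#'
#' @param channel_image Integer-valued matrix/array with values in 0..255.
#' @return List of class `intensity_histogram`: `counts` (length 256, value v
#'   at index v+1) and `total` (pixel count).
#' @export
compute_histogram <- function(channel_image) {
  v <- as.vector(channel_image)
  if (!is.numeric(v) || anyNA(v)) stop("image must be numeric without NA")
  if (any(v != floor(v)) || any(v < 0 | v > 255)) {
    stop("image must be 8-bit: integer values in 0..255")
  }
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  structure(list(counts = counts, total = length(v)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  occ <- which(x$counts > 0L) - 1L
  cat("Intensity histogram:", x$total, "px,", length(occ),
      "distinct values in [", min(occ), ",", max(occ), "]\n")
  invisible(x)
}

# weighted mean/sd of intensities lo..hi under histogram counts
interval_stats <- function(counts, lo, hi) {
  v <- lo:hi
  w <- counts[v + 1L]
  n <- sum(w)
  mu <- sum(w * v) / n
  list(mass = n, mu = mu, sigma = sqrt(sum(w * (v - mu)^2) / n))
}

n_distinct_in <- function(counts, lo, hi) sum(counts[(lo:hi) + 1L] > 0L)

#' Iterative histogram-based multi-level threshold selection
#'
#' Selects `n` strictly increasing thresholds inside the occupied intensity
#' range by iterative interval subdivision of the histogram: a worklist of
#' intensity intervals starts with the occupied range; intervals are processed
#' in decreasing order of pixel mass; for each interval the occupancy-weighted
#' mean `mu` and SD `sigma` are computed and sub-thresholds are emitted at
#' `mu - w*sigma` and `mu + w*sigma` (at `mu` alone when `w = 0`), clipped
#' inside the interval, with collisions against existing thresholds resolved
#' by shifting one intensity unit upward; recursion continues on the outer
#' sub-intervals. If the worklist empties before `n` thresholds exist, the
#' current segments are re-scanned (largest pixel mass first) so that any
#' segment still holding two or more distinct values can be subdivided. The
#' procedure is fully deterministic.
#'
#' A threshold `t` is the lowest intensity of the segment above it: a pixel of
#' value `v` belongs to segment `findInterval(v, thresholds)`.
#'
#' @param hist An [compute_histogram()] result (or an 8-bit image, which is
#'   tabulated first).
#' @param n Number of thresholds requested (>= 1). If the image has only `k`
#'   distinct values, at most `k - 1` thresholds exist; fewer are returned
#'   with a warning.
#' @param w Spread weight of the subdivision rule (default 1).
#' @return List of class `threshold_set`: `n` (thresholds produced),
#'   `thresholds` (sorted), `psnr_db` (PSNR of the segment-mean reconstruction
#'   against the histogram's image; `Inf` when the reconstruction is exact),
#'   `w`.
#' @export
select_thresholds <- function(hist, n, w = 1) {
  if (!inherits(hist, "intensity_histogram")) hist <- compute_histogram(hist)
  if (n < 1L) stop("`n` must be >= 1")
  counts <- hist$counts
  occ <- which(counts > 0L) - 1L
  if (length(occ) < 2L) {
    stop("degenerate histogram: fewer than 2 distinct intensity values")
  }
  n_max <- length(occ) - 1L
  thresholds <- integer(0)

  emit <- function(cand, lo, hi) {
    t <- min(max(cand, lo + 1L), hi)
    while (t %in% thresholds) t <- t + 1L
    if (t > hi) return(NULL)
    thresholds <<- c(thresholds, t)
    t
  }
  splittable <- function(lo, hi) {
    hi > lo && n_distinct_in(counts, lo, hi) >= 2L
  }
  worklist <- list(c(min(occ), max(occ)))

  while (length(thresholds) < min(n, n_max)) {
    if (length(worklist) == 0L) {
      # completion rule: re-scan current segments for splittable ones
      b <- c(min(occ), sort(thresholds), max(occ) + 1L)
      segs <- Map(function(lo, hi) c(lo, hi), b[-length(b)], b[-1L] - 1L)
      worklist <- Filter(function(iv) splittable(iv[1L], iv[2L]), segs)
      if (length(worklist) == 0L) break
    }
    mass <- vapply(worklist, function(iv)
      interval_stats(counts, iv[1L], iv[2L])$mass, numeric(1))
    los <- vapply(worklist, `[`, numeric(1), 1L)
    pick <- order(-mass, los)[1L]
    iv <- worklist[[pick]]
    worklist <- worklist[-pick]
    lo <- iv[1L]; hi <- iv[2L]
    if (!splittable(lo, hi)) next
    st <- interval_stats(counts, lo, hi)
    cands <- if (w == 0) as.integer(round(st$mu))
             else as.integer(round(c(st$mu - w * st$sigma, st$mu + w * st$sigma)))
    emitted <- integer(0)
    for (cand in cands) {
      if (length(thresholds) >= min(n, n_max)) break
      t <- emit(cand, lo, hi)
      if (!is.null(t)) emitted <- c(emitted, t)
    }
    if (length(emitted)) {
      # recurse on the outer sub-intervals only
      t_lo <- min(emitted); t_hi <- max(emitted)
      if (splittable(lo, t_lo - 1L)) worklist <- c(worklist, list(c(lo, t_lo - 1L)))
      if (splittable(t_hi, hi)) worklist <- c(worklist, list(c(t_hi, hi)))
    }
  }
  if (length(thresholds) < n) {
    warning("only ", length(thresholds), " of ", n,
            " thresholds could be produced (", length(occ),
            " distinct values)")
  }
  thresholds <- sort(thresholds)
  structure(
    list(n = length(thresholds), thresholds = thresholds,
         psnr_db = psnr_from_hist(counts, thresholds), w = w),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Threshold set: n =", x$n, "->",
      paste(x$thresholds, collapse = ", "),
      sprintf("(PSNR %.2f dB)\n", x$psnr_db))
  invisible(x)
}

# PSNR of the segment-mean reconstruction computed on the histogram alone
psnr_from_hist <- function(counts, thresholds) {
  v <- 0:255
  seg <- findInterval(v, thresholds)
  w <- counts
  repr <- vapply(split(seq_along(v), seg), function(i) {
    if (sum(w[i]) == 0) return(NA_real_)
    sum(w[i] * v[i]) / sum(w[i])
  }, numeric(1))
  rv <- repr[as.character(seg)]
  mse <- sum(w * (v - rv)^2, na.rm = TRUE) / sum(w)
  if (mse == 0) Inf else 20 * log10(255 / sqrt(mse))
}

#' Piecewise-constant reconstruction of a channel under a threshold set
#'
#' Replaces every pixel by the mean intensity of its segment (segment means
#' minimize the reconstruction RMSE for fixed thresholds). Segments that
#' contain no pixel are assigned their interval midpoint as representative.
#'
#' @param channel_image 8-bit matrix.
#' @param ts A [select_thresholds()] result or a bare numeric vector of
#'   thresholds.
#' @return List of class `segmented_image`: `segments` (integer matrix of
#'   segment indices in `0..n`), `repr` (representative intensity per
#'   segment), `reconstructed` (numeric matrix), `thresholds`.
#' @export
reconstruct <- function(channel_image, ts) {
  thr <- if (inherits(ts, "threshold_set")) ts$thresholds else sort(ts)
  hist <- compute_histogram(channel_image)
  v <- 0:255
  seg_v <- findInterval(v, thr)
  bounds <- c(0, thr, 256)
  repr <- vapply(0:length(thr), function(s) {
    i <- which(seg_v == s)
    if (sum(hist$counts[i]) == 0) (bounds[s + 1L] + bounds[s + 2L] - 1) / 2
    else sum(hist$counts[i] * v[i]) / sum(hist$counts[i])
  }, numeric(1))
  seg <- matrix(findInterval(channel_image, thr), nrow(channel_image))
  rec <- matrix(repr[seg + 1L], nrow(channel_image))
  structure(list(segments = seg, repr = repr, reconstructed = rec,
                 thresholds = thr),
            class = "segmented_image")
}

#' Peak signal-to-noise ratio between two 8-bit images
#'
#' `20 * log10(255 / RMSE)`. Identical inputs have zero RMSE; infinite PSNR is
#' represented by the sentinel `Inf`, which orders above every finite value.
#'
#' @param original,reconstructed Equal-shaped numeric arrays on the 8-bit
#'   scale (MAX = 255).
#' @return PSNR in dB (`Inf` for identical inputs).
#' @export
psnr <- function(original, reconstructed) {
  if (!identical(dim(original), dim(reconstructed)) ||
      length(original) != length(reconstructed)) {
    stop("shape mismatch between original and reconstructed image")
  }
  mse <- mean((as.numeric(original) - as.numeric(reconstructed))^2)
  if (mse == 0) Inf else 20 * log10(255 / sqrt(mse))
}

#' Choose the number of thresholds by the PSNR elbow rule
#'
#' Computes threshold sets over `n_range` and returns the smallest `n` whose
#' PSNR gain over `n - 1` falls below `epsilon_db`. If a reconstruction
#' becomes exact (infinite PSNR) or no further segment can be subdivided, that
#' saturating `n` is returned. A constant (degenerate) image yields an `n = 0`
#' single-segment result with a warning. The full PSNR curve is attached as
#' attribute `psnr_curve`.
#'
#' @param channel_image 8-bit matrix.
#' @param n_range Candidate threshold counts (default `2:15`).
#' @param epsilon_db Minimum worthwhile PSNR gain in dB (> 0, default 0.5).
#' @param w Subdivision spread weight passed to [select_thresholds()].
#' @return A [select_thresholds()] `threshold_set` (possibly with `n = 0`).
#' @export
choose_optimal_n <- function(channel_image, n_range = 2:15, epsilon_db = 0.5,
                             w = 1) {
  if (length(n_range) == 0L) stop("`n_range` must be non-empty")
  if (epsilon_db <= 0) stop("`epsilon_db` must be > 0")
  n_range <- sort(unique(as.integer(n_range)))
  if (any(n_range < 1L)) stop("`n_range` must contain counts >= 1")
  hist <- compute_histogram(channel_image)
  occ <- which(hist$counts > 0L) - 1L
  if (length(occ) < 2L) {
    warning("degenerate (constant) image: returning single-segment result")
    ts <- structure(list(n = 0L, thresholds = integer(0), psnr_db = Inf, w = w),
                    class = "threshold_set")
    attr(ts, "psnr_curve") <- data.frame(n = 0L, psnr_db = Inf)
    return(ts)
  }
  prev_psnr <- if (min(n_range) == 1L) {
    psnr_from_hist(hist$counts, integer(0)) # single segment baseline
  } else {
    select_thresholds(hist, min(n_range) - 1L, w)$psnr_db
  }
  curve <- data.frame(n = min(n_range) - 1L, psnr_db = prev_psnr)
  chosen <- NULL
  for (n in n_range) {
    ts <- suppressWarnings(select_thresholds(hist, n, w))
    curve <- rbind(curve, data.frame(n = n, psnr_db = ts$psnr_db))
    if (ts$n < n || is.infinite(ts$psnr_db)) { chosen <- ts; break } # saturated
    if (ts$psnr_db - prev_psnr < epsilon_db) { chosen <- ts; break }
    prev_psnr <- ts$psnr_db
  }
  if (is.null(chosen)) chosen <- ts # end of range: largest n searched
  attr(chosen, "psnr_curve") <- curve
  chosen
}

#' Detect cells in a multichannel image
#'
#' Foreground is the union, over channels, of pixels at or above that
#' channel's lowest non-zero threshold. Connected components (8-connectivity)
#' of at least `min_area` pixels become cells. Each cell's centroid is the
#' unweighted mean of its 0-based pixel coordinates converted to um, and its
#' per-channel intensity is the mean over the bright core of the component
#' (pixels whose channel-summed intensity reaches `core_frac` of the
#' component's peak), which avoids the downward bias that dim edge roll-off
#' pixels would otherwise impose on an absolute intensity code.
#'
#' @param image `multichannel_image` array (H x W x C), list of matrices, or a
#'   single matrix.
#' @param pixel_size_um um per pixel (taken from the image attribute if
#'   present).
#' @param min_area Minimum component area in px.
#' @param thresholds Optional list (one per channel) of `threshold_set`s or
#'   numeric threshold vectors; computed by [choose_optimal_n()] if `NULL`.
#' @param n_range,epsilon_db,w Passed to [choose_optimal_n()] when thresholds
#'   are computed internally.
#' @param core_frac Fraction of the component's peak summed intensity defining
#'   the measurement core (1 keeps only peak pixels; 0 uses the full support).
#' @return Data.frame `cell_id, x_um, y_um, area_px, ch1..chK` with attributes
#'   `thresholds` (per-channel `threshold_set`s) and `pixel_size_um`. Empty
#'   foreground gives an empty table.
#' @export
detect_cells <- function(image, pixel_size_um = NULL, min_area = 5L,
                         thresholds = NULL, n_range = 2:15, epsilon_db = 0.5,
                         w = 1, core_frac = 0.95) {
  chans <- as_channel_list(image)
  K <- length(chans)
  ps <- pixel_size_um %||% attr(image, "pixel_size_um") %||% 1
  ts_list <- vector("list", K)
  for (k in seq_len(K)) {
    ts_list[[k]] <- if (!is.null(thresholds)) {
      tk <- thresholds[[k]]
      if (inherits(tk, "threshold_set")) tk
      else structure(list(n = length(tk), thresholds = sort(as.integer(tk)),
                          psnr_db = NA_real_, w = w), class = "threshold_set")
    } else {
      suppressWarnings(choose_optimal_n(chans[[k]], n_range, epsilon_db, w))
    }
  }
  H <- nrow(chans[[1L]]); W <- ncol(chans[[1L]])
  fg <- matrix(FALSE, H, W)
  for (k in seq_len(K)) {
    thr <- ts_list[[k]]$thresholds
    thr <- thr[thr > 0]
    if (length(thr)) fg <- fg | (chans[[k]] >= min(thr))
  }
  empty <- data.frame(cell_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_px = integer(0))
  for (k in seq_len(K)) empty[[paste0("ch", k)]] <- numeric(0)
  if (!any(fg)) {
    return(structure(empty, thresholds = ts_list, pixel_size_um = ps))
  }
  lab <- EBImage::bwlabel(fg)
  area <- tabulate(lab[lab > 0L])
  keep <- which(area >= min_area)
  if (length(keep) == 0L) {
    return(structure(empty, thresholds = ts_list, pixel_size_um = ps))
  }
  total <- Reduce(`+`, chans)
  sel <- lab > 0L & (lab %in% keep)
  members <- split(which(sel), lab[sel])
  # order components deterministically by label id
  members <- members[order(as.integer(names(members)))]
  rows_of <- function(i) (i - 1L) %% H      # 0-based row
  cols_of <- function(i) (i - 1L) %/% H     # 0-based col
  recs <- lapply(seq_along(members), function(j) {
    idx <- members[[j]]
    core <- idx[total[idx] >= core_frac * max(total[idx])]
    rec <- data.frame(
      cell_id = j,
      x_um = mean(cols_of(idx)) * ps,
      y_um = mean(rows_of(idx)) * ps,
      area_px = length(idx)
    )
    for (k in seq_len(K)) rec[[paste0("ch", k)]] <- mean(chans[[k]][core])
    rec
  })
  out <- do.call(rbind, recs)
  structure(out, thresholds = ts_list, pixel_size_um = ps)
}

#' @keywords internal
as_channel_list <- function(image) {
  if (is.list(image)) return(lapply(image, as.matrix))
  d <- dim(image)
  if (length(d) == 2L) return(list(matrix(image, d[1L], d[2L])))
  if (length(d) == 3L) {
    return(lapply(seq_len(d[3L]), function(k)
      matrix(image[, , k], d[1L], d[2L])))
  }
  stop("image must be a matrix, H x W x C array, or list of matrices")
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
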