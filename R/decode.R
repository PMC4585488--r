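#' Intensity quantizer: five 51-point levels on the 8-bit scale
#'
#' The fluorophore code of a cell is obtained by quantizing its mean intensity
#' in each channel into five equal levels of 51 intensity points each
#' (0-50, 51-101, 102-152, 153-203, 204-255). `quantize_intensity()` implements
#' `floor(intensity / 51)` with the single leftover gray value 255 clamped into
#' the top level, so the map is total on [0, 255] and monotone non-decreasing.
#'
#' @param intensity Numeric vector of intensities in [0, 255].
#' @param levels Number of levels (default 5; level width is `floor(256/levels)`
#'   except that the top level absorbs the remainder of the scale).
#' @return Integer vector of levels in `0:(levels-1)`.
#' @examples
#' quantize_intensity(c(0, 50, 51, 127, 204, 255))
#' @export
quantize_intensity <- function(intensity, levels = 5L) {
  if (!is.numeric(intensity)) stop("`intensity` must be numeric")
  if (anyNA(intensity)) stop("`intensity` contains NA")
  if (any(intensity < 0 | intensity > 255)) {
    bad <- which(intensity < 0 | intensity > 255)[1L]
    stop(sprintf("intensity out of [0,255] at position %d: %g", bad, intensity[bad]))
  }
  width <- quantizer_bin_width(levels)
  pmin(as.integer(floor(intensity / width)), levels - 1L)
}

#' @rdname quantize_intensity
#' @export
quantizer_bin_width <- function(levels = 5L) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("need at least 2 levels")
  256L %/% levels
}

#' @rdname quantize_intensity
#' @details `quantizer_bins()` tabulates the level intervals and their center
#'   intensities `width * level + floor(width/2)`; the centers are the nominal
#'   expression intensities used by the clone simulator because they maximize
#'   the margin to the quantizer boundaries.
#' @export
quantizer_bins <- function(levels = 5L) {
  width <- quantizer_bin_width(levels)
  lev <- seq_len(levels) - 1L
  lower <- width * lev
  upper <- c(width * (lev[-1L]), 256L) - 1L
  data.frame(
    level = lev,
    lower = lower,
    upper = upper,
    center = width * lev + width %/% 2L
  )
}

#' Nominal bin-center intensity of a quantizer level
#' @param level Integer vector of levels.
#' @param levels Number of quantizer levels.
#' @return Numeric intensities (51*level + 25 for the default quantizer).
#' @export
level_center <- function(level, levels = 5L) {
  width <- quantizer_bin_width(levels)
  if (any(level < 0 | level >= levels)) stop("level out of range")
  width * as.numeric(level) + width %/% 2
}

#' Award fluorophore codes to cells
#'
#' Quantizes each cell's per-channel mean intensity into discrete levels and
#' concatenates them (in channel order) into the cell's code. Cells whose code
#' is all-zero carry no detectable fluorophore combination and are flagged as
#' unlabeled; they are excluded from clone grouping.
#'
#' @param cells A cell table (data.frame) with intensity columns `ch1..chK`.
#' @param levels Number of quantizer levels per channel.
#' @return The input data.frame with added integer columns `code_ch1..code_chK`,
#'   a character column `code` (levels pasted without separator, channel order),
#'   and a logical column `unlabeled`.
#' @examples
#' encode_cells(data.frame(ch1 = 25, ch2 = 76, ch3 = 127, ch4 = 229))$code
#' @export
encode_cells <- function(cells, levels = 5L) {
  ch <- channel_columns(cells)
  if (length(ch) == 0L) stop("no channel intensity columns (ch1..chK) found")
  lev <- lapply(cells[ch], quantize_intensity, levels = levels)
  names(lev) <- paste0("code_", ch)
  cells[names(lev)] <- lev
  lev_mat <- do.call(cbind, lev)
  cells$code <- if (nrow(cells)) apply(lev_mat, 1L, paste0, collapse = "") else character(0)
  cells$unlabeled <- if (nrow(cells)) rowSums(lev_mat) == 0L else logical(0)
  cells
}

#' @keywords internal
channel_columns <- function(cells) {
  nm <- names(cells)
  ch <- nm[grepl("^ch[0-9]+$", nm)]
  ch[order(as.integer(sub("^ch", "", ch)))]
}

#' Partition encoded cells into clones by code identity
#'
#' All labeled cells sharing one code within one tissue section form one clone
#' (code reiteration across a section is taken as clonal identity). Optionally,
#' same-code cells can additionally be split by single-linkage clustering at a
#' maximum link distance, as a sensitivity analysis for true code collisions
#' between spatially implausible cells. Clones are never merged across
#' sections.
#'
#' @param cells Encoded cell table (see [encode_cells()]) with coordinate
#'   columns `x_um`, `y_um` (and optionally `z_um`) and optionally a `section`
#'   column (a single section is assumed if absent).
#' @param max_link_distance_um If non-NULL, same-code cells further apart than
#'   this single-linkage distance are split into separate clones.
#' @return A list of class `clone_partition`:
#'   `cells` — the input with an integer `clone` column (NA for unlabeled);
#'   `groups` — data.frame `clone, code, section, size, extent_um` where
#'   `extent_um` is the maximum pairwise member distance.
#' @export
group_clones <- function(cells, max_link_distance_um = NULL) {
  if (is.null(cells$code)) cells <- encode_cells(cells)
  if (is.null(cells$section)) cells$section <- 1L
  cells$clone <- NA_integer_
  labeled <- which(!cells$unlabeled)
  key <- paste(cells$section, cells$code, sep = "\r")
  next_id <- 1L
  groups <- list()
  for (k in unique(key[labeled])) {
    idx <- labeled[key[labeled] == k]
    sub <- rep(1L, length(idx))
    if (!is.null(max_link_distance_um) && length(idx) > 1L) {
      d <- stats::dist(cell_coords(cells[idx, , drop = FALSE]))
      sub <- stats::cutree(stats::hclust(d, method = "single"),
                           h = max_link_distance_um)
    }
    for (s in sort(unique(sub))) {
      members <- idx[sub == s]
      cells$clone[members] <- next_id
      ext <- 0
      if (length(members) > 1L) {
        ext <- max(stats::dist(cell_coords(cells[members, , drop = FALSE])))
      }
      groups[[next_id]] <- data.frame(
        clone = next_id,
        code = cells$code[members[1L]],
        section = cells$section[members[1L]],
        size = length(members),
        extent_um = ext
      )
      next_id <- next_id + 1L
    }
  }
  groups <- if (length(groups)) do.call(rbind, groups) else
    data.frame(clone = integer(0), code = character(0), section = integer(0),
               size = integer(0), extent_um = numeric(0))
  structure(list(cells = cells, groups = groups), class = "clone_partition")
}

#' @export
print.clone_partition <- function(x, ...) {
  cat("Clone partition:", nrow(x$groups), "clones over",
      sum(!is.na(x$cells$clone)), "labeled cells (",
      sum(x$cells$unlabeled), "unlabeled)\n")
  invisible(x)
}

#' @keywords internal
cell_coords <- function(cells) {
  cols <- intersect(c("x_um", "y_um", "z_um"), names(cells))
  as.matrix(cells[cols])
}

#' Clone-size frequency histogram
#'
#' Bins clone sizes into the conventional size classes 1-8, 8-16, 16-32
#' (half-open on the right except the last bin, which is closed). Also reports
#' which integer sizes inside the binned range are unrepresented, since gaps in
#' the arithmetic progression of observed clone sizes are themselves
#' informative about rounds of amplifying divisions.
#'
#' @param partition A `clone_partition` (or a data.frame with a `size` column,
#'   or a bare integer vector of clone sizes).
#' @param breaks Increasing numeric bin edges (default `c(1, 8, 16, 32)`).
#' @return List of class `clone_size_histogram` with `breaks`, `counts`
#'   (length `length(breaks)-1`, sums to the number of clones), `labels`, and
#'   `missing_sizes` (unobserved integer sizes in `[breaks[1], max(breaks)]`).
#' @export
clone_size_histogram <- function(partition, breaks = c(1, 8, 16, 32)) {
  sizes <- if (inherits(partition, "clone_partition")) partition$groups$size
  else if (is.data.frame(partition)) partition$size
  else as.numeric(partition)
  if (any(diff(breaks) <= 0)) stop("bins must be non-overlapping: `breaks` strictly increasing")
  if (length(sizes) && any(sizes < breaks[1L] | sizes > breaks[length(breaks)])) {
    stop("clone sizes outside the binned range [", breaks[1L], ", ",
         breaks[length(breaks)], "]")
  }
  bin <- findInterval(sizes, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  labels <- sprintf("[%g,%g%s", breaks[-length(breaks)], breaks[-1L],
                    c(rep(")", length(breaks) - 2L), "]"))
  all_sizes <- seq.int(ceiling(breaks[1L]), floor(breaks[length(breaks)]))
  structure(
    list(breaks = breaks, counts = counts, labels = labels,
         n_clones = length(sizes),
         missing_sizes = setdiff(all_sizes, unique(sizes))),
    class = "clone_size_histogram"
  )
}

#' @export
print.clone_size_histogram <- function(x, ...) {
  cat("Clone sizes (", x$n_clones, " clones):\n", sep = "")
  print(stats::setNames(x$counts, x$labels))
  if (length(x$missing_sizes)) {
    cat("unrepresented sizes:", paste(x$missing_sizes, collapse = ", "), "\n")
  }
  invisible(x)
}
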