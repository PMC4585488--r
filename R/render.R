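#' Rendering configuration for synthetic multichannel images
#'
#' @param pixel_size_um Pixel size in um/px (> 0).
#' @param cell_radius_um Soma radius in um; each cell is rendered as a
#'   uniformly filled disk of this radius with a Gaussian edge roll-off, so
#'   interior pixels carry the cell's nominal channel intensity (a fluorescent
#'   soma fill, not a point source).
#' @param edge_sigma_px SD (px) of the Gaussian edge roll-off; 0 gives a hard
#'   disk.
#' @param background_level Additive background intensity (8-bit units); must be
#'   below the lowest non-zero quantizer bin center so background never mimics
#'   expression.
#' @param field_um Optional `c(width, height)` of the field in um; if `NULL`
#'   the field is sized to the cells plus `margin_um`.
#' @param margin_um Margin added around the cells when auto-sizing.
#' @return List of class `render_config`.
#' @export
render_config <- function(pixel_size_um = 1, cell_radius_um = 3,
                          edge_sigma_px = 0.8, background_level = 8,
                          field_um = NULL, margin_um = 10) {
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0")
  if (cell_radius_um <= 0) stop("`cell_radius_um` must be > 0")
  if (edge_sigma_px < 0) stop("`edge_sigma_px` must be >= 0")
  lowest_nonzero_center <- level_center(1L)
  if (background_level < 0 || background_level >= lowest_nonzero_center) {
    stop("`background_level` must be in [0, ", lowest_nonzero_center,
         ") (below the lowest non-zero bin center)")
  }
  structure(as.list(environment()), class = "render_config")
}

#' Render a cell table as a multichannel 8-bit image
#'
#' Each cell contributes, in every channel, a disk of radius
#' `cell_radius_um` at its nominal channel intensity with a Gaussian edge
#' roll-off (profile `pnorm((R - r) / sigma)`); contributions are additive, a
#' constant background is added, and the result is rounded and clipped to the
#' 8-bit range.
#'
#' @param cells Cell table with `x_um`, `y_um` and channel columns `ch1..chK`.
#' @param cfg A [render_config()].
#' @return Integer array `height x width x channels` of class
#'   `multichannel_image` with attribute `pixel_size_um`.
#' @export
render_image <- function(cells, cfg = render_config()) {
  stopifnot(inherits(cfg, "render_config"))
  ch <- channel_columns(cells)
  if (length(ch) == 0L) stop("no channel intensity columns (ch1..chK) found")
  ps <- cfg$pixel_size_um
  if (is.null(cfg$field_um)) {
    w_um <- (if (nrow(cells)) max(cells$x_um) else 0) + cfg$margin_um
    h_um <- (if (nrow(cells)) max(cells$y_um) else 0) + cfg$margin_um
  } else {
    w_um <- cfg$field_um[1L]; h_um <- cfg$field_um[2L]
  }
  W <- max(1L, as.integer(ceiling(w_um / ps)))
  H <- max(1L, as.integer(ceiling(h_um / ps)))
  if (nrow(cells)) {
    out_of_field <- cells$x_um < 0 | cells$y_um < 0 |
      cells$x_um / ps > W - 1L | cells$y_um / ps > H - 1L
    if (any(out_of_field)) {
      ids <- if (!is.null(cells$cell_id)) cells$cell_id[out_of_field]
             else which(out_of_field)
      stop("cell centroids outside the field: ",
           paste(utils::head(ids, 20L), collapse = ", "))
    }
  }
  img <- array(0, dim = c(H, W, length(ch)))
  R <- cfg$cell_radius_um / ps
  sig <- cfg$edge_sigma_px
  reach <- ceiling(R + 4 * max(sig, 0.25))
  for (i in seq_len(nrow(cells))) {
    xc <- cells$x_um[i] / ps
    yc <- cells$y_um[i] / ps
    cols <- max(0L, floor(xc - reach)):min(W - 1L, ceiling(xc + reach))
    rows <- max(0L, floor(yc - reach)):min(H - 1L, ceiling(yc + reach))
    r <- sqrt(outer((rows - yc)^2, (cols - xc)^2, `+`))
    prof <- if (sig > 0) stats::pnorm((R - r) / sig) else (r <= R) * 1
    for (k in seq_along(ch)) {
      img[rows + 1L, cols + 1L, k] <- img[rows + 1L, cols + 1L, k] +
        prof * cells[[ch[k]]][i]
    }
  }
  img <- round(img + cfg$background_level)
  img[img > 255] <- 255
  img[img < 0] <- 0
  storage.mode(img) <- "integer"
  structure(img, class = "multichannel_image", pixel_size_um = ps)
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x)
  cat("Multichannel 8-bit image:", d[1L], "x", d[2L], "px,", d[3L],
      "channels,", attr(x, "pixel_size_um"), "um/px\n")
  invisible(x)
}

#' Read and write multichannel 8-bit TIFF images
#'
#' Channel-first convention: one TIFF directory (page) per channel.
#'
#' @param img Integer array `height x width x channels` with values in 0..255.
#' @param path File path.
#' @param pixel_size_um Pixel size recorded on the returned image.
#' @return `write_image_tiff` returns `path` invisibly; `read_image_tiff`
#'   returns a `multichannel_image` array.
#' @export
write_image_tiff <- function(img, path) {
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  pages <- lapply(seq_len(dim(img)[3L]), function(k) img[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, pixel_size_um = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1L] # tolerate gray stored with alpha
    m
  })
  img <- array(0L, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) img[, , k] <- as.integer(round(pages[[k]] * 255))
  structure(img, class = "multichannel_image", pixel_size_um = pixel_size_um)
}
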