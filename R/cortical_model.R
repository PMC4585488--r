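#' Laminated cortical slab geometry
#'
#' A `cortical_model` describes the geometry used by the clone simulator and
#' by layer assignment: an ordered stack of cortical layers given as contiguous
#' half-open depth intervals `[a, b)` in micrometres, with depth 0 at the pial
#' surface increasing toward the white matter, plus the tangential extent of
#' the simulated slab and an optional section thickness in z.
#'
#' @param boundaries Numeric vector of layer boundary depths in um,
#'   strictly increasing, starting at the pial surface (typically 0). There is
#'   one more boundary than there are layers; the last boundary is the total
#'   cortical thickness.
#' @param layer_names Character vector of layer labels, ordered from pia to
#'   white matter, one per interval.
#' @param slab_width_um Tangential (x) extent of the simulated slab, um.
#' @param slab_z_um Section thickness in z, um; 0 gives a planar (2D) model.
#' @return An object of class `cortical_model` with fields `layer_names`,
#'   `boundaries`, `thickness_um`, `slab_width_um`, `slab_z_um`.
#' @examples
#' m <- cortical_model(c(0, 100, 200), c("upper", "lower"))
#' layer_of(m, c(0, 99.9, 100, 199))
#' @export
cortical_model <- function(boundaries, layer_names, slab_width_um = 2000,
                           slab_z_um = 0) {
  if (!is.numeric(boundaries) || anyNA(boundaries)) {
    stop("`boundaries` must be a numeric vector without NA")
  }
  if (length(layer_names) != length(boundaries) - 1L || length(layer_names) < 1L) {
    stop("need exactly one more boundary than layer names")
  }
  if (any(diff(boundaries) <= 0)) {
    stop("layer boundaries must be strictly increasing (overlapping or unordered intervals)")
  }
  if (boundaries[1L] < 0) stop("boundaries must be non-negative depths")
  if (slab_width_um <= 0) stop("`slab_width_um` must be positive")
  if (slab_z_um < 0) stop("`slab_z_um` must be >= 0")
  structure(
    list(
      layer_names = as.character(layer_names),
      boundaries = as.numeric(boundaries),
      thickness_um = boundaries[length(boundaries)],
      slab_width_um = slab_width_um,
      slab_z_um = slab_z_um
    ),
    class = "cortical_model"
  )
}

#' @export
print.cortical_model <- function(x, ...) {
  cat("Cortical slab model:", length(x$layer_names), "layers,",
      x$thickness_um, "um deep x", x$slab_width_um, "um wide")
  if (x$slab_z_um > 0) cat(" x", x$slab_z_um, "um thick")
  cat("\n")
  iv <- sprintf("[%g, %g)", x$boundaries[-length(x$boundaries)], x$boundaries[-1L])
  cat(paste0("  ", format(x$layer_names), "  ", iv, collapse = "\n"), "\n")
  invisible(x)
}

#' Map depths to cortical layers
#'
#' Assigns each depth (um from the pial surface) to its layer under the
#' half-open convention: a depth exactly on an internal boundary belongs to
#' the deeper (next) layer; the deepest boundary itself is included in the
#' last layer. Depths outside `[0, thickness]` return `NA`.
#'
#' @param model A [cortical_model()].
#' @param depth_um Numeric vector of depths in um.
#' @return Character vector of layer names (NA outside the modeled range).
#' @export
layer_of <- function(model, depth_um) {
  stopifnot(inherits(model, "cortical_model"))
  idx <- findInterval(depth_um, model$boundaries, rightmost.closed = TRUE)
  idx[depth_um < model$boundaries[1L] |
        depth_um > model$thickness_um] <- NA_integer_
  model$layer_names[idx]
}

#' Default six-layer mouse somatosensory cortex model
#'
#' Layer boundaries approximating a ~1 mm thick early-postnatal mouse S1
#' cortex with layers L1, L2/3, L4, L5, L6 and the subplate (SP). Proportions
#' are round-number approximations of Nissl-stained S1 sections; they are a
#' simulation default, not a measurement.
#'
#' @param slab_width_um Tangential slab extent, um.
#' @param slab_z_um Section thickness in z, um (0 = planar).
#' @return A [cortical_model()].
#' @export
default_cortical_model <- function(slab_width_um = 2000, slab_z_um = 0) {
  cortical_model(
    boundaries = c(0, 100, 350, 500, 700, 950, 1000),
    layer_names = c("L1", "L2/3", "L4", "L5", "L6", "SP"),
    slab_width_um = slab_width_um,
    slab_z_um = slab_z_um
  )
}

#' Supragranular / infragranular layer grouping
#'
#' Default grouping used for aggregate laminar statistics: supragranular =
#' L2/3 + L4, infragranular = L5 + L6 + SP. L1 is essentially cell-sparse and
#' belongs to neither aggregate.
#'
#' @return Named list of character vectors of layer names.
#' @export
default_layer_groups <- function() {
  list(
    supragranular = c("L2/3", "L4"),
    infragranular = c("L5", "L6", "SP")
  )
}
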