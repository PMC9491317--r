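# Core data objects: images, label maps, velocity and deformation fields.
#
# All objects are plain numeric arrays with a class attribute; grids are
# 0-based voxel coordinates, displacements are in voxel units, and the vector
# component axis is always the last array axis. Physical spacing (mm/voxel)
# is carried as an attribute and only matters for surface-distance metrics.

#' Create an image
#'
#' Wraps an n-dimensional (n = 2 or 3) numeric array of intensities as an
#' image with per-axis voxel spacing in millimetres.
#'
#' @param data Numeric array (2D or 3D) of finite intensities.
#' @param spacing Numeric vector of strictly positive mm-per-voxel values,
#'   one per axis (recycled from a scalar).
#' @return An object of class `hr_image`.
#' @export
as_image <- function(data, spacing = 1) {
  data <- as_grid_array(data)
  nd <- length(dim(data))
  if (!(nd %in% c(2L, 3L)))
    hr_stop("shape", "images must be 2D or 3D")
  if (!all(is.finite(data)))
    hr_stop("value", "image intensities must be finite")
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(spacing <= 0))
    hr_stop("value", "voxel spacing must be strictly positive")
  structure(data, spacing = spacing, class = "hr_image")
}

#' Create a label map
#'
#' Wraps an integer-valued array of segmentation labels on the same grid as
#' a paired image. Label 0 denotes background.
#'
#' @param data Array of non-negative integer labels.
#' @param spacing Voxel spacing, as in [as_image()].
#' @return An object of class `hr_labelmap` with attribute `label_set`, the
#'   sorted distinct nonzero labels present.
#' @export
as_labelmap <- function(data, spacing = 1) {
  data <- as_grid_array(data)
  nd <- length(dim(data))
  if (!(nd %in% c(2L, 3L)))
    hr_stop("shape", "label maps must be 2D or 3D")
  if (any(data < 0) || any(data != round(data)))
    hr_stop("value", "labels must be non-negative integers")
  spacing <- rep_len(as.numeric(spacing), nd)
  lab <- sort(unique(as.vector(data)))
  structure(data, spacing = spacing, label_set = lab[lab != 0],
            class = "hr_labelmap")
}

#' Create a stationary velocity field
#'
#' @param vectors Array with one spatial vector per voxel: dims `(H, W, 2)`
#'   in 2D or `(H, W, D, 3)` in 3D; components in voxel units, component axis
#'   last.
#' @return An object of class `hr_velocity`.
#' @export
as_velocity <- function(vectors) {
  vectors <- as_field_array(vectors, "velocity field")
  structure(vectors, class = "hr_velocity")
}

#' Create a deformation field
#'
#' Stores the displacement `u` of the map `phi(p) = p + u(p)`, one n-vector
#' per voxel in voxel units, component axis last.
#'
#' @param displacement Array with dims `(H, W, 2)` or `(H, W, D, 3)`.
#' @return An object of class `hr_deformation`.
#' @export
as_deformation <- function(displacement) {
  displacement <- as_field_array(displacement, "deformation field")
  structure(displacement, class = "hr_deformation")
}

as_grid_array <- function(data) {
  if (is.null(dim(data))) hr_stop("shape", "expected an array, not a vector")
  a <- array(as.numeric(data), dim = dim(data))
  a
}

as_field_array <- function(v, what) {
  if (is.null(dim(v)))
    hr_stop("shape", paste(what, "must be an array"))
  a <- array(as.numeric(v), dim = dim(v))
  nd <- length(dim(a))
  if (!(nd %in% c(3L, 4L)) || dim(a)[nd] != nd - 1L)
    hr_stop("shape",
            paste(what, "must have dims (H,W,2) or (H,W,D,3): last axis is",
                  "the vector component axis"))
  if (!all(is.finite(a)))
    hr_stop("value", paste(what, "components must be finite"))
  a
}

# spatial grid dims of any of the above
grid_dim <- function(x) {
  d <- dim(x)
  if (inherits(x, c("hr_velocity", "hr_deformation"))) d[-length(d)] else d
}

field_ndim <- function(x) length(grid_dim(x))

spacing_of <- function(x) {
  s <- attr(x, "spacing")
  if (is.null(s)) rep(1, field_ndim(x)) else s
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!identical(as.integer(grid_dim(a)), as.integer(grid_dim(b))))
    hr_stop("shape", paste(what, "must share the same grid"))
  invisible(TRUE)
}

#' @export
print.hr_image <- function(x, ...) {
  cat("<hr_image> ", paste(dim(x), collapse = "x"),
      " | spacing ", paste(attr(x, "spacing"), collapse = "x"), " mm",
      " | range [", signif(min(x), 4), ", ", signif(max(x), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.hr_labelmap <- function(x, ...) {
  cat("<hr_labelmap> ", paste(dim(x), collapse = "x"),
      " | labels {", paste(attr(x, "label_set"), collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' @export
print.hr_velocity <- function(x, ...) {
  d <- dim(x)
  cat("<hr_velocity> grid ", paste(d[-length(d)], collapse = "x"),
      " | max |v| ", signif(max(abs(x)), 4), " voxels\n", sep = "")
  invisible(x)
}

#' @export
print.hr_deformation <- function(x, ...) {
  d <- dim(x)
  cat("<hr_deformation> grid ", paste(d[-length(d)], collapse = "x"),
      " | max |u| ", signif(max(abs(x)), 4), " voxels\n", sep = "")
  invisible(x)
}
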