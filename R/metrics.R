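# Evaluation metrics: Dice overlap, 95th-percentile surface distance, and
# the standard deviation of the Jacobian determinant.

#' Per-label Dice overlap (percentage points)
#'
#' `100 * 2|A intersect B| / (|A| + |B|)` per label. Labels absent from both
#' maps are reported as `NA` (missing), not zero.
#'
#' @param a,b Label maps on a shared grid.
#' @param labels Labels to score (default: union of nonzero labels present).
#' @return Named numeric vector of Dice scores in `[0, 100]`.
#' @export
dice_score <- function(a, b, labels = NULL) {
  aa <- as_grid_array(a); bb <- as_grid_array(b)
  check_same_grid(aa, bb, "label maps")
  if (is.null(labels))
    labels <- sort(union(unique(as.vector(aa)), unique(as.vector(bb))))
  labels <- labels[labels != 0]
  out <- vapply(labels, function(l) {
    na <- sum(aa == l); nb <- sum(bb == l)
    if (na + nb == 0) return(NA_real_)
    100 * 2 * sum(aa == l & bb == l) / (na + nb)
  }, numeric(1))
  names(out) <- labels
  out
}

# boundary voxel coordinates (rows) of one label, face adjacency
label_boundary <- function(x, label) {
  dm <- dim(x)
  nd <- length(dm)
  inside <- x == label
  if (!any(inside)) return(NULL)
  shift_non <- function(axis, by) {
    # neighbour along axis; out-of-grid counts as non-label
    idx <- lapply(dm, seq_len)
    n <- dm[axis]
    src <- pmin(pmax(seq_len(n) + by, 1), n)
    idx[[axis]] <- src
    nb <- array(do.call(`[`, c(list(inside), idx)), dim = dm)
    edge <- lapply(dm, seq_len)
    out_of_grid <- if (by > 0) seq_len(n) + by > n else seq_len(n) + by < 1
    edge[[axis]] <- which(out_of_grid)
    if (length(edge[[axis]]))
      nb <- do.call(`[<-`, c(list(nb), edge, list(FALSE)))
    nb
  }
  has_bg_nb <- array(FALSE, dim = dm)
  for (ax in seq_len(nd)) {
    has_bg_nb <- has_bg_nb | !shift_non(ax, 1) | !shift_non(ax, -1)
  }
  which(inside & has_bg_nb, arr.ind = TRUE)
}

#' 95th-percentile symmetric surface distance (mm)
#'
#' Boundary voxels (face adjacency) of `label` are extracted in both maps;
#' the pooled set of nearest boundary-to-boundary distances in both
#' directions is summarized by its 95th percentile (linear-interpolation
#' quantile), scaled by the voxel spacing.
#'
#' @param a,b Label maps on a shared grid.
#' @param label Label present in both maps.
#' @param spacing mm per voxel per axis (default: spacing of `a`, or 1).
#' @return Distance in millimetres.
#' @export
surface_distance_95 <- function(a, b, label, spacing = NULL) {
  aa <- as_grid_array(a); bb <- as_grid_array(b)
  check_same_grid(aa, bb, "label maps")
  if (is.null(spacing)) spacing <- spacing_of(a)
  spacing <- rep_len(spacing, length(dim(aa)))
  pa <- label_boundary(aa, label)
  pb <- label_boundary(bb, label)
  if (is.null(pa) || is.null(pb))
    hr_stop("value", "label must be present in both maps")
  pa_mm <- sweep(pa, 2, spacing, `*`)
  pb_mm <- sweep(pb, 2, spacing, `*`)
  nn_dist <- function(from, to) {
    # nearest squared distance per 'from' row
    apply(from, 1, function(p) {
      sqrt(min(colSums((t(to) - p)^2)))
    })
  }
  d <- c(nn_dist(pa_mm, pb_mm), nn_dist(pb_mm, pa_mm))
  unname(quantile(d, 0.95))
}

#' Standard deviation of the Jacobian determinant
#'
#' Dispersion of local volume change of a deformation, computed over the
#' grid interior (boundary voxels of the replicated determinant field are
#' excluded).
#'
#' @param phi A deformation field.
#' @return Non-negative scalar.
#' @export
jacobian_sd <- function(phi) {
  det <- jacobian_determinant(phi)
  inner <- attr(det, "interior")
  sd(as.numeric(do.call(`[`, c(list(det), inner))))
}
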