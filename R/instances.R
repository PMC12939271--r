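#' Tooth instance: one connected pixel region with its moments
#'
#' Construct a tooth instance from pixel coordinates. Coordinates are
#' 0-based `(row, col)` pairs (origin top-left, row increasing downward).
#' Second-order central moments are computed as raw sums over pixel centers:
#' `mu20 = sum (r - rbar)^2`, `mu02 = sum (c - cbar)^2`,
#' `mu11 = sum (r - rbar)(c - cbar)` (pixel^2 units). With this assignment
#' the principal-axis orientation measured from the vertical image axis is
#' `theta = 0.5 * atan2(2 mu11, mu20 - mu02)`.
#'
#' @param coords Two-column matrix of 0-based `(row, col)` pixel coordinates.
#' @param class_index Tooth class index (1..32), or `NA` for anonymous masks.
#' @return A `tooth_instance`: list with `class_index`, `coords`, `centroid`,
#'   `mu20`, `mu02`, `mu11`, `n_pixels`.
#' @export
tooth_instance <- function(coords, class_index = NA_integer_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) < 1L) {
    stop("coords must be a non-empty (row, col) matrix")
  }
  ctr <- colMeans(coords)
  dr <- coords[, 1] - ctr[1]
  dc <- coords[, 2] - ctr[2]
  structure(list(
    class_index = class_index,
    coords = coords,
    centroid = ctr,
    mu20 = sum(dr * dr),
    mu02 = sum(dc * dc),
    mu11 = sum(dr * dc),
    n_pixels = nrow(coords)
  ), class = "tooth_instance")
}

#' @export
print.tooth_instance <- function(x, ...) {
  cat(sprintf("<tooth_instance class=%s> %d px, centroid (%.1f, %.1f)\n",
              x$class_index, x$n_pixels, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Instance from a binary mask
#'
#' @param mask Logical or 0/1 matrix.
#' @param class_index Optional class index.
#' @return A [tooth_instance()], or `NULL` for an empty mask.
#' @export
mask_instance <- function(mask, class_index = NA_integer_) {
  idx <- which(mask != 0)
  if (length(idx) == 0) return(NULL)
  nr <- nrow(mask)
  coords <- cbind(row = (idx - 1L) %% nr, col = (idx - 1L) %/% nr)
  tooth_instance(coords, class_index)
}

#' Extract tooth instances from a label map
#'
#' For each nonzero class present, pixels are grouped into 8-connected
#' components; the largest component is kept as the tooth instance and any
#' smaller fragments are dropped with a message. Instances smaller than
#' `min_pixels` are discarded entirely (at the 512 x 1024 working
#' resolution a real tooth is far larger than the default 50 px).
#'
#' @param map A [label_map()].
#' @param min_pixels Minimum retained component size (default 50).
#' @param classes Optional integer vector restricting extraction to these
#'   class indices (default: all classes present).
#' @return List of [tooth_instance()] objects, ordered by class index.
#' @export
extract_instances <- function(map, min_pixels = 50L, classes = NULL) {
  stopifnot(inherits(map, "label_map"))
  nr <- nrow(map)
  present <- sort(setdiff(unique(as.vector(map)), 0L))
  if (!is.null(classes)) present <- intersect(present, classes)
  out <- list()
  for (k in present) {
    idx <- which(map == k)
    comps <- connected_components(idx, nr, nrow(map) * ncol(map) / nr)
    sizes <- lengths(comps)
    if (length(comps) > 1L) {
      message(sprintf(
        "class %d: %d fragment(s) dropped (sizes %s), keeping largest (%d px)",
        k, length(comps) - 1L,
        paste(sort(sizes, decreasing = TRUE)[-1], collapse = ","),
        max(sizes)))
    }
    keep <- comps[[which.max(sizes)]]
    if (length(keep) < min_pixels) next
    coords <- cbind(row = (keep - 1L) %% nr, col = (keep - 1L) %/% nr)
    out[[length(out) + 1L]] <- tooth_instance(coords, class_index = k)
  }
  out
}

# 8-connected components of a set of linear (column-major, 1-based) indices.
# Adjacency is built vectorised by matching index offsets; component
# labelling is delegated to igraph.
connected_components <- function(idx, nr, nc) {
  n <- length(idx)
  if (n == 0) return(list())
  if (n == 1) return(list(idx))
  r <- (idx - 1L) %% nr
  c <- (idx - 1L) %/% nr
  # undirected: half of the 8-neighborhood suffices
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  ei <- integer(0); ej <- integer(0)
  for (o in offs) {
    nb <- idx + o[1] + o[2] * nr
    ok <- (r + o[1] >= 0L) & (r + o[1] < nr) & (c + o[2] >= 0L) & (c + o[2] < nc)
    m <- match(nb, idx)
    hit <- ok & !is.na(m)
    ei <- c(ei, which(hit))
    ej <- c(ej, m[hit])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ei) > 0) {
    g <- igraph::add_edges(g, rbind(ei, ej))
  }
  memb <- igraph::components(g)$membership
  split(idx, memb)
}

#' Principal-axis orientation of an instance
#'
#' Orientation of the major principal axis of the pixel region, measured
#' from the vertical image axis, computed from the second-order central
#' moments as `theta = 0.5 * atan2(2 mu11, mu20 - mu02)`. The result lies
#' in `(-pi/2, pi/2]`: 0 for a region elongated along image rows (a vertical
#' tooth), `pi/2` for a horizontal region, positive when the inferior
#' (bottom) end of the axis tilts toward increasing column index.
#'
#' Isotropic regions (`mu20 == mu02` and `mu11 == 0`, e.g. a square or
#' disk) have no defined major axis; 0 is returned with the `degenerate`
#' attribute set to `TRUE`.
#'
#' @param inst A [tooth_instance()] with at least 3 pixels.
#' @return Orientation in radians with a logical attribute `degenerate`.
#' @export
principal_orientation <- function(inst) {
  stopifnot(inherits(inst, "tooth_instance"))
  if (inst$n_pixels < 3L) stop("need at least 3 pixels for orientation")
  num <- 2 * inst$mu11
  den <- inst$mu20 - inst$mu02
  tot <- inst$mu20 + inst$mu02
  if (tot <= 0 || sqrt(num^2 + den^2) < 1e-12 * tot) {
    return(structure(0, degenerate = TRUE))
  }
  structure(0.5 * atan2(num, den), degenerate = FALSE)
}

#' Orientation-aware apical exclusion
#'
#' Removes the apical fraction of a tooth region along its own principal
#' axis before the long axis is re-estimated, suppressing the influence of
#' apical root curvature and dilacerations. Pixels are projected onto the
#' unit vector of the instance's principal axis with the sign fixed so the
#' positive direction points toward increasing row index (downward). The
#' apex of a maxillary tooth points toward the image top and therefore sits
#' at the minimum projection values; a mandibular apex sits at the maximum.
#' With projection extent `E = p_max - p_min`, maxillary teeth retain
#' pixels with `p >= p_min + fraction * E` and mandibular teeth retain
#' `p <= p_max - fraction * E`. Pixels exactly on the cutoff are retained,
#' so `fraction = 0` is the identity. Moments are recomputed on the
#' retained set.
#'
#' @param inst A [tooth_instance()].
#' @param arch `"maxillary"` or `"mandibular"` (selects the apical end).
#' @param fraction Fraction of the axial extent to exclude, in `[0, 0.5)`;
#'   default 0.22.
#' @return A trimmed [tooth_instance()] with recomputed moments.
#' @export
apical_exclude <- function(inst, arch = c("maxillary", "mandibular"),
                           fraction = 0.22) {
  stopifnot(inherits(inst, "tooth_instance"))
  arch <- match.arg(arch)
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 0.5) {
    stop("fraction must be in [0, 0.5)")
  }
  if (fraction == 0) return(inst)
  theta <- as.numeric(principal_orientation(inst))
  u <- c(cos(theta), sin(theta))  # row component >= 0: points downward
  p <- inst$coords[, 1] * u[1] + inst$coords[, 2] * u[2]
  pmin <- min(p); pmax <- max(p)
  keep <- if (arch == "maxillary") {
    p >= pmin + fraction * (pmax - pmin)
  } else {
    p <= pmax - fraction * (pmax - pmin)
  }
  if (!any(keep)) stop("apical exclusion removed all pixels")
  tooth_instance(inst$coords[keep, , drop = FALSE],
                 class_index = inst$class_index)
}

#' Measured angle of a (trimmed) instance in degrees
#'
#' Recomputes the principal orientation on the instance as given (normally
#' after [apical_exclude()]) and expresses it as the signed angular
#' deviation from the vertical image axis in degrees, in `(-90, 90]`.
#' Degenerate (isotropic) regions yield 0 with attribute `degenerate`.
#'
#' @param inst A [tooth_instance()] with at least 3 pixels.
#' @return Angle in degrees with logical attribute `degenerate`.
#' @export
measure_angle <- function(inst) {
  th <- principal_orientation(inst)
  structure(as.numeric(th) * 180 / pi, degenerate = attr(th, "degenerate"))
}
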