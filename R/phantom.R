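#' Specification of a single synthetic tooth
#'
#' A stylized tooth for the phantom generator: a rounded ("capsule") shaft
#' of given length and width whose long axis deviates from the vertical
#' image axis by `true_angle_deg` (the ground truth recovered by the
#' measurement pipeline). An optional apical hook models root dilaceration:
#' the apical `apical_hook_fraction` of the length is drawn as a second
#' segment deflected by `apical_hook_angle_deg`, joined continuously. The
#' apical end points toward the image top for maxillary FDI codes and
#' toward the bottom for mandibular codes; `crown_center` is the occlusal
#' end of the axis.
#'
#' @param fdi_code FDI tooth code (character or integer).
#' @param crown_center Numeric `(row, col)`, 0-based, occlusal end of the
#'   shaft axis.
#' @param shaft_length Axis length in pixels (>= 40).
#' @param shaft_width Shaft width in pixels.
#' @param true_angle_deg Ground-truth long-axis deviation from vertical, in
#'   degrees, `|angle| <= 45`; positive tilts the inferior end of the axis
#'   toward increasing column index.
#' @param apical_hook_angle_deg Extra deflection of the apical segment
#'   (0 = straight root).
#' @param apical_hook_fraction Portion of the length forming the hook,
#'   in `[0, 0.5)`.
#' @param present Logical; absent teeth rasterize to an empty mask.
#' @return One-row tibble (a tooth spec).
#' @export
tooth_spec <- function(fdi_code, crown_center, shaft_length, shaft_width,
                       true_angle_deg, apical_hook_angle_deg = 0,
                       apical_hook_fraction = 0.2, present = TRUE) {
  stopifnot(shaft_length >= 40, abs(true_angle_deg) <= 45,
            apical_hook_fraction >= 0, apical_hook_fraction < 0.5)
  tibble::tibble(
    fdi_code = as.character(fdi_code),
    crown_row = crown_center[1], crown_col = crown_center[2],
    shaft_length = shaft_length, shaft_width = shaft_width,
    true_angle_deg = true_angle_deg,
    apical_hook_angle_deg = apical_hook_angle_deg,
    apical_hook_fraction = apical_hook_fraction,
    present = present
  )
}

#' Phantom specification
#'
#' @param teeth Tibble of tooth specs ([tooth_spec()] rows, at most 32,
#'   distinct FDI codes).
#' @param image_shape `(rows, cols)`, default `c(512, 1024)`.
#' @param image_id Identifier for the generated map.
#' @param schema An [fdi_schema()].
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(teeth, image_shape = c(512L, 1024L),
                         image_id = "phantom", schema = fdi_schema()) {
  stopifnot(nrow(teeth) <= 32, !anyDuplicated(teeth$fdi_code))
  structure(list(teeth = teeth, image_shape = as.integer(image_shape),
                 image_id = as.character(image_id), schema = schema),
            class = "phantom_spec")
}

# centreline polyline of a tooth: crown end, (optional) hook joint, apex end.
# Returns a 2- or 3-row matrix of (row, col) points, 0-based.
tooth_polyline <- function(tooth, schema) {
  arch <- schema$arch[match(tooth$fdi_code, schema$fdi_code)]
  if (is.na(arch)) stop("unknown FDI code: ", tooth$fdi_code)
  th <- tooth$true_angle_deg * pi / 180
  u <- c(cos(th), sin(th))                 # down-pointing unit axis
  s <- if (arch == "maxillary") -1 else 1  # apical direction along rows
  crown <- c(tooth$crown_row, tooth$crown_col)
  hf <- tooth$apical_hook_fraction
  if (tooth$apical_hook_angle_deg == 0 || hf == 0) {
    apex <- crown + s * tooth$shaft_length * u
    return(rbind(crown, apex))
  }
  joint <- crown + s * (1 - hf) * tooth$shaft_length * u
  th2 <- (tooth$true_angle_deg + tooth$apical_hook_angle_deg) * pi / 180
  u2 <- c(cos(th2), sin(th2))
  apex <- joint + s * hf * tooth$shaft_length * u2
  rbind(crown, joint, apex)
}

#' Rasterize a single tooth to a binary mask
#'
#' Draws the tooth as a capsule (all pixels within `shaft_width / 2` of the
#' centreline polyline). Errors if any part of the capsule would fall
#' outside the image.
#'
#' @param tooth One-row tooth spec ([tooth_spec()]).
#' @param shape Image shape `(rows, cols)`.
#' @param schema An [fdi_schema()] (determines the apical direction).
#' @return Logical matrix of shape `shape`.
#' @export
rasterize_tooth <- function(tooth, shape = c(512L, 1024L),
                            schema = fdi_schema()) {
  mask <- matrix(FALSE, shape[1], shape[2])
  if (!tooth$present) return(mask)
  pts <- tooth_polyline(tooth, schema)
  rad <- tooth$shaft_width / 2
  if (min(pts[, 1]) - rad < 0 || max(pts[, 1]) + rad > shape[1] - 1 ||
      min(pts[, 2]) - rad < 0 || max(pts[, 2]) + rad > shape[2] - 1) {
    stop("tooth ", tooth$fdi_code, " geometry out of image bounds")
  }
  r0 <- max(0, floor(min(pts[, 1]) - rad - 1))
  r1 <- min(shape[1] - 1, ceiling(max(pts[, 1]) + rad + 1))
  c0 <- max(0, floor(min(pts[, 2]) - rad - 1))
  c1 <- min(shape[2] - 1, ceiling(max(pts[, 2]) + rad + 1))
  rr <- r0:r1; cc <- c0:c1
  gr <- matrix(rr, length(rr), length(cc))
  gc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  dmin <- matrix(Inf, length(rr), length(cc))
  for (i in seq_len(nrow(pts) - 1)) {
    dmin <- pmin(dmin, dist_to_segment(gr, gc, pts[i, ], pts[i + 1, ]))
  }
  mask[rr + 1, cc + 1] <- dmin <= rad
  mask
}

# distance from grid points to segment p-q (all in (row, col) coords)
dist_to_segment <- function(gr, gc, p, q) {
  v <- q - p
  len2 <- sum(v * v)
  t <- ((gr - p[1]) * v[1] + (gc - p[2]) * v[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((gr - (p[1] + t * v[1]))^2 + (gc - (p[2] + t * v[2]))^2)
}

#' Generate a phantom label map with ground truth
#'
#' Rasterizes every present tooth of the spec into a 33-class label map and
#' emits the ground-truth table. Teeth must occupy disjoint pixel sets;
#' overlap is an error (the built-in [default_dentition()] layouts are
#' constructed to be disjoint). Deterministic: the spec fully determines
#' the output.
#'
#' @param spec A [phantom_spec()].
#' @return List with `map` (a [label_map()]) and `truth` (tibble
#'   `image_id`, `fdi_code`, `true_angle_deg`, `n_pixels`).
#' @examples
#' ph <- generate_phantom(default_dentition(seed = 1))
#' length(setdiff(unique(as.vector(ph$map)), 0))  # 32 tooth classes
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$image_shape
  px <- matrix(0L, shape[1], shape[2])
  truth <- list()
  for (i in seq_len(nrow(spec$teeth))) {
    tooth <- spec$teeth[i, ]
    if (!tooth$present) next
    mask <- rasterize_tooth(tooth, shape, spec$schema)
    idx <- which(mask)
    if (any(px[idx] != 0L)) {
      clash <- unique(px[idx][px[idx] != 0L])
      stop("overlapping teeth: ", tooth$fdi_code, " intersects class ",
           paste(clash, collapse = ","))
    }
    k <- fdi_class_index(tooth$fdi_code, spec$schema)
    px[idx] <- k
    truth[[length(truth) + 1L]] <- tibble::tibble(
      image_id = spec$image_id, fdi_code = tooth$fdi_code,
      true_angle_deg = tooth$true_angle_deg, n_pixels = length(idx))
  }
  truth <- if (length(truth) == 0) {
    tibble::tibble(image_id = character(), fdi_code = character(),
                   true_angle_deg = double(), n_pixels = integer())
  } else {
    dplyr::bind_rows(truth)
  }
  truth <- truth[order(truth$fdi_code), ]
  list(map = label_map(px, schema = spec$schema, image_id = spec$image_id),
       truth = truth)
}

# Arch layout constants for the default dentition. Sixteen tooth positions
# per arch across the 1024-px width; occlusal rows follow a shallow arch
# curve; lengths/widths/base tilts vary by tooth type. No anatomical atlas
# is reproduced here -- the values are plausible stylized defaults and can
# be edited via the returned spec.
arch_layout <- function(schema) {
  upper <- c("18", "17", "16", "15", "14", "13", "12", "11",
             "21", "22", "23", "24", "25", "26", "27", "28")
  lower <- c("48", "47", "46", "45", "44", "43", "42", "41",
             "31", "32", "33", "34", "35", "36", "37", "38")
  # per position digit 1..8: length, width, base tilt magnitude (deg)
  len <- c(104, 104, 112, 100, 100, 95, 95, 90)
  wid <- c(16, 16, 18, 20, 20, 24, 24, 22)
  base <- c(2, 3, 7, 4, 3, 2, 3, 5)
  build <- function(codes, arch) {
    j <- seq_along(codes)
    col <- 512 + (j - 8.5) * 63
    t <- (col - 512) / 472.5
    row <- if (arch == "maxillary") 238 - 22 * t^2 else 274 + 22 * t^2
    pos <- as.integer(substr(codes, 2, 2))
    mesial <- ifelse(col < 512, 1, -1)  # apex tipped away from the midline
    sgn <- if (arch == "maxillary") mesial else -mesial
    tibble::tibble(fdi_code = codes, crown_row = row, crown_col = col,
                   shaft_length = len[pos], shaft_width = wid[pos],
                   base_angle_deg = sgn * base[pos])
  }
  rbind(build(upper, "maxillary"), build(lower, "mandibular"))
}

#' Default full-dentition phantom specification
#'
#' Arranges all 32 permanent teeth on two arch curves with anatomically
#' plausible base angulations. Each tooth's ground-truth angle is its base
#' angle plus Gaussian noise (truncated at 2.5 SD to keep tilts plausible
#' and interproximal spaces open); apical hooks are assigned with
#' probability `hook_prob`, with deflection magnitude uniform in 10--30
#' degrees and random direction over the apical 20% of the length. A
#' tooth whose drawn tilt/hook would violate a conservative clearance bound
#' against its already-placed neighbor is redrawn from the same RNG stream
#' (bounded retries), so default specs always satisfy the disjointness
#' precondition of [generate_phantom()]. Deterministic given `seed`.
#'
#' @param seed Integer seed for the angle and hook draws.
#' @param angle_noise_sd SD of the per-tooth angular noise, degrees
#'   (default 3).
#' @param hook_prob Probability that a tooth has an apical hook
#'   (default 0.15).
#' @param missing Character vector of FDI codes to mark absent.
#' @param image_id Identifier; default derived from the seed.
#' @param schema An [fdi_schema()].
#' @return A [phantom_spec()].
#' @export
default_dentition <- function(seed, angle_noise_sd = 3, hook_prob = 0.15,
                              missing = character(0),
                              image_id = sprintf("phantom_%06d", seed),
                              schema = fdi_schema()) {
  stopifnot(angle_noise_sd >= 0, hook_prob >= 0, hook_prob <= 1)
  layout <- arch_layout(schema)
  teeth <- withr::with_seed(seed, {
    rows <- vector("list", nrow(layout))
    prev <- NULL
    for (i in seq_len(nrow(layout))) {
      l <- layout[i, ]
      for (try in 1:25) {
        noise <- stats::rnorm(1, 0, angle_noise_sd)
        lim <- 2.5 * angle_noise_sd
        noise <- min(max(noise, -lim), lim)
        hook <- 0
        if (stats::runif(1) < hook_prob) {
          hook <- sample(c(-1, 1), 1) * stats::runif(1, 10, 30)
        }
        cand <- tooth_spec(
          l$fdi_code, c(l$crown_row, l$crown_col), l$shaft_length,
          l$shaft_width, l$base_angle_deg + noise,
          apical_hook_angle_deg = hook,
          present = !(l$fdi_code %in% missing))
        # clearance only against the mesial neighbor in the same arch
        # (row 8/9 and 16/17 boundaries start a new run of neighbors)
        same_arch <- !is.null(prev) && i %% 16 != 1
        if (!same_arch || !cand$present || !prev$present ||
            polyline_clearance(cand, prev, schema) > 2) {
          break
        }
      }
      rows[[i]] <- cand
      prev <- cand
    }
    dplyr::bind_rows(rows)
  })
  phantom_spec(teeth, image_id = image_id, schema = schema)
}

# minimum gap between the capsule surfaces of two teeth, from sampled
# centreline points (conservative screen used by default_dentition)
polyline_clearance <- function(ta, tb, schema) {
  sample_pts <- function(tooth) {
    pts <- tooth_polyline(tooth, schema)
    out <- list()
    for (i in seq_len(nrow(pts) - 1)) {
      t <- seq(0, 1, length.out = 12)
      out[[i]] <- cbind(pts[i, 1] + t * (pts[i + 1, 1] - pts[i, 1]),
                        pts[i, 2] + t * (pts[i + 1, 2] - pts[i, 2]))
    }
    do.call(rbind, out)
  }
  pa <- sample_pts(ta); pb <- sample_pts(tb)
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  sqrt(min(d2)) - (ta$shaft_width + tb$shaft_width) / 2
}

#' Simulate acquisition-geometry perturbation
#'
#' Applies an in-plane rotation about the image center and an optional
#' horizontal shear to a label map (nearest-neighbor resampling, preserving
#' label integrity), emulating repeat acquisitions with different head
#' positioning and projection geometry. Ground-truth angles are updated
#' analytically: rotation adds `rotation_deg` to every vertical-axis angle;
#' shear maps an axis vector `(u_r, u_c)` to `(u_r, u_c + shear * u_r)`.
#' An optional random integer translation of up to `jitter_px` pixels
#' (drawn from `seed`) emulates positioning offsets and leaves angles
#' unchanged. A tooth losing more than half its pixels to the frame edge
#' is dropped from the truth table with a warning.
#'
#' @param map A [label_map()].
#' @param truth Matching ground-truth tibble (from [generate_phantom()]).
#' @param rotation_deg In-plane rotation in degrees, `|rotation| <= 10`.
#' @param shear Horizontal shear coefficient (column shift per row),
#'   default 0.
#' @param jitter_px Maximum absolute random translation per axis, default 0.
#' @param seed Seed for the translation jitter.
#' @return List with perturbed `map` and updated `truth`.
#' @export
perturb_acquisition <- function(map, truth, rotation_deg, shear = 0,
                                jitter_px = 0, seed = 1) {
  stopifnot(inherits(map, "label_map"), abs(rotation_deg) <= 10)
  nr <- nrow(map); nc <- ncol(map)
  shift <- c(0L, 0L)
  if (jitter_px > 0) {
    shift <- withr::with_seed(seed,
      sample(seq(-jitter_px, jitter_px), 2, replace = TRUE))
  }
  px <- unclass_matrix(map)
  if (rotation_deg != 0 || shear != 0 || any(shift != 0)) {
    ctr <- c((nr - 1) / 2, (nc - 1) / 2)
    th <- rotation_deg * pi / 180
    g <- expand.grid(r = 0:(nr - 1), c = 0:(nc - 1))
    # inverse map: undo translation, then shear, then rotation
    r1 <- g$r - shift[1]
    c1 <- g$c - shift[2]
    c1 <- c1 - shear * (r1 - ctr[1])
    dr <- r1 - ctr[1]; dc <- c1 - ctr[2]
    rs <- round(cos(th) * dr + sin(th) * dc + ctr[1])
    cs <- round(-sin(th) * dr + cos(th) * dc + ctr[2])
    ok <- rs >= 0 & rs < nr & cs >= 0 & cs < nc
    out <- integer(nr * nc)
    out[ok] <- px[cbind(rs[ok] + 1L, cs[ok] + 1L)]
    px <- matrix(out, nr, nc)
  }
  new_map <- label_map(px, schema = attr(map, "schema"),
                       image_id = attr(map, "image_id"))
  # update truth
  th0 <- truth$true_angle_deg * pi / 180
  ur <- cos(th0); uc <- sin(th0)
  rot <- rotation_deg * pi / 180
  ur1 <- cos(rot) * ur - sin(rot) * uc
  uc1 <- sin(rot) * ur + cos(rot) * uc
  uc1 <- uc1 + shear * ur1
  ang <- atan2(uc1, ur1) * 180 / pi
  ang <- ifelse(ang <= -90, ang + 180, ifelse(ang > 90, ang - 180, ang))
  truth$true_angle_deg <- ang
  counts <- tabulate(px, nbins = 32L)
  k <- fdi_class_index(truth$fdi_code, attr(map, "schema"))
  kept <- counts[k] >= 0.5 * truth$n_pixels
  if (any(!kept)) {
    warning("dropped from truth (pushed out of frame): ",
            paste(truth$fdi_code[!kept], collapse = ", "))
  }
  truth$n_pixels <- counts[k]
  list(map = new_map, truth = truth[kept, , drop = FALSE])
}

#' Write a phantom to disk
#'
#' Writes the label map (PNG), the ground-truth CSV and the tooth spec
#' (JSON) side by side for reproducibility.
#'
#' @param phantom List with `map` and `truth` (from [generate_phantom()]).
#' @param dir Output directory (created if needed).
#' @param spec Optional [phantom_spec()] to serialize alongside.
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- attr(phantom$map, "image_id")
  p_png <- file.path(dir, paste0(id, ".png"))
  p_csv <- file.path(dir, paste0(id, "_truth.csv"))
  write_labelmap(phantom$map, p_png)
  readr::write_csv(phantom$truth, p_csv)
  paths <- c(p_png, p_csv)
  if (!is.null(spec)) {
    p_json <- file.path(dir, paste0(id, "_spec.json"))
    jsonlite::write_json(list(image_shape = spec$image_shape,
                              image_id = spec$image_id,
                              teeth = spec$teeth),
                         p_json, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p_json)
  }
  invisible(paths)
}
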