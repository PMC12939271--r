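#' Default posterior tooth selection
#'
#' The tooth types measured by default: canines, first and second premolars,
#' and first and second molars, in both arches (at most 20 teeth per image).
#' Incisors and third molars are not measured by default.
#'
#' @return Character vector of tooth type names.
#' @export
default_tooth_selection <- function() {
  c("canine", "first premolar", "second premolar", "first molar",
    "second molar")
}

#' Measure root angulations for every selected tooth in a label map
#'
#' Runs the full per-image pipeline: instance extraction
#' ([extract_instances()]), initial principal-axis estimation, apical
#' exclusion with the arch-dependent direction ([apical_exclude()]), and
#' re-estimation of the long-axis angle on the trimmed region
#' ([measure_angle()]). Teeth absent from the map produce no record;
#' per-tooth failures (pathological geometry) produce a flagged record with
#' `NA` angle rather than aborting the batch.
#'
#' @param map A [label_map()].
#' @param schema An [fdi_schema()]; defaults to the map's own schema.
#' @param selection Tooth types to measure; default
#'   [default_tooth_selection()].
#' @param fraction Apical exclusion fraction, default 0.22.
#' @param min_pixels Minimum instance size, default 50.
#' @return A tibble with one row per measured tooth, sorted by FDI code:
#'   `image_id`, `fdi_code`, `arch`, `side`, `tooth_type`, `angle_deg`
#'   (signed, vertical-axis convention), `angle_abs_deg`,
#'   `angle_vs_border_deg`, `n_pixels_total`, `n_pixels_retained`,
#'   `degenerate_flag`, `apical_fraction`.
#' @examples
#' ph <- generate_phantom(default_dentition(seed = 1))
#' rec <- measure_image(ph$map)
#' nrow(rec)  # 20: five posterior types in four quadrants
#' @export
measure_image <- function(map, schema = NULL,
                          selection = default_tooth_selection(),
                          fraction = 0.22, min_pixels = 50L) {
  stopifnot(inherits(map, "label_map"))
  if (is.null(schema)) schema <- attr(map, "schema")
  image_id <- attr(map, "image_id")
  sel_classes <- schema$class_index[schema$tooth_type %in% selection]
  insts <- extract_instances(map, min_pixels = min_pixels,
                             classes = sel_classes)
  rows <- lapply(insts, function(inst) {
    info <- fdi_lookup(inst$class_index, schema)
    rec <- tryCatch({
      trimmed <- apical_exclude(inst, arch = info$arch, fraction = fraction)
      ang <- measure_angle(trimmed)
      list(angle = as.numeric(ang), degenerate = isTRUE(attr(ang, "degenerate")),
           retained = trimmed$n_pixels)
    }, error = function(e) {
      list(angle = NA_real_, degenerate = TRUE, retained = 0L)
    })
    tibble::tibble(
      image_id = image_id,
      fdi_code = info$fdi_code,
      arch = info$arch,
      side = info$side,
      tooth_type = info$tooth_type,
      angle_deg = rec$angle,
      angle_abs_deg = abs(rec$angle),
      angle_vs_border_deg = angle_vs_reference_border(rec$angle, info$arch),
      n_pixels_total = inst$n_pixels,
      n_pixels_retained = rec$retained,
      degenerate_flag = rec$degenerate,
      apical_fraction = fraction
    )
  })
  out <- if (length(rows) == 0) empty_records() else dplyr::bind_rows(rows)
  out[order(out$fdi_code), ]
}

empty_records <- function() {
  tibble::tibble(
    image_id = character(), fdi_code = character(), arch = character(),
    side = character(), tooth_type = character(), angle_deg = double(),
    angle_abs_deg = double(), angle_vs_border_deg = double(),
    n_pixels_total = integer(), n_pixels_retained = integer(),
    degenerate_flag = logical(), apical_fraction = double()
  )
}

#' Re-express a vertical-axis angle relative to the horizontal film border
#'
#' Clinically the long axis is referenced to the fixed horizontal borders of
#' the film: the upper border for maxillary teeth and the lower border for
#' mandibular teeth. Both borders are horizontal and parallel to the image
#' x-axis, so the angle to either border is the complement of the
#' vertical-axis angle: `90 - |angle_deg|`. The sign (mesial vs distal tilt)
#' is carried separately by `angle_deg`; a perfectly vertical tooth is at
#' 90 degrees to the border.
#'
#' @param angle_deg Signed vertical-axis angle(s) in `(-90, 90]`.
#' @param arch `"maxillary"` or `"mandibular"`; selects which border is the
#'   reference line, which does not change the numeric value (documented
#'   equivalence).
#' @return Angle(s) to the horizontal reference border, in degrees.
#' @export
angle_vs_reference_border <- function(angle_deg,
                                      arch = c("maxillary", "mandibular")) {
  arch <- match.arg(arch)
  if (any(!is.na(angle_deg) & (angle_deg <= -90 | angle_deg > 90))) {
    stop("angle_deg must lie in (-90, 90]")
  }
  90 - abs(angle_deg)
}

# ---- record CSV I/O ---------------------------------------------------------

canonical_record_cols <- c("image_id", "fdi_code", "angle_deg",
                           "angle_abs_deg", "angle_vs_border_deg",
                           "n_pixels_total", "n_pixels_retained",
                           "degenerate_flag")

#' Read and write angulation record CSVs
#'
#' The on-disk format is a CSV with header `image_id, fdi_code, angle_deg,
#' angle_abs_deg, angle_vs_border_deg, n_pixels_total, n_pixels_retained,
#' degenerate_flag`. On read, anatomical descriptors (`arch`, `side`,
#' `tooth_type`) are re-derived from the FDI code.
#'
#' @param records Tibble of measurement records (from [measure_image()]).
#' @param path CSV path.
#' @param schema An [fdi_schema()] used to re-derive descriptors on read.
#' @return `write_angulation_csv` returns `path` invisibly;
#'   `read_angulation_csv` returns a tibble of records.
#' @export
write_angulation_csv <- function(records, path) {
  readr::write_csv(records[, canonical_record_cols], path)
  invisible(path)
}

#' @rdname write_angulation_csv
#' @export
read_angulation_csv <- function(path, schema = fdi_schema()) {
  rec <- readr::read_csv(path, col_types = readr::cols(
    image_id = readr::col_character(),
    fdi_code = readr::col_character(),
    angle_deg = readr::col_double(),
    angle_abs_deg = readr::col_double(),
    angle_vs_border_deg = readr::col_double(),
    n_pixels_total = readr::col_integer(),
    n_pixels_retained = readr::col_integer(),
    degenerate_flag = readr::col_logical()
  ))
  i <- match(rec$fdi_code, schema$fdi_code)
  if (anyNA(i)) stop("unknown FDI code in ", path)
  rec$arch <- schema$arch[i]
  rec$side <- schema$side[i]
  rec$tooth_type <- schema$tooth_type[i]
  rec
}
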