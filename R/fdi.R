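#' FDI permanent-tooth class schema
#'
#' Builds the schema mapping segmentation class indices 1--32 to FDI
#' two-digit tooth codes, together with the anatomical descriptors derived
#' from the code: arch (maxillary/mandibular), side (patient right/left) and
#' tooth type. Class 0 is always background, giving 33 classes in total.
#'
#' The class-index-to-FDI assignment is not universal across segmentation
#' models, so it is shipped as a plain-text config table
#' (`inst/extdata/fdi_schema.tsv`, columns `class_index` and `fdi_code`) and
#' any consistent bijection onto the 32 permanent-tooth codes may be
#' substituted via `path`.
#'
#' FDI quadrants: 1 = upper right, 2 = upper left, 3 = lower left,
#' 4 = lower right ("right"/"left" are the patient's sides). The position
#' digit 1--8 runs from central incisor to third molar.
#'
#' @param path Optional path to an alternative tab-separated mapping table
#'   with columns `class_index` (1--32) and `fdi_code` (valid FDI codes).
#' @return A tibble of class `fdi_schema` with columns `class_index`,
#'   `fdi_code` (character), `arch`, `side`, `tooth_type`.
#' @examples
#' sch <- fdi_schema()
#' nrow(sch)            # 32 teeth
#' n_classes(sch)       # 33 including background
#' @export
fdi_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fdi_schema.tsv", package = "rootangle",
                        mustWork = TRUE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("integer", "character"))
  if (!identical(names(tab), c("class_index", "fdi_code"))) {
    stop("schema table must have columns 'class_index' and 'fdi_code'")
  }
  if (nrow(tab) != 32L || anyDuplicated(tab$class_index) ||
      anyDuplicated(tab$fdi_code)) {
    stop("schema must map 32 distinct class indices to 32 distinct FDI codes")
  }
  if (!setequal(tab$class_index, 1:32)) {
    stop("class indices must be exactly 1..32")
  }
  valid <- as.character(c(11:18, 21:28, 31:38, 41:48))
  if (!setequal(tab$fdi_code, valid)) {
    stop("FDI codes must be exactly 11-18, 21-28, 31-38, 41-48")
  }
  quadrant <- as.integer(substr(tab$fdi_code, 1, 1))
  position <- as.integer(substr(tab$fdi_code, 2, 2))
  out <- tibble::tibble(
    class_index = tab$class_index,
    fdi_code = tab$fdi_code,
    arch = ifelse(quadrant %in% c(1L, 2L), "maxillary", "mandibular"),
    side = ifelse(quadrant %in% c(1L, 4L), "right", "left"),
    tooth_type = tooth_type_names()[position]
  )
  out <- out[order(out$class_index), ]
  class(out) <- c("fdi_schema", class(out))
  out
}

#' Tooth type names by FDI position digit
#'
#' @return Character vector of length 8, indexed by the FDI position digit.
#' @export
tooth_type_names <- function() {
  c("central incisor", "lateral incisor", "canine", "first premolar",
    "second premolar", "first molar", "second molar", "third molar")
}

#' Number of segmentation classes (teeth + background)
#'
#' @param schema An `fdi_schema`.
#' @return Integer: number of tooth classes plus one background class.
#' @export
n_classes <- function(schema = fdi_schema()) {
  nrow(schema) + 1L
}

#' Look up a tooth class
#'
#' Returns the FDI descriptor for a segmentation class index. Class 0
#' (background) is not a tooth and raises an error.
#'
#' @param class_index Integer in 1..32.
#' @param schema An `fdi_schema`.
#' @return A list with elements `fdi_code`, `arch`, `side`, `tooth_type`.
#' @examples
#' sch <- fdi_schema()
#' fdi_lookup(fdi_class_index("16", sch), sch)$tooth_type  # "first molar"
#' @export
fdi_lookup <- function(class_index, schema = fdi_schema()) {
  if (length(class_index) != 1L || is.na(class_index) ||
      class_index != as.integer(class_index)) {
    stop("class_index must be a single integer")
  }
  if (class_index < 1 || class_index > nrow(schema)) {
    stop("class_index out of range: background (0) and values > ",
         nrow(schema), " are not teeth")
  }
  row <- schema[schema$class_index == class_index, ]
  list(fdi_code = row$fdi_code, arch = row$arch, side = row$side,
       tooth_type = row$tooth_type)
}

#' Class index for an FDI code
#'
#' @param fdi_code FDI tooth code (character or integer, e.g. "36").
#' @param schema An `fdi_schema`.
#' @return Integer class index in 1..32.
#' @export
fdi_class_index <- function(fdi_code, schema = fdi_schema()) {
  fdi_code <- as.character(fdi_code)
  i <- match(fdi_code, schema$fdi_code)
  if (anyNA(i)) stop("unknown FDI code: ", fdi_code[is.na(i)][1])
  schema$class_index[i]
}
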