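# Pattern vocabulary for lung adenocarcinoma (LUAD) growth patterns.

#' Canonical pattern names in fixture code order
#' @keywords internal
.PATTERNS <- c("lepidic", "acinar", "papillary", "micropapillary",
               "solid", "complex_glandular")

#' Build the six-pattern codebook
#'
#' The codebook fixes the integer code, three-tier grade, four-tier grade and
#' severity rank of each of the six LUAD growth patterns. Grade tiers follow
#' the dominant-pattern grading conventions: tier 3 is the WHO mapping
#' (G1 lepidic; G2 acinar, papillary; G3 micropapillary, solid, complex
#' glandular); tier 4 places complex glandular as an intermediate G3 between
#' the low-risk (G2) and high-risk (G4) patterns. The severity rank is a
#' total order used for tie-breaking, from least to most aggressive:
#' lepidic < acinar < papillary < complex_glandular < micropapillary < solid.
#'
#' @param codes integer codes for the six patterns, in the order
#'   lepidic, acinar, papillary, micropapillary, solid, complex_glandular.
#' @param background_code integer code of non-tumor / unannotated pixels.
#' @return an object of class `pattern_codebook`: a data.frame with columns
#'   `code`, `name`, `tier3`, `tier4`, `severity_rank`, plus attribute
#'   `background_code`.
#' @export
#' @examples
#' cb <- pattern_codebook()
#' cb$tier3[cb$name == "complex_glandular"]  # 3
pattern_codebook <- function(codes = 1:6, background_code = 0L) {
  codes <- as.integer(codes)
  background_code <- as.integer(background_code)
  if (length(codes) != 6L || anyDuplicated(codes))
    stop("exactly 6 unique pattern codes required")
  if (background_code %in% codes)
    stop("background_code must differ from all pattern codes")
  cb <- data.frame(
    code = codes,
    name = .PATTERNS,
    tier3 = c(1L, 2L, 2L, 3L, 3L, 3L),
    tier4 = c(1L, 2L, 2L, 4L, 4L, 3L),
    severity_rank = c(1L, 2L, 3L, 5L, 6L, 4L),
    stringsAsFactors = FALSE
  )
  attr(cb, "background_code") <- background_code
  class(cb) <- c("pattern_codebook", "data.frame")
  cb
}

#' Severity order of the six patterns
#'
#' @param codebook a [pattern_codebook()].
#' @return character vector of pattern names from least to most severe.
#' @export
severity_order <- function(codebook = pattern_codebook()) {
  codebook$name[order(codebook$severity_rank)]
}

#' Pattern-area correction weights
#'
#' Dimensionless multipliers on pixel area compensating for the different
#' epithelial tumor-cell density of the patterns: in the same region the
#' epithelial component is more abundant in higher-grade patterns than in
#' lepidic growth, so raw pixel counts under-represent low-grade patterns.
#' Defaults are the weights derived from the training-data pattern area
#' distribution.
#'
#' @param lepidic,acinar,papillary,micropapillary,solid,complex_glandular
#'   positive multipliers per pattern.
#' @return named numeric vector over the six patterns.
#' @export
#' @examples
#' correction_weights()          # the calibrated defaults
#' correction_weights(1, 1, 1, 1, 1, 1)  # raw-percent mode
correction_weights <- function(lepidic = 1.41, acinar = 1.35,
                               papillary = 1.06, micropapillary = 1.14,
                               solid = 1.0, complex_glandular = 1.10) {
  w <- c(lepidic = lepidic, acinar = acinar, papillary = papillary,
         micropapillary = micropapillary, solid = solid,
         complex_glandular = complex_glandular)
  if (any(!is.finite(w)) || any(w <= 0)) stop("all weights must be positive")
  w
}

#' Unit weights (disable area correction)
#' @return named numeric vector of 1s over the six patterns.
#' @export
unit_weights <- function() correction_weights(1, 1, 1, 1, 1, 1)

# canonical spelling for pattern labels ("Micro-papillary" etc.)
.normalize_pattern <- function(x) {
  x <- gsub("[ -]", "_", tolower(trimws(x)))
  x[x == "micro_papillary"] <- "micropapillary"
  x
}

#' Read a codebook from a two-column config file
#'
#' Accepts a CSV with columns `code` and `name`; names must be the six
#' canonical pattern names plus optionally `background`.
#'
#' @param path file path.
#' @return a [pattern_codebook()].
#' @export
read_codebook <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "name") %in% names(df)))
    stop("codebook file needs columns 'code' and 'name'")
  df$name <- .normalize_pattern(df$name)
  bg <- df$code[df$name %in% c("background", "bg", "none")]
  pat <- df[df$name %in% .PATTERNS, , drop = FALSE]
  if (nrow(pat) != 6L)
    stop("codebook file must define all six patterns; found: ",
         paste(pat$name, collapse = ", "))
  codes <- pat$code[match(.PATTERNS, pat$name)]
  pattern_codebook(codes, if (length(bg)) bg[1] else 0L)
}
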