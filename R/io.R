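# Readers/writers for masks and tables, plus machine-readable reports.
# Percentage tables are accepted in [0, 100] with a renormalization
# tolerance of 1 point; masks are (row, column) rasters, origin top-left,
# 0-based pattern codes per the codebook.

#' Read a single-channel 8-bit label mask (PNG or TIFF)
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param slide_id slide identifier (default: file name without extension).
#' @param mpp microns per pixel, or NULL.
#' @return a [label_mask()].
#' @export
read_mask <- function(path, slide_id = NULL, mpp = NULL) {
  if (is.null(slide_id)) slide_id <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    raster <- round(img * 255)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    raster <- img
  } else stop("unsupported mask format: .", ext)
  label_mask(raster, slide_id, mpp)
}

#' Write a label mask as 8-bit PNG or TIFF
#'
#' @param mask a [label_mask()] (codes must fit 0..255).
#' @param path output path (.png/.tif/.tiff).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  r <- mask$raster
  if (any(r < 0 | r > 255)) stop("codes must fit an 8-bit image")
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") png::writePNG(r / 255, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(r / 255, path, bits.per.sample = 8L)
  else stop("unsupported mask format: .", ext)
  invisible(path)
}

#' Read a pattern composition table into case compositions
#'
#' Long-format CSV with columns `case_id`, `pattern` and either `pixels`
#' (raw pixel counts; the correction weights are applied) or `pct`
#' (already-formed percentages; renormalized when their case sum is within
#' 1 point of 100, rejected otherwise). An optional `slide_id` column
#' triggers per-slide weighting before case-level pooling. Row-level
#' problems (unknown patterns, malformed numbers, duplicate keys) are
#' collected and reported with row numbers; the read aborts unless
#' `skip_bad = TRUE`.
#'
#' @param path CSV path.
#' @param codebook a [pattern_codebook()].
#' @param weights [correction_weights()] applied to `pixels` input.
#' @param min_secondary_pct see [dominant_secondary()].
#' @param skip_bad drop offending rows instead of aborting.
#' @return named list of `case_composition` objects.
#' @export
read_composition_table <- function(path, codebook = pattern_codebook(),
                                   weights = correction_weights(),
                                   min_secondary_pct = 5,
                                   skip_bad = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("case_id", "pattern") %in% names(df)))
    stop("composition table needs columns case_id, pattern")
  value_col <- intersect(c("pixels", "pct"), names(df))[1]
  if (is.na(value_col))
    stop("composition table needs a 'pixels' or 'pct' column")
  df$pattern <- .normalize_pattern(df$pattern)
  if (!"slide_id" %in% names(df)) df$slide_id <- df$case_id
  problems <- character(0)
  bad <- !df$pattern %in% .PATTERNS
  if (any(bad))
    problems <- c(problems, paste0("row ", which(bad), ": unknown pattern '",
                                   df$pattern[bad], "'"))
  vals <- suppressWarnings(as.numeric(df[[value_col]]))
  nn <- is.na(vals)
  if (any(nn))
    problems <- c(problems,
                  paste0("row ", which(nn), ": malformed ", value_col))
  key <- paste(df$case_id, df$slide_id, df$pattern)
  dup <- duplicated(key)
  if (any(dup))
    problems <- c(problems, paste0("row ", which(dup),
                                   ": duplicate (case, slide, pattern) key"))
  if (length(problems)) {
    if (!skip_bad)
      stop("composition table has ", length(problems), " bad row(s):\n",
           paste(utils::head(problems, 10), collapse = "\n"))
    keep <- !(bad | nn | dup)
    df <- df[keep, , drop = FALSE]
    vals <- vals[keep]
    warning("dropped ", sum(!keep), " bad row(s)")
  }
  df$value <- vals
  out <- lapply(split(df, df$case_id), function(cd) {
    if (value_col == "pixels") {
      slides <- lapply(split(cd, cd$slide_id), function(sd) {
        counts <- stats::setNames(rep(0, 6L), .PATTERNS)
        counts[sd$pattern] <- sd$value
        w <- weights[.PATTERNS]
        weighted <- counts * w
        tot <- sum(weighted)
        structure(list(slide_id = sd$slide_id[1], raw_pixels = counts,
                       weighted_area = weighted,
                       pct = if (tot > 0) 100 * weighted / tot else
                         weighted,
                       background_pixels = NA_integer_, unit = "wpx",
                       mpp = NULL, empty = tot == 0),
                  class = "slide_composition")
      })
      aggregate_case(slides, cd$case_id[1], min_secondary_pct, codebook)
    } else {
      pct <- tapply(cd$value, cd$pattern, sum)
      case_from_pct(pct[!is.na(pct)], cd$case_id[1],
                    min_secondary_pct, codebook, tol = 1)
    }
  })
  out[order(names(out))]
}

#' Write slide/case composition tables and a JSON report
#'
#' @param comps list of `case_composition` objects.
#' @param prefix output path prefix; writes `<prefix>_cases.csv` and
#'   `<prefix>_report.json`.
#' @return invisibly, the case-level data.frame.
#' @export
write_composition_tables <- function(comps, prefix) {
  rows <- do.call(rbind, lapply(comps, function(cc) {
    data.frame(case_id = cc$case_id, pattern = .PATTERNS,
               weighted_area = as.numeric(cc$weighted_area[.PATTERNS]),
               pct = as.numeric(cc$pct[.PATTERNS]),
               dominant = cc$dominant, secondary = cc$secondary,
               secondary_is_proxy = cc$secondary_is_proxy,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, paste0(prefix, "_cases.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(comps, function(cc)
      list(case_id = cc$case_id, pct = as.list(round(cc$pct, 6)),
           dominant = cc$dominant, secondary = cc$secondary,
           secondary_is_proxy = cc$secondary_is_proxy)),
    paste0(prefix, "_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(rows)
}

#' Read a multi-rater score table
#'
#' CSV with the item id in the first column (or the column named by
#' `mapping$item`) and one column per rater. Labels may be pattern names
#' or integer codes (resolved via the codebook).
#'
#' @param path CSV path.
#' @param ai_rater optional AI rater column name.
#' @param mapping optional list with `item` (item-id column name) and
#'   `raters` (subset/order of rater columns) to adapt foreign layouts.
#' @param codebook a [pattern_codebook()].
#' @return a [rater_panel()].
#' @export
read_rater_table <- function(path, ai_rater = NULL, mapping = NULL,
                             codebook = pattern_codebook()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  item_col <- if (!is.null(mapping$item)) mapping$item else names(df)[1]
  rater_cols <- if (!is.null(mapping$raters)) mapping$raters
                else setdiff(names(df), item_col)
  R <- as.matrix(df[, rater_cols, drop = FALSE])
  rownames(R) <- as.character(df[[item_col]])
  norm <- function(x) {
    x <- trimws(as.character(x))
    x[x == ""] <- NA
    num <- suppressWarnings(as.integer(x))
    is_code <- !is.na(num)
    x[is_code] <- codebook$name[match(num[is_code], codebook$code)]
    x[!is_code] <- .normalize_pattern(x[!is_code])
    x
  }
  R <- apply(R, 2, norm)
  rownames(R) <- as.character(df[[item_col]])
  rater_panel(R, ai_rater = ai_rater)
}

#' Read a survival table
#'
#' @param path CSV with the [survival_records()] columns.
#' @param endpoint optional endpoint filter (OS/CSS/PFS) applied when an
#'   `endpoint` column exists.
#' @return a [survival_records()] data.frame.
#' @export
read_survival_table <- function(path, endpoint = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(endpoint) && "endpoint" %in% names(df))
    df <- df[df$endpoint == endpoint, , drop = FALSE]
  survival_records(df)
}

#' Write a survival table
#' @param records a [survival_records()] data.frame.
#' @param path output CSV path.
#' @export
write_survival_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis result as JSON
#'
#' @param x a list of results (matrices are converted to row-wise lists).
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}
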