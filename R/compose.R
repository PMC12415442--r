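# Slide- and case-level pattern compositions from label masks.

#' Construct a label mask
#'
#' @param raster integer matrix of pattern codes plus background code,
#'   (row, column) with origin top-left.
#' @param slide_id slide identifier.
#' @param mpp microns per pixel, or `NULL` when the physical scale is unknown.
#' @return object of class `label_mask`.
#' @export
label_mask <- function(raster, slide_id = "slide", mpp = NULL) {
  raster <- as.matrix(raster)
  if (nrow(raster) < 1L || ncol(raster) < 1L) stop("raster must be >= 1x1")
  storage.mode(raster) <- "integer"
  if (!is.null(mpp) && (!is.finite(mpp) || mpp <= 0))
    stop("mpp must be a positive real")
  structure(list(slide_id = as.character(slide_id), raster = raster,
                 mpp = mpp), class = "label_mask")
}

#' Quantify pattern composition of one label mask
#'
#' Tallies pattern pixels, applies the area-correction weights, and converts
#' to percentages. Background pixels are excluded from all totals. When the
#' mask carries a microns-per-pixel scale, weighted areas are reported in
#' mm^2 (pixels x (mpp/1000)^2), otherwise in weighted pixels.
#'
#' @param mask a [label_mask()].
#' @param codebook a [pattern_codebook()].
#' @param weights named weight vector, see [correction_weights()]. Pass
#'   [unit_weights()] for raw-percent mode.
#' @return object of class `slide_composition`: list with `slide_id`,
#'   `raw_pixels`, `weighted_area`, `pct` (each a named vector over the six
#'   patterns), `background_pixels`, `unit` ("mm2" or "wpx"), `mpp`, and
#'   `empty` flag (TRUE when the mask holds no pattern pixel).
#' @export
#' @examples
#' cb <- pattern_codebook()
#' m <- label_mask(matrix(c(1L, 5L), 10, 200), "s1")  # lepidic + solid
#' quantify_mask(m, cb)$pct
quantify_mask <- function(mask, codebook = pattern_codebook(),
                          weights = correction_weights()) {
  stopifnot(inherits(mask, "label_mask"))
  bg <- attr(codebook, "background_code")
  vals <- mask$raster
  known <- c(bg, codebook$code)
  bad <- setdiff(unique(as.vector(vals)), known)
  if (length(bad))
    stop("raster contains codes absent from codebook: ",
         paste(sort(bad), collapse = ", "))
  counts <- tabulate(match(vals, codebook$code), nbins = 6L)
  names(counts) <- codebook$name
  counts <- counts[.PATTERNS]
  w <- weights[.PATTERNS]
  if (anyNA(w)) stop("weights must be named over all six patterns")
  px_area <- if (is.null(mask$mpp)) 1 else (mask$mpp / 1000)^2
  weighted <- counts * w * px_area
  tot <- sum(weighted)
  pct <- if (tot > 0) 100 * weighted / tot else
    stats::setNames(rep(0, 6L), .PATTERNS)
  structure(list(
    slide_id = mask$slide_id,
    raw_pixels = counts,
    weighted_area = weighted,
    pct = pct,
    background_pixels = sum(vals == bg),
    unit = if (is.null(mask$mpp)) "wpx" else "mm2",
    mpp = mask$mpp,
    empty = tot == 0
  ), class = "slide_composition")
}

#' Resolve dominant and secondary pattern from percentages
#'
#' Dominant is the pattern with the largest (weighted) percentage, ties
#' broken toward the higher severity rank. Secondary is the largest among
#' the remaining patterns reaching at least `min_secondary_pct`; when none
#' does, the Gleason proxy convention applies (secondary := dominant) and
#' the proxy flag is set.
#'
#' @param pct named numeric vector of percentages over the six patterns,
#'   or a `case_composition` / `slide_composition`.
#' @param min_secondary_pct minimum abundance (%) for a reportable
#'   secondary pattern; default 5.
#' @param codebook a [pattern_codebook()] (supplies the severity order).
#' @return list with `dominant`, `secondary`, `secondary_is_proxy`.
#' @export
#' @examples
#' dominant_secondary(c(acinar = 97, solid = 3))  # proxy kicks in
dominant_secondary <- function(pct, min_secondary_pct = 5,
                               codebook = pattern_codebook()) {
  if (inherits(pct, c("case_composition", "slide_composition"))) pct <- pct$pct
  full <- stats::setNames(rep(0, 6L), .PATTERNS)
  full[names(pct)] <- pct
  if (all(full <= 0)) stop("empty composition: no pattern abundance")
  sev <- codebook$severity_rank[match(.PATTERNS, codebook$name)]
  ord <- order(-full, -sev)          # by pct desc, then severity desc
  dominant <- .PATTERNS[ord[1]]
  rest <- ord[-1]
  ok <- rest[full[rest] >= min_secondary_pct & full[rest] > 0]
  if (length(ok)) {
    list(dominant = dominant, secondary = .PATTERNS[ok[1]],
         secondary_is_proxy = FALSE)
  } else {
    list(dominant = dominant, secondary = dominant,
         secondary_is_proxy = TRUE)
  }
}

#' Aggregate slide compositions into a case composition
#'
#' Weighted areas are pooled (summed) across slides before percentages are
#' recomputed, so larger tumor areas dominate the case-level percentages —
#' area-weighted pooling, not a mean of slide percentages. All slides must
#' be on one physical unit: either all mm^2 (mpp known) or all weighted
#' pixels at a shared implicit scale.
#'
#' @param compositions list of `slide_composition` objects.
#' @param case_id case identifier.
#' @param min_secondary_pct passed to [dominant_secondary()].
#' @param codebook a [pattern_codebook()].
#' @return object of class `case_composition`: list with `case_id`,
#'   `slide_ids`, `weighted_area`, `pct`, `dominant`, `secondary`,
#'   `secondary_is_proxy`, `unit`.
#' @export
aggregate_case <- function(compositions, case_id = "case",
                           min_secondary_pct = 5,
                           codebook = pattern_codebook()) {
  if (!length(compositions)) stop("need at least one slide composition")
  if (inherits(compositions, "slide_composition"))
    compositions <- list(compositions)
  units <- vapply(compositions, `[[`, "", "unit")
  if (length(unique(units)) > 1L)
    stop("unit mismatch across slides: mpp known for some slides only")
  area <- Reduce(`+`, lapply(compositions, `[[`, "weighted_area"))
  tot <- sum(area)
  pct <- if (tot > 0) 100 * area / tot else
    stats::setNames(rep(0, 6L), .PATTERNS)
  ds <- if (tot > 0)
    dominant_secondary(pct, min_secondary_pct, codebook)
  else list(dominant = NA_character_, secondary = NA_character_,
            secondary_is_proxy = NA)
  structure(list(
    case_id = as.character(case_id),
    slide_ids = vapply(compositions, `[[`, "", "slide_id"),
    weighted_area = area,
    pct = pct,
    dominant = ds$dominant,
    secondary = ds$secondary,
    secondary_is_proxy = ds$secondary_is_proxy,
    unit = units[1]
  ), class = "case_composition")
}

#' Build a case composition directly from percentages
#'
#' Convenience constructor for tabulated data: percentages are renormalized
#' to sum to 100 when within `tol` of 100 (rounding slack), otherwise an
#' error is raised.
#'
#' @param pct named numeric vector (subset of the six pattern names).
#' @param case_id case identifier.
#' @param min_secondary_pct,codebook as in [aggregate_case()].
#' @param tol allowed deviation of `sum(pct)` from 100 before renormalizing.
#' @return a `case_composition`.
#' @export
case_from_pct <- function(pct, case_id = "case", min_secondary_pct = 5,
                          codebook = pattern_codebook(), tol = 1) {
  full <- stats::setNames(rep(0, 6L), .PATTERNS)
  bad <- setdiff(names(pct), .PATTERNS)
  if (length(bad)) stop("unknown pattern names: ", paste(bad, collapse = ", "))
  full[names(pct)] <- pct
  s <- sum(full)
  if (s <= 0) stop("empty composition")
  if (abs(s - 100) > tol)
    stop("percentages sum to ", signif(s, 6), ", outside tolerance ", tol)
  full <- 100 * full / s
  ds <- dominant_secondary(full, min_secondary_pct, codebook)
  structure(list(
    case_id = as.character(case_id), slide_ids = character(0),
    weighted_area = full, pct = full,
    dominant = ds$dominant, secondary = ds$secondary,
    secondary_is_proxy = ds$secondary_is_proxy, unit = "pct"
  ), class = "case_composition")
}

#' @export
print.slide_composition <- function(x, ...) {
  cat("<slide_composition>", x$slide_id,
      if (x$empty) "(empty: all background)" else "", "\n")
  print(round(rbind(pixels = x$raw_pixels,
                    area = x$weighted_area, pct = x$pct), 3))
  invisible(x)
}

#' @export
print.case_composition <- function(x, ...) {
  cat("<case_composition>", x$case_id, "| dominant:", x$dominant,
      "| secondary:", x$secondary,
      if (isTRUE(x$secondary_is_proxy)) "(proxy)" else "", "\n")
  print(round(x$pct, 3))
  invisible(x)
}
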