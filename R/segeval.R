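# Pixel-level evaluation of a predicted pattern mask against ground truth.

.check_pair <- function(gt, pred) {
  g <- if (inherits(gt, "label_mask")) gt$raster else as.matrix(gt)
  p <- if (inherits(pred, "label_mask")) pred$raster else as.matrix(pred)
  if (!identical(dim(g), dim(p)))
    stop("shape mismatch: gt ", paste(dim(g), collapse = "x"),
         " vs pred ", paste(dim(p), collapse = "x"))
  list(gt = as.vector(g), pred = as.vector(p))
}

#' Per-class Dice (F1) of a predicted mask
#'
#' Dice_c = 2 |GT_c intersect PR_c| / (|GT_c| + |PR_c|), measuring overlap
#' of ground truth and prediction per pattern class in \[0, 1\]. Pixels
#' where the ground truth equals `ignore_code` (unannotated / background)
#' are excluded before any tally, so the evaluation is restricted to the
#' annotated region. The macro Dice is the unweighted mean over classes
#' present in the ground truth; a support-weighted mean is also reported.
#'
#' @param gt,pred [label_mask()]s or integer matrices of equal shape.
#' @param ignore_code ground-truth code excluded from evaluation
#'   (default: the codebook's background code).
#' @param codebook a [pattern_codebook()].
#' @return list with `dice_by_class` (named over the six patterns, `NaN`
#'   for classes absent from both masks), `macro_dice`, `weighted_dice`,
#'   `support` (gt pixels per class).
#' @export
dice_per_class <- function(gt, pred,
                           ignore_code = attr(codebook, "background_code"),
                           codebook = pattern_codebook()) {
  v <- .check_pair(gt, pred)
  keep <- v$gt != ignore_code
  g <- v$gt[keep]; p <- v$pred[keep]
  codes <- codebook$code
  gi <- match(g, codes); pi <- match(p, codes)
  n_gt <- tabulate(gi, 6L)
  n_pr <- tabulate(pi, 6L)
  n_int <- tabulate(gi[!is.na(gi) & !is.na(pi) & gi == pi], 6L)
  dice <- ifelse(n_gt + n_pr > 0, 2 * n_int / (n_gt + n_pr), NaN)
  names(dice) <- codebook$name
  dice <- dice[.PATTERNS]
  support <- stats::setNames(n_gt, codebook$name)[.PATTERNS]
  present <- support > 0
  list(dice_by_class = dice,
       macro_dice = mean(dice[present]),
       weighted_dice = sum(dice[present] * support[present]) /
         sum(support[present]),
       support = support)
}

#' Discrepant-pixel structure of a predicted mask
#'
#' For each ground-truth class c, over the pixels with gt = c but
#' pred != c, the row gives the percentage of those misclassified pixels
#' assigned to each other class. Pixels predicted as background inside the
#' annotated region are tallied in a seventh `background` column. Rows sum
#' to 100 where any discrepant pixel exists and are `NA` otherwise; the
#' diagonal is 0 by construction.
#'
#' @inheritParams dice_per_class
#' @return list with `discrepancy` (6 x 7 matrix of row percentages),
#'   `n_discrepant` (misclassified pixels per gt class), `support`.
#' @export
discrepancy_matrix <- function(gt, pred,
                               ignore_code = attr(codebook, "background_code"),
                               codebook = pattern_codebook()) {
  v <- .check_pair(gt, pred)
  keep <- v$gt != ignore_code
  g <- v$gt[keep]; p <- v$pred[keep]
  cols <- c(.PATTERNS, "background")
  M <- matrix(NA_real_, 6, 7, dimnames = list(.PATTERNS, cols))
  n_disc <- stats::setNames(integer(6), .PATTERNS)
  gname <- codebook$name[match(g, codebook$code)]
  pname <- codebook$name[match(p, codebook$code)]
  pname[p == ignore_code] <- "background"
  for (c_ in .PATTERNS) {
    sel <- !is.na(gname) & gname == c_ & pname != c_
    n <- sum(sel)
    n_disc[c_] <- n
    if (n > 0) {
      cnt <- table(factor(pname[sel], levels = cols))
      M[c_, ] <- 100 * as.numeric(cnt) / n
      M[c_, c_] <- 0
    }
  }
  list(discrepancy = M, n_discrepant = n_disc,
       support = stats::setNames(tabulate(match(gname, .PATTERNS), 6L),
                                 .PATTERNS))
}

#' Combined segmentation evaluation report
#'
#' @inheritParams dice_per_class
#' @return list of class `eval_report` merging [dice_per_class()] and
#'   [discrepancy_matrix()] outputs.
#' @export
seg_eval <- function(gt, pred,
                     ignore_code = attr(codebook, "background_code"),
                     codebook = pattern_codebook()) {
  d <- dice_per_class(gt, pred, ignore_code, codebook)
  m <- discrepancy_matrix(gt, pred, ignore_code, codebook)
  structure(c(d, m[c("discrepancy", "n_discrepant")]),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> macro Dice:", round(x$macro_dice, 4),
      "| support-weighted:", round(x$weighted_dice, 4), "\n")
  print(round(x$dice_by_class, 4))
  invisible(x)
}
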