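# Interobserver agreement: kappa, simple agreement, majority vote with
# consensus rule, leave-one-out analysis.

#' Build a rater panel
#'
#' @param ratings items x raters matrix (or data.frame) of pattern labels;
#'   `NA` marks a missing rating. Row names are item (ROI) ids, column
#'   names rater ids.
#' @param ai_rater optional id of an AI rater column. The AI participates
#'   in pairwise kappa but is always excluded from majority votes.
#' @return object of class `rater_panel`.
#' @export
rater_panel <- function(ratings, ai_rater = NULL) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2L) stop("at least 2 raters required")
  if (nrow(ratings) < 1L) stop("at least 1 item required")
  if (is.null(colnames(ratings)))
    colnames(ratings) <- paste0("R", seq_len(ncol(ratings)))
  if (is.null(rownames(ratings)))
    rownames(ratings) <- paste0("item", seq_len(nrow(ratings)))
  known <- ratings[!is.na(ratings)]
  bad <- setdiff(unique(known), .PATTERNS)
  if (length(bad))
    stop("labels outside the six-pattern vocabulary: ",
         paste(bad, collapse = ", "))
  if (!is.null(ai_rater) && !ai_rater %in% colnames(ratings))
    stop("ai_rater not found among rater columns")
  structure(list(items = rownames(ratings), raters = colnames(ratings),
                 ratings = ratings, ai_rater = ai_rater),
            class = "rater_panel")
}

#' Cohen's kappa between two label vectors
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e). With
#' `weighting = "equal"`, linearly spaced disagreement weights
#' `|i - j| / (k - 1)` over the declared category order give partial credit
#' to near-miss categories (equal-weight kappa). Pairs with a missing value
#' are dropped. When chance agreement is 1 (both raters constant on the
#' same single category) kappa is defined as 1.
#'
#' @param a,b label vectors of equal length.
#' @param weighting "none" (unweighted) or "equal" (linear weights).
#' @param categories the full ordered category list defining weight
#'   distances; defaults to the six patterns in severity order.
#' @return kappa in \[-1, 1\].
#' @export
#' @examples
#' cohen_kappa(c("acinar","acinar","solid","solid"),
#'             c("acinar","solid","solid","solid"),
#'             categories = c("acinar", "solid"))  # 0.5
cohen_kappa <- function(a, b, weighting = c("none", "equal"),
                        categories = severity_order()) {
  weighting <- match.arg(weighting)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no overlapping non-missing ratings")
  bad <- setdiff(unique(c(a, b)), categories)
  if (length(bad))
    stop("labels not in declared category order: ", paste(bad, collapse = ", "))
  fa <- factor(a, levels = categories)
  fb <- factor(b, levels = categories)
  O <- table(fa, fb) / length(a)
  pa <- rowSums(O); pb <- colSums(O)
  k <- length(categories)
  if (weighting == "none") {
    po <- sum(diag(O)); pe <- sum(pa * pb)
    if (abs(1 - pe) < .Machine$double.eps^0.5) return(1)
    (po - pe) / (1 - pe)
  } else {
    w <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
    E <- outer(pa, pb)
    den <- sum(w * E)
    if (den < .Machine$double.eps^0.5) return(1)
    1 - sum(w * O) / den
  }
}

#' Simple agreement between two label vectors
#'
#' Fraction of items with identical labels, over pairs where both ratings
#' are present.
#'
#' @param a,b label vectors of equal length.
#' @return agreement in \[0, 1\].
#' @export
simple_agreement <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no overlapping non-missing ratings")
  mean(a[keep] == b[keep])
}

#' Pairwise kappa matrix and per-rater averages
#'
#' Computes kappa for every rater pair and the per-rater average (excluding
#' self). When the panel declares an AI rater, a second set of averages over
#' pathologist partners only (`avg_ai_excluded`) is reported, so the AI's
#' own average and the pathologists' averages are comparable on the same
#' partner set.
#'
#' @param panel a [rater_panel()].
#' @param weighting,categories see [cohen_kappa()].
#' @return list with `kappa` (symmetric matrix), `avg` (named per-rater
#'   means), `avg_ai_excluded` (or NULL), `agreement` (simple-agreement
#'   matrix), `avg_agreement`.
#' @export
pairwise_kappa <- function(panel, weighting = c("none", "equal"),
                           categories = severity_order()) {
  weighting <- match.arg(weighting)
  R <- panel$ratings
  empty <- colSums(!is.na(R)) == 0
  if (any(empty)) {
    warning("excluding raters with all-missing ratings: ",
            paste(colnames(R)[empty], collapse = ", "))
    R <- R[, !empty, drop = FALSE]
  }
  nr <- ncol(R)
  if (nr < 2L) stop("fewer than 2 usable raters")
  K <- matrix(1, nr, nr, dimnames = list(colnames(R), colnames(R)))
  A <- K
  for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
    K[i, j] <- K[j, i] <- cohen_kappa(R[, i], R[, j], weighting, categories)
    A[i, j] <- A[j, i] <- simple_agreement(R[, i], R[, j])
  }
  off <- function(M) {
    v <- vapply(seq_len(nr), function(i) mean(M[i, -i]), 0)
    names(v) <- colnames(R); v
  }
  avg_ai <- NULL
  ai <- panel$ai_rater
  if (!is.null(ai) && ai %in% colnames(R)) {
    path <- setdiff(colnames(R), ai)
    avg_ai <- vapply(colnames(R), function(r)
      mean(K[r, setdiff(path, r)]), 0)
  }
  list(kappa = K, avg = off(K), avg_ai_excluded = avg_ai,
       agreement = A, avg_agreement = off(A))
}

#' Majority vote with consensus rule
#'
#' For each item, the modal label over the (non-AI, non-missing) ratings is
#' the majority vote MV-1; the second most frequent label is MV-2. Consensus
#' is reached when the modal count meets `consensus_min` (default: strict
#' majority of the participating raters, i.e. 7 of 13). A tie for the modal
#' label yields no consensus; MV-1 is then the most severe of the tied
#' labels, and the tie is flagged.
#'
#' @param panel a [rater_panel()]; the declared AI rater is excluded.
#' @param consensus_min minimum modal count for consensus; `NULL` for
#'   strict majority `floor(n/2) + 1`.
#' @param codebook a [pattern_codebook()] (severity tie-break order).
#' @return data.frame with one row per item: `item`, `mv1`, `mv2`,
#'   `mv1_count`, `n_ratings`, `n_distinct`, `consensus`, `tie`, plus the
#'   per-pattern counts as a `counts` matrix attribute.
#' @export
majority_vote <- function(panel, consensus_min = NULL,
                          codebook = pattern_codebook()) {
  R <- panel$ratings
  if (!is.null(panel$ai_rater))
    R <- R[, setdiff(colnames(R), panel$ai_rater), drop = FALSE]
  n_raters <- ncol(R)
  if (is.null(consensus_min)) consensus_min <- n_raters %/% 2 + 1
  if (consensus_min > n_raters)
    stop("consensus_min exceeds number of participating raters")
  sev_desc <- rev(severity_order(codebook))
  counts <- t(apply(R, 1, function(r)
    table(factor(r[!is.na(r)], levels = sev_desc))))
  colnames(counts) <- sev_desc
  pick <- function(cnt, exclude = NULL) {
    if (!is.null(exclude)) cnt[exclude] <- -1L
    if (all(cnt <= 0)) return(list(lab = NA_character_, n = 0L, tie = FALSE))
    m <- max(cnt)
    tied <- names(cnt)[cnt == m]
    list(lab = tied[1], n = m, tie = length(tied) > 1)  # sev-desc order
  }
  rows <- lapply(seq_len(nrow(R)), function(i) {
    cnt <- counts[i, ]
    p1 <- pick(cnt)
    p2 <- pick(cnt, exclude = p1$lab)
    data.frame(item = rownames(R)[i], mv1 = p1$lab, mv2 = p2$lab,
               mv1_count = p1$n, n_ratings = sum(cnt),
               n_distinct = sum(cnt > 0),
               consensus = !p1$tie && p1$n >= consensus_min,
               tie = p1$tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "counts") <- counts
  attr(out, "consensus_min") <- consensus_min
  out
}

#' Leave-one-out majority-vote agreement for one rater
#'
#' Compares a target rater's labels with the majority vote of the remaining
#' raters (the target and any raters in `exclude` — by default the AI — are
#' removed from the vote). The comparison is restricted to items where the
#' reduced vote reaches consensus and the target provided a rating; dropped
#' items are counted.
#'
#' @param panel a [rater_panel()].
#' @param target_rater rater id to evaluate.
#' @param exclude further rater ids excluded from the vote (default: the
#'   panel's AI rater).
#' @param consensus_min see [majority_vote()]; `NULL` for strict majority
#'   of the reduced panel.
#' @param weighting,categories see [cohen_kappa()].
#' @return list with `kappa`, `agreement`, `n_items` (used),
#'   `n_no_consensus`, `n_missing`.
#' @export
leave_one_out <- function(panel, target_rater,
                          exclude = panel$ai_rater, consensus_min = NULL,
                          weighting = c("none", "equal"),
                          categories = severity_order()) {
  weighting <- match.arg(weighting)
  if (target_rater %in% exclude) stop("target rater cannot be in exclude set")
  rest <- setdiff(panel$raters, c(target_rater, exclude))
  if (length(rest) < 2L) stop("fewer than 2 raters remain for the vote")
  sub <- rater_panel(panel$ratings[, rest, drop = FALSE])
  mv <- majority_vote(sub, consensus_min)
  tgt <- panel$ratings[, target_rater]
  use <- mv$consensus & !is.na(tgt)
  if (!any(use)) stop("no consensus items remain for rater ", target_rater)
  list(kappa = cohen_kappa(tgt[use], mv$mv1[use], weighting, categories),
       agreement = simple_agreement(tgt[use], mv$mv1[use]),
       n_items = sum(use),
       n_no_consensus = sum(!mv$consensus),
       n_missing = sum(mv$consensus & is.na(tgt)))
}

#' Full agreement analysis of a rater panel
#'
#' Runs the complete interobserver protocol: pairwise kappa (and simple
#' agreement) with per-rater averages, majority vote with the consensus
#' rule, the consensus/no-consensus split, per-pattern consensus counts
#' (of the items whose majority label is each pattern, how many reached
#' consensus), and the leave-one-out analysis per rater.
#'
#' @param panel a [rater_panel()].
#' @param weighting,categories see [cohen_kappa()].
#' @param consensus_min see [majority_vote()].
#' @return list with components `pairwise`, `votes`, `n_items`,
#'   `n_consensus`, `n_no_consensus`, `pattern_consensus` (data.frame:
#'   pattern, n_mv1, n_consensus), `leave_one_out` (data.frame per
#'   non-AI rater), `kappa_range` (min/max of pathologists' averages).
#' @export
agreement_report <- function(panel, weighting = c("none", "equal"),
                             categories = severity_order(),
                             consensus_min = NULL) {
  weighting <- match.arg(weighting)
  pw <- pairwise_kappa(panel, weighting, categories)
  mv <- majority_vote(panel, consensus_min)
  pat_cons <- do.call(rbind, lapply(.PATTERNS, function(p) {
    sel <- !is.na(mv$mv1) & mv$mv1 == p
    data.frame(pattern = p, n_mv1 = sum(sel),
               n_consensus = sum(sel & mv$consensus),
               stringsAsFactors = FALSE)
  }))
  humans <- setdiff(panel$raters, panel$ai_rater)
  loo <- do.call(rbind, lapply(humans, function(r) {
    res <- leave_one_out(panel, r, exclude = panel$ai_rater,
                         consensus_min = consensus_min,
                         weighting = weighting, categories = categories)
    data.frame(rater = r, kappa = res$kappa, agreement = res$agreement,
               n_items = res$n_items, stringsAsFactors = FALSE)
  }))
  avg_h <- if (!is.null(pw$avg_ai_excluded))
    pw$avg_ai_excluded[humans] else pw$avg[humans]
  list(pairwise = pw, votes = mv, n_items = nrow(mv),
       n_consensus = sum(mv$consensus),
       n_no_consensus = sum(!mv$consensus),
       pattern_consensus = pat_cons,
       leave_one_out = loo,
       kappa_range = range(avg_h))
}
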