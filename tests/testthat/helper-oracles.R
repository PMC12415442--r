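# Independent brute-force oracles. These deliberately re-derive every rule
# from first principles in scalar code, sharing nothing with the package's
# vectorized implementations.

PAT <- c("lepidic", "acinar", "papillary", "micropapillary", "solid",
         "complex_glandular")

# scalar rule-table grader: one composition -> all six systems
oracle_grade_all <- function(pct) {
  sev <- c(lepidic = 1, acinar = 2, papillary = 3, complex_glandular = 4,
           micropapillary = 5, solid = 6)
  t3 <- c(lepidic = 1, acinar = 2, papillary = 2, micropapillary = 3,
          solid = 3, complex_glandular = 3)
  t4 <- c(lepidic = 1, acinar = 2, papillary = 2, complex_glandular = 3,
          micropapillary = 4, solid = 4)
  nm <- names(pct)
  top <- nm[pct == max(pct)]
  dom <- top[which.max(sev[top])]
  rest <- pct[setdiff(nm, dom)]
  cand <- rest[rest >= 5 & rest > 0]
  sec <- if (length(cand)) {
    t2 <- names(cand)[cand == max(cand)]
    t2[which.max(sev[t2])]
  } else dom
  hg3 <- sum(pct[c("micropapillary", "solid", "complex_glandular")])
  hg2 <- sum(pct[c("micropapillary", "solid")])
  who <- t3[[dom]]
  d <- t3[[dom]]; s <- t3[[sec]]; score <- d + s
  pg <- if (score == 2) "PG0"
        else if (d == 1 && s == 2) "PG1"
        else if (d == 2 && s == 1) "PG2"
        else if (score == 4) "PG3"
        else if (score == 5) "PG4"
        else "PG5"
  c(WHO = paste0("G", who),
    IASLC = paste0("G", if (who < 3 && hg3 > 20) 3 else who),
    IASLC_SIMPLIFIED = paste0("G", if (who < 3 && hg2 > 20) 3 else who),
    IASLC_MODIFIED = paste0("G", if (who < 3 && hg3 > 50) 3 else who),
    FOUR_TIER = paste0("G", t4[[dom]]),
    PROG_SCORE = pg)
}

# all weak compositions of `total` into 6 parts with step `step` (percent)
simplex_grid <- function(step = 5, total = 100) {
  n <- total / step
  rows <- list()
  for (a in 0:n) for (b in 0:(n - a)) for (c_ in 0:(n - a - b))
    for (d in 0:(n - a - b - c_)) for (e in 0:(n - a - b - c_ - d)) {
      f <- n - a - b - c_ - d - e
      rows[[length(rows) + 1L]] <- c(a, b, c_, d, e, f)
    }
  m <- do.call(rbind, rows) * step
  colnames(m) <- PAT
  m
}

# brute-force tally of the joint (gt, pred) pixel counts over every class
# pair, then Dice and the discrepancy rows from the counts
oracle_seg <- function(gt, pred, bg = 0L) {
  labs <- c(PAT, "background")
  g <- as.vector(gt); p <- as.vector(pred)
  codes <- c(1:6, bg)
  cnt <- matrix(0L, 7, 7, dimnames = list(labs, labs))
  for (i in 1:7) for (j in 1:7)
    cnt[i, j] <- sum(g == codes[i] & p == codes[j])
  cnt <- cnt[1:6, , drop = FALSE]      # drop gt-background rows (ignored)
  dice <- sapply(PAT, function(c_) {
    a <- sum(cnt[c_, ])                 # |GT_c| within annotated region
    b <- sum(cnt[, c_])                 # |PR_c| within annotated region
    if (a + b == 0) NaN else 2 * cnt[c_, c_] / (a + b)
  })
  disc <- matrix(NA_real_, 6, 7, dimnames = list(PAT, labs))
  for (c_ in PAT) {
    wrong <- cnt[c_, ]; wrong[c_] <- 0L
    if (sum(wrong) > 0) {
      disc[c_, ] <- 100 * wrong / sum(wrong)
      disc[c_, c_] <- 0
    }
  }
  support <- rowSums(cnt)
  present <- support > 0
  list(dice = dice, macro = mean(dice[present]), disc = disc,
       support = support)
}

# independent two-rater kappa from an explicitly built contingency table
oracle_kappa <- function(a, b, cats, weighted = FALSE) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  k <- length(cats)
  O <- matrix(0, k, k, dimnames = list(cats, cats))
  for (i in seq_along(a)) O[a[i], b[i]] <- O[a[i], b[i]] + 1
  O <- O / sum(O)
  pa <- rowSums(O); pb <- colSums(O)
  if (!weighted) {
    po <- sum(diag(O)); pe <- sum(pa * pb)
    if (1 - pe < 1e-12) return(1)
    (po - pe) / (1 - pe)
  } else {
    w <- abs(outer(1:k, 1:k, "-")) / (k - 1)
    den <- sum(w * outer(pa, pb))
    if (den < 1e-12) return(1)
    1 - sum(w * O) / den
  }
}

# item-by-item modal label with severity tie-break (most severe wins)
oracle_mode <- function(labels, sev_order) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return(list(lab = NA, n = 0, tie = FALSE))
  tab <- table(labels)
  m <- max(tab)
  tied <- names(tab)[tab == m]
  best <- tied[which.max(match(tied, sev_order))]
  list(lab = best, n = as.integer(m), tie = length(tied) > 1)
}

default_panel_fixture <- function(n_items = 300, seed = 42) {
  gen_rater_panel(n_items = n_items,
                  confusions = default_rater_confusions(),
                  seed = seed)
}
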