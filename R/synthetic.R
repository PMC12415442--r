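# Seeded synthetic generators: mask pairs with known confusion, rater
# panels with known per-rater confusion matrices, and survival cohorts with
# known proportional-hazards structure. These give every analysis module a
# test surface with known ground truth; they emulate the statistical
# structure of the real inputs, not histology texture.

#' Default simulation specification (the standard fixture)
#'
#' Bundles the default sizes and parameters of all generators: a 13-rater,
#' 283-item agreement panel over the six patterns; a 1000-case survival
#' cohort with five prognostic-score groups, a log hazard ratio of 0.6 per
#' grade step and 20% independent censoring; 64 x 64 mask pairs.
#'
#' @param seed integer seed.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L) {
  structure(list(seed = as.integer(seed),
                 n_items = 283L, n_raters = 13L,
                 n_cases = 1000L, mask_size = 64L,
                 log_hr_step = 0.6, censoring = 0.2,
                 baseline_rate = 0.01),
            class = "sim_spec")
}

#' Build a row-stochastic rater/segmentation confusion matrix
#'
#' Diagonal mass `acc` (probability of the true label); the remaining mass
#' is spread over the other categories, decaying with severity-order
#' distance so that confusions fall mostly between morphologically adjacent
#' patterns.
#'
#' @param acc per-class probability of the correct label, scalar or
#'   length-6 vector.
#' @param decay geometric decay per unit of category distance.
#' @return 6 x 6 row-stochastic matrix, rows = true pattern, columns =
#'   assigned pattern, in severity order.
#' @export
make_confusion <- function(acc = 0.7, decay = 0.5) {
  cats <- severity_order()
  k <- length(cats)
  acc <- rep(acc, length.out = k)
  stopifnot(all(acc > 0 & acc <= 1))
  M <- matrix(0, k, k, dimnames = list(cats, cats))
  for (i in seq_len(k)) {
    off <- decay^abs(seq_len(k) - i)
    off[i] <- 0
    M[i, ] <- off / sum(off) * (1 - acc[i])
    M[i, i] <- acc[i]
  }
  M
}

.check_stochastic <- function(M) {
  if (!is.matrix(M) || any(M < 0) ||
      any(abs(rowSums(M) - 1) > 1e-8))
    stop("confusion matrix must be row-stochastic (rows sum to 1)")
  if (is.null(dimnames(M))) {
    cats <- severity_order()
    dimnames(M) <- list(cats, cats)
  }
  M
}

#' Generate a ground-truth / prediction mask pair with known confusion
#'
#' The ground truth is a blobby multi-class raster built from random seed
#' points (each pixel takes the class of its nearest seed, giving
#' Voronoi-like regions). The prediction corrupts each pixel independently
#' according to the given confusion matrix, so segmentation metrics can be
#' checked against the generating matrix.
#'
#' @param size raster side length (>= 16).
#' @param confusion 6 x 6 row-stochastic matrix over the patterns in
#'   severity order (see [make_confusion()]); identity = perfect
#'   prediction.
#' @param n_blobs number of seed regions.
#' @param bg_frac fraction of blobs assigned to background.
#' @param seed integer seed.
#' @param codebook a [pattern_codebook()].
#' @return list with `gt`, `pred` (both [label_mask()]s) and `confusion`.
#' @export
gen_mask_pair <- function(size = 64, confusion = make_confusion(0.8),
                          n_blobs = 25, bg_frac = 0.15, seed = 1L,
                          codebook = pattern_codebook()) {
  if (size < 16) stop("mask_size must be >= 16")
  confusion <- .check_stochastic(confusion)
  set.seed(seed)
  cats <- severity_order(codebook)
  bg <- attr(codebook, "background_code")
  cx <- stats::runif(n_blobs, 1, size)
  cy <- stats::runif(n_blobs, 1, size)
  blob_cls <- ifelse(stats::runif(n_blobs) < bg_frac, "background",
                     sample(cats, n_blobs, replace = TRUE))
  px <- expand.grid(r = seq_len(size), c = seq_len(size))
  d2 <- outer(px$r, cx, "-")^2 + outer(px$c, cy, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  gt_name <- blob_cls[nearest]
  code_of <- function(nm) ifelse(nm == "background", bg,
                                 codebook$code[match(nm, codebook$name)])
  gt <- matrix(code_of(gt_name), size, size)
  pred_name <- gt_name
  for (c_ in cats) {
    sel <- gt_name == c_
    if (any(sel))
      pred_name[sel] <- sample(cats, sum(sel), replace = TRUE,
                               prob = confusion[c_, ])
  }
  pred <- matrix(code_of(pred_name), size, size)
  list(gt = label_mask(gt, "gt"), pred = label_mask(pred, "pred"),
       confusion = confusion)
}

#' Generate a multi-rater panel with known confusion structure
#'
#' Each item carries a latent true pattern drawn from `prior`; each rater's
#' label is drawn from their personal confusion matrix row for that latent
#' pattern. The expected pairwise kappa between any two raters is then
#' available in closed form via [expected_pairwise_kappa()].
#'
#' @param n_items number of ROIs.
#' @param confusions list of 6 x 6 row-stochastic matrices, one per rater
#'   (>= 2); names become rater ids.
#' @param prior probability vector over the six patterns (severity order).
#' @param seed integer seed.
#' @param ai_rater optional name of the rater to flag as the AI.
#' @return list with `panel` (a [rater_panel()]), `latent` (true pattern
#'   per item), `prior`, `confusions`.
#' @export
gen_rater_panel <- function(n_items = 283,
                            confusions = default_rater_confusions(),
                            prior = rep(1 / 6, 6), seed = 1L,
                            ai_rater = NULL) {
  if (length(confusions) < 2L) stop("at least 2 raters required")
  confusions <- lapply(confusions, .check_stochastic)
  stopifnot(length(prior) == 6, all(prior >= 0), sum(prior) > 0)
  prior <- prior / sum(prior)
  set.seed(seed)
  cats <- severity_order()
  if (is.null(names(confusions)))
    names(confusions) <- paste0("P", seq_along(confusions))
  latent <- sample(cats, n_items, replace = TRUE, prob = prior)
  R <- vapply(confusions, function(M) {
    out <- character(n_items)
    for (c_ in cats) {
      sel <- latent == c_
      if (any(sel))
        out[sel] <- sample(cats, sum(sel), replace = TRUE, prob = M[c_, ])
    }
    out
  }, character(n_items))
  rownames(R) <- sprintf("ROI%03d", seq_len(n_items))
  list(panel = rater_panel(R, ai_rater = ai_rater),
       latent = latent, prior = stats::setNames(prior, cats),
       confusions = confusions)
}

#' Default 13-rater confusion set for the standard panel fixture
#'
#' Thirteen raters with per-class accuracies spread over 0.55-0.80,
#' emulating low-to-moderate interobserver agreement on pattern subtyping.
#'
#' @param n_raters number of raters.
#' @return named list of confusion matrices.
#' @export
default_rater_confusions <- function(n_raters = 13) {
  accs <- seq(0.55, 0.80, length.out = n_raters)
  out <- lapply(accs, make_confusion)
  names(out) <- paste0("P", seq_len(n_raters))
  out
}

#' Closed-form expected kappa between two raters
#'
#' Given the latent-pattern prior and two row-stochastic confusion
#' matrices, the joint label distribution is
#' P(a = i, b = j) = sum_t prior_t A\[t, i\] B\[t, j\]; observed and chance
#' agreement (and their weighted analogues) follow directly, giving the
#' large-sample expectation of [cohen_kappa()].
#'
#' @param prior probability vector over categories.
#' @param A,B row-stochastic confusion matrices (rows = latent category).
#' @param weighting "none" or "equal" (linear weights).
#' @return expected kappa.
#' @export
expected_pairwise_kappa <- function(prior, A, B,
                                    weighting = c("none", "equal")) {
  weighting <- match.arg(weighting)
  prior <- prior / sum(prior)
  J <- t(A) %*% diag(prior) %*% B   # J[i, j] = P(a = i, b = j)
  pa <- rowSums(J); pb <- colSums(J)
  k <- length(prior)
  if (weighting == "none") {
    po <- sum(diag(J)); pe <- sum(pa * pb)
    (po - pe) / (1 - pe)
  } else {
    w <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
    1 - sum(w * J) / sum(w * outer(pa, pb))
  }
}

# (dominant tier, secondary tier) combinations per prognostic-score group
.PG_COMBOS <- list(
  `1` = list(c(1, 2)),                       # score 3a
  `2` = list(c(2, 1)),                       # score 3b
  `3` = list(c(2, 2), c(1, 3), c(3, 1)),     # score 4
  `4` = list(c(2, 3), c(3, 2)),              # score 5
  `5` = list(c(3, 3))                        # score 6
)

#' Generate a synthetic survival cohort with known prognostic structure
#'
#' Each case draws a latent prognostic group (PG1..PG5). A dominant and a
#' secondary pattern whose three-tier grades sum to that group's score are
#' chosen, and a full six-pattern composition is built around them
#' (dominant 50-65%, secondary the majority of the remainder, the rest
#' spread over the other patterns), so re-grading the composition recovers
#' the latent group. Survival times are exponential under a proportional-
#' hazards model with `log_hr_step` per grade step above PG1; censoring is
#' by an independent exponential time calibrated so the expected censored
#' fraction equals `censoring`. pT, pN and age are drawn with mild positive
#' correlation with the latent grade; a cohort label (C1..C5) is assigned
#' at random.
#'
#' @param n_cases number of cases (>= 10).
#' @param log_hr_step log hazard ratio per grade-group step.
#' @param censoring expected censored fraction in \[0, 1).
#' @param baseline_rate baseline exponential event rate per month (PG1).
#' @param group_probs probability of each of the five groups.
#' @param seed integer seed.
#' @param codebook a [pattern_codebook()].
#' @return list with `compositions` (list of `case_composition`),
#'   `records` (a [survival_records()] data.frame with endpoint OS),
#'   `latent` (data.frame: case_id, pg_group, score, dominant, secondary).
#' @export
gen_cohort <- function(n_cases = 1000, log_hr_step = 0.6, censoring = 0.2,
                       baseline_rate = 0.01,
                       group_probs = c(0.15, 0.2, 0.25, 0.2, 0.2),
                       seed = 1L, codebook = pattern_codebook()) {
  if (n_cases < 10) stop("n_cases must be >= 10")
  stopifnot(censoring >= 0, censoring < 1, baseline_rate > 0,
            length(group_probs) == 5)
  set.seed(seed)
  tier_of <- stats::setNames(codebook$tier3, codebook$name)
  by_tier <- split(codebook$name, codebook$tier3)
  ids <- sprintf("case%04d", seq_len(n_cases))
  g <- sample(1:5, n_cases, replace = TRUE, prob = group_probs)
  comps <- vector("list", n_cases)
  dominant <- secondary <- character(n_cases)
  for (i in seq_len(n_cases)) {
    combos <- .PG_COMBOS[[as.character(g[i])]]
    ds <- combos[[sample.int(length(combos), 1)]]
    dom <- sample(by_tier[[as.character(ds[1])]], 1)
    sec_pool <- setdiff(by_tier[[as.character(ds[2])]], dom)
    sec <- sample(sec_pool, 1)
    dom_pct <- stats::runif(1, 50, 65)
    rest <- 100 - dom_pct
    sec_pct <- rest * stats::runif(1, 0.55, 0.70)
    others <- setdiff(.PATTERNS, c(dom, sec))
    filler <- stats::rgamma(4, shape = 1)
    filler <- (rest - sec_pct) * filler / sum(filler)
    pct <- stats::setNames(numeric(6), .PATTERNS)
    pct[dom] <- dom_pct; pct[sec] <- sec_pct; pct[others] <- filler
    comps[[i]] <- case_from_pct(pct, ids[i], codebook = codebook)
    dominant[i] <- dom; secondary[i] <- sec
  }
  rate <- baseline_rate * exp(log_hr_step * (g - 1))
  T_ev <- stats::rexp(n_cases, rate)
  if (censoring > 0) {
    C_ev <- stats::rexp(n_cases, rate * censoring / (1 - censoring))
    time <- pmin(T_ev, C_ev)
    event <- as.integer(T_ev <= C_ev)
  } else {
    time <- T_ev
    event <- rep(1L, n_cases)
  }
  pT_w <- function(gg) { w <- c(4, 3, 2, 1) + 0.8 * (gg - 1); w / sum(w) }
  pT <- vapply(g, function(gg) sample(1:4, 1, prob = pT_w(gg)), 0L)
  pN <- vapply(g, function(gg)
    sample(0:2, 1, prob = c(6 - 0.5 * gg, 1 + 0.3 * gg, 0.5 + 0.2 * gg)), 0L)
  age <- pmin(90, pmax(35, round(stats::rnorm(n_cases, 64 + 0.6 * g, 9))))
  stage <- ifelse(pN >= 2, "III",
           ifelse(pN == 1, "II",
           ifelse(pT <= 2, "I", "II")))
  records <- survival_records(data.frame(
    case_id = ids, endpoint = "OS",
    time = pmax(time, 1e-3), event = event,
    pT = pT, pN = pN, age = age, stage = stage,
    cohort = sample(paste0("C", 1:5), n_cases, replace = TRUE),
    stringsAsFactors = FALSE))
  latent <- data.frame(case_id = ids, pg_group = paste0("PG", g),
                       score = g + 2L, dominant = dominant,
                       secondary = secondary, stringsAsFactors = FALSE)
  list(compositions = comps, records = records, latent = latent)
}
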