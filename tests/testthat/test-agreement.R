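# Kappa, simple agreement, majority vote, leave-one-out.

test_that("kappa matches hand-computed contingency tables", {
  a <- c("acinar", "acinar", "solid", "solid")
  b <- c("acinar", "solid", "solid", "solid")
  # p_o = 0.75, p_e = 0.5 -> kappa = 0.5
  expect_equal(cohen_kappa(a, b), 0.5)
  expect_equal(simple_agreement(a, b), 0.75)
  expect_equal(cohen_kappa(a, a), 1)
  expect_equal(simple_agreement(a, a), 1)
  # single shared category with perfect agreement: defined as 1
  expect_equal(cohen_kappa(rep("solid", 5), rep("solid", 5)), 1)
  expect_equal(cohen_kappa(rep("solid", 5), rep("solid", 5), "equal"), 1)
  # disjoint labels
  expect_equal(simple_agreement(rep("solid", 4), rep("acinar", 4)), 0)
  expect_error(cohen_kappa(NA_character_, NA_character_), "overlap|missing")
})

test_that("kappa agrees with the brute-force oracle on random panels", {
  set.seed(21)
  cats <- severity_order()
  for (rep_ in 1:20) {
    a <- sample(cats, 60, replace = TRUE)
    b <- ifelse(runif(60) < 0.6, a, sample(cats, 60, replace = TRUE))
    expect_equal(cohen_kappa(a, b), oracle_kappa(a, b, cats), tolerance = 1e-12)
    expect_equal(cohen_kappa(a, b, "equal"),
                 oracle_kappa(a, b, cats, weighted = TRUE), tolerance = 1e-12)
  }
})

test_that("chance-level labels give kappa near 0; relabelling invariance", {
  set.seed(22)
  cats <- severity_order()
  a <- sample(cats, 20000, replace = TRUE)
  b <- sample(cats, 20000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.02)
  # unweighted kappa invariant under a category permutation
  perm <- setNames(sample(cats), cats)
  a2 <- unname(perm[a]); b2 <- unname(perm[b])
  expect_equal(cohen_kappa(a, b), cohen_kappa(a2, b2), tolerance = 1e-12)
})

test_that("pairwise matrix, averages and AI handling behave", {
  R <- cbind(P1 = rep(c("acinar", "solid"), 10),
             P2 = rep(c("acinar", "solid"), 10),
             P3 = rep(c("acinar", "solid"), 10))
  pw <- pairwise_kappa(rater_panel(R))
  expect_equal(unname(pw$kappa), matrix(1, 3, 3))
  expect_equal(unname(pw$avg), rep(1, 3))
  # a random rater averages near zero at large n
  set.seed(23)
  cats <- severity_order()
  lat <- sample(cats, 5000, replace = TRUE)
  R2 <- cbind(P1 = lat, P2 = lat, RND = sample(cats, 5000, replace = TRUE))
  pw2 <- pairwise_kappa(rater_panel(R2))
  expect_lt(abs(pw2$avg[["RND"]]), 0.05)
  expect_gt(pw2$avg[["P1"]], 0.4)
  # all-missing rater excluded with a warning
  R3 <- cbind(R, P4 = NA_character_)
  expect_warning(pw3 <- pairwise_kappa(rater_panel(R3)), "all-missing")
  expect_equal(dim(pw3$kappa), c(3, 3))
})

test_that("majority vote applies the consensus rule and severity tie-break", {
  mk <- function(counts) {
    # build a 13-rater single-item panel from a named count vector
    rater_panel(matrix(rep(names(counts), counts), nrow = 1,
                       dimnames = list("roi", paste0("P", 1:sum(counts)))))
  }
  v <- majority_vote(mk(c(acinar = 13)))
  expect_true(v$consensus); expect_equal(v$mv1_count, 13)
  v <- majority_vote(mk(c(acinar = 6, papillary = 4, solid = 3)),
                     consensus_min = 7)
  expect_false(v$consensus)
  expect_equal(v$mv1, "acinar"); expect_equal(v$mv2, "papillary")
  expect_equal(v$n_distinct, 3)
  v <- majority_vote(mk(c(acinar = 7, solid = 6)))
  expect_true(v$consensus); expect_equal(v$mv1, "acinar")
  # modal tie: no consensus, severity-ordered mv1, tie flag
  v <- majority_vote(mk(c(micropapillary = 6, solid = 6, lepidic = 1)))
  expect_false(v$consensus); expect_true(v$tie)
  expect_equal(v$mv1, "solid")
  # default consensus_min for 13 raters is 7 (strict majority)
  expect_equal(attr(majority_vote(mk(c(acinar = 13))), "consensus_min"), 7)
})

test_that("votes match an item-by-item oracle and consensus is monotone", {
  gp <- default_panel_fixture(200, seed = 31)
  mv <- majority_vote(gp$panel)
  sev <- severity_order()
  for (i in seq_len(nrow(mv))) {
    o <- oracle_mode(gp$panel$ratings[i, ], sev)
    expect_equal(mv$mv1[i], o$lab)
    expect_equal(mv$mv1_count[i], o$n)
    expect_equal(mv$tie[i], o$tie)
    expect_equal(mv$n_ratings[i], sum(!is.na(gp$panel$ratings[i, ])))
  }
  # raising consensus_min never creates new consensus items
  for (cm in 8:12) {
    mv_hi <- majority_vote(gp$panel, consensus_min = cm)
    expect_true(all(mv$consensus | !mv_hi$consensus))
    mv <- mv_hi
  }
})

test_that("AI rater is excluded from votes but kept in pairwise kappa", {
  set.seed(32)
  cats <- severity_order()
  lat <- sample(cats, 100, replace = TRUE)
  R <- cbind(P1 = lat, P2 = lat, P3 = lat,
             AI = sample(cats, 100, replace = TRUE))
  panel <- rater_panel(R, ai_rater = "AI")
  mv <- majority_vote(panel)
  expect_true(all(mv$n_ratings == 3))      # AI not counted
  pw <- pairwise_kappa(panel)
  expect_true("AI" %in% rownames(pw$kappa))
  expect_equal(length(pw$avg_ai_excluded), 4)
})

test_that("leave-one-out agrees with definitions", {
  R <- matrix(rep(severity_order(), each = 13), ncol = 13, byrow = TRUE,
              dimnames = list(paste0("i", 1:6), paste0("P", 1:13)))
  panel <- rater_panel(R)
  for (r in c("P1", "P7", "P13")) {
    res <- leave_one_out(panel, r)
    expect_equal(res$kappa, 1)
    expect_equal(res$agreement, 1)
    expect_equal(res$n_items, 6)
  }
  # a rater matching the reduced majority on every consensus item scores 1
  gp <- default_panel_fixture(150, seed = 33)
  R2 <- gp$panel$ratings
  sub <- rater_panel(R2[, -1, drop = FALSE])
  mv <- majority_vote(sub)
  R2[, 1] <- ifelse(mv$consensus, mv$mv1, R2[, 1])
  res <- leave_one_out(rater_panel(R2), colnames(R2)[1])
  expect_equal(res$kappa, 1)
  expect_error(leave_one_out(panel, "P1", exclude = "P1"), "exclude")
})

test_that("agreement_report reproduces counts and ranges coherently", {
  gp <- default_panel_fixture(250, seed = 34)
  rep_ <- agreement_report(gp$panel, weighting = "equal")
  expect_equal(rep_$n_items, 250)
  expect_equal(rep_$n_consensus + rep_$n_no_consensus, 250)
  expect_equal(sum(rep_$pattern_consensus$n_mv1) +
                 sum(is.na(majority_vote(gp$panel)$mv1)), 250)
  expect_true(all(rep_$pattern_consensus$n_consensus <=
                    rep_$pattern_consensus$n_mv1))
  expect_equal(nrow(rep_$leave_one_out), 13)
  expect_true(rep_$kappa_range[1] <= rep_$kappa_range[2])
})
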