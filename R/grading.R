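# Grading engines: WHO, IASLC (+ simplified / modified variants), the
# four-tier dominant-pattern grading and the dominant+secondary prognostic
# score. All engines are pure functions of the case composition.

.SYSTEMS <- c("WHO", "IASLC", "IASLC_SIMPLIFIED", "IASLC_MODIFIED",
              "FOUR_TIER", "PROG_SCORE")

#' Grading configuration
#'
#' @param high_grade_set patterns whose summed abundance can trigger the
#'   IASLC upgrade; default micropapillary, solid and complex glandular.
#' @param high_grade_threshold_pct upgrade threshold in percent. The rule is
#'   a strict greater-than: exactly the threshold does NOT upgrade.
#' @param min_secondary_pct abundance floor for a reportable secondary
#'   pattern (see [dominant_secondary()]).
#' @param tiers 3 or 4; tier system used by [score_prognostic()].
#' @return list of class `grading_config`.
#' @export
grading_config <- function(high_grade_set = c("micropapillary", "solid",
                                              "complex_glandular"),
                           high_grade_threshold_pct = 20,
                           min_secondary_pct = 5,
                           tiers = 3) {
  stopifnot(length(high_grade_set) >= 1,
            all(high_grade_set %in% .PATTERNS),
            high_grade_threshold_pct >= 0, high_grade_threshold_pct <= 100,
            tiers %in% c(3, 4))
  structure(list(high_grade_set = high_grade_set,
                 high_grade_threshold_pct = high_grade_threshold_pct,
                 min_secondary_pct = min_secondary_pct,
                 tiers = tiers),
            class = "grading_config")
}

# Vectorized rule core shared by all engines and the batch API.
# pct: n x 6 numeric matrix, columns .PATTERNS. Dominant/secondary ties are
# broken toward higher severity by scanning columns in severity-descending
# order with max.col(ties.method = "first").
.grade_core <- function(pct, codebook, cfg) {
  sev_desc <- rev(severity_order(codebook))
  m <- pct[, sev_desc, drop = FALSE]
  dom_i <- max.col(m, ties.method = "first")
  dominant <- sev_desc[dom_i]

  m2 <- m
  m2[cbind(seq_len(nrow(m)), dom_i)] <- -Inf
  m2[m2 < cfg$min_secondary_pct] <- -Inf
  sec_i <- max.col(m2, ties.method = "first")
  has_sec <- m2[cbind(seq_len(nrow(m2)), sec_i)] > -Inf
  secondary <- ifelse(has_sec, sev_desc[sec_i], dominant)

  tier3 <- codebook$tier3[match(dominant, codebook$name)]
  tier4 <- codebook$tier4[match(dominant, codebook$name)]
  hg_full <- rowSums(pct[, c("micropapillary", "solid", "complex_glandular"),
                         drop = FALSE])
  hg_cfg <- rowSums(pct[, cfg$high_grade_set, drop = FALSE])
  list(dominant = dominant, secondary = secondary,
       secondary_is_proxy = !has_sec,
       tier3 = tier3, tier4 = tier4,
       hg_full = hg_full, hg_cfg = hg_cfg)
}

.pct_matrix <- function(comp) {
  if (inherits(comp, "case_composition")) comp <- list(comp)
  if (is.list(comp) && all(vapply(comp, inherits, TRUE, "case_composition"))) {
    p <- do.call(rbind, lapply(comp, `[[`, "pct"))
    rownames(p) <- vapply(comp, `[[`, "", "case_id")
    return(p[, .PATTERNS, drop = FALSE])
  }
  p <- as.matrix(comp)
  if (!all(.PATTERNS %in% colnames(p)))
    stop("percentage matrix needs all six pattern columns")
  p[, .PATTERNS, drop = FALSE]
}

.grade_result <- function(system, grade_label, dominant, secondary,
                          high_grade_pct, base_grade = NA_character_,
                          upgraded = FALSE, score = NA_integer_,
                          score_sublabel = NA_character_,
                          purely_lepidic = FALSE) {
  structure(list(system = system, grade_label = unname(grade_label),
                 score = score, score_sublabel = score_sublabel,
                 base_grade = unname(base_grade), upgraded = unname(upgraded),
                 high_grade_pct = unname(high_grade_pct),
                 dominant = dominant, secondary = secondary,
                 purely_lepidic = purely_lepidic),
            class = "grade_result")
}

#' @export
print.grade_result <- function(x, ...) {
  cat("<grade_result>", x$system, "->", x$grade_label,
      if (isTRUE(x$upgraded)) paste0("(upgraded from ", x$base_grade, ")")
      else "", "\n")
  invisible(x)
}

#' WHO three-tier grading (dominant pattern only)
#'
#' G1 for lepidic-dominant, G2 for acinar/papillary-dominant, G3 for
#' micropapillary/solid/complex-glandular-dominant tumors. Non-dominant
#' patterns are ignored; no upgrade rule exists.
#'
#' @param comp a `case_composition` (see [aggregate_case()],
#'   [case_from_pct()]).
#' @param codebook a [pattern_codebook()].
#' @param cfg a [grading_config()].
#' @return a `grade_result`.
#' @export
grade_who <- function(comp, codebook = pattern_codebook(),
                      cfg = grading_config()) {
  g <- .grade_core(.pct_matrix(comp), codebook, cfg)
  .grade_result("WHO", paste0("G", g$tier3), unname(g$dominant),
                unname(g$secondary), g$hg_full)
}

#' IASLC grading (WHO base with high-grade upgrade)
#'
#' Base grade as WHO; a G1 or G2 tumor whose summed high-grade pattern
#' abundance (micropapillary + solid + complex glandular by default)
#' strictly exceeds the threshold (default 20%) is upgraded to G3.
#'
#' @inheritParams grade_who
#' @return a `grade_result` with `upgraded` and `base_grade` filled.
#' @export
grade_iaslc <- function(comp, codebook = pattern_codebook(),
                        cfg = grading_config()) {
  g <- .grade_core(.pct_matrix(comp), codebook, cfg)
  base <- paste0("G", g$tier3)
  up <- g$tier3 < 3 & g$hg_cfg > cfg$high_grade_threshold_pct
  .grade_result("IASLC", if (up) "G3" else base, g$dominant, g$secondary,
                g$hg_cfg, base_grade = if (up) base else NA_character_,
                upgraded = up)
}

#' Simplified IASLC grading (complex glandular excluded from the upgrade sum)
#'
#' As [grade_iaslc()] but only micropapillary + solid count toward the
#' upgrade threshold. A complex-glandular-dominant tumor is still G3 through
#' its base grade.
#'
#' @inheritParams grade_who
#' @export
grade_iaslc_simplified <- function(comp, codebook = pattern_codebook(),
                                   cfg = grading_config()) {
  cfg$high_grade_set <- c("micropapillary", "solid")
  r <- grade_iaslc(comp, codebook, cfg)
  r$system <- "IASLC_SIMPLIFIED"
  r
}

#' Modified IASLC grading (50% high-grade tolerated)
#'
#' As [grade_iaslc()] with the upgrade threshold raised to 50%: up to half
#' the tumor area may be high-grade patterns without upgrade, as long as
#' none of them is dominant (a high-grade dominant is G3 via its base
#' grade).
#'
#' @inheritParams grade_who
#' @export
grade_iaslc_modified <- function(comp, codebook = pattern_codebook(),
                                 cfg = grading_config()) {
  cfg$high_grade_threshold_pct <- 50
  r <- grade_iaslc(comp, codebook, cfg)
  r$system <- "IASLC_MODIFIED"
  r
}

#' Four-tier dominant-pattern grading
#'
#' Accounts for the intermediate risk of the complex glandular pattern:
#' G1 lepidic; G2 acinar, papillary; G3 complex glandular; G4
#' micropapillary, solid. Dominant-pattern based, no upgrade rule.
#'
#' @inheritParams grade_who
#' @export
grade_four_tier <- function(comp, codebook = pattern_codebook(),
                            cfg = grading_config()) {
  g <- .grade_core(.pct_matrix(comp), codebook, cfg)
  .grade_result("FOUR_TIER", paste0("G", g$tier4), g$dominant, g$secondary,
                g$hg_full)
}

#' Dominant + secondary prognostic score (Gleason-style)
#'
#' The score is the sum of the single-pattern tier grades of the dominant
#' and secondary patterns. With three-tier grades the score runs 2..6;
#' score 3 is subdivided into 3a (dominant tier 1 + secondary tier 2) and
#' 3b (2 + 1). Scores map to prognostic groups: 3a -> PG1, 3b -> PG2,
#' 4 -> PG3, 5 -> PG4, 6 -> PG5. Score 2 (purely lepidic tumors, where the
#' secondary pattern is the Gleason proxy of the dominant) is emitted as
#' PG0 with the `purely_lepidic` flag rather than dropped; it is rarely
#' relevant in routine diagnostics but applies to such cases.
#'
#' With `tiers = 4` (complex glandular as its own intermediate tier) the
#' raw `(d, s, score)` is returned without a prognostic-group label, as no
#' canonical grouping exists for that variant.
#'
#' @param dominant,secondary pattern names, or a single `case_composition`
#'   as `dominant` (its resolved dominant/secondary are used).
#' @param tiers 3 (default) or 4.
#' @param codebook a [pattern_codebook()].
#' @return a `grade_result`; `score` holds the sum, `grade_label` the
#'   prognostic group (PG0..PG5) for `tiers = 3` or `"S<score>"` for
#'   `tiers = 4`.
#' @export
#' @examples
#' score_prognostic("lepidic", "acinar")$grade_label   # "PG1" (score 3a)
#' score_prognostic("acinar", "lepidic")$grade_label   # "PG2" (score 3b)
score_prognostic <- function(dominant, secondary = NULL, tiers = 3,
                             codebook = pattern_codebook()) {
  if (inherits(dominant, "case_composition")) {
    comp <- dominant
    dominant <- comp$dominant
    secondary <- comp$secondary
  }
  if (is.null(secondary)) stop("secondary pattern required")
  if (!dominant %in% .PATTERNS || !secondary %in% .PATTERNS)
    stop("unknown pattern name")
  tcol <- if (tiers == 3) "tier3" else "tier4"
  d <- codebook[[tcol]][match(dominant, codebook$name)]
  s <- codebook[[tcol]][match(secondary, codebook$name)]
  if (tiers == 3 && (!d %in% 1:3 || !s %in% 1:3))
    stop("tier value outside 1..3")
  score <- d + s
  if (tiers == 4) {
    return(.grade_result("PROG_SCORE", paste0("S", score), dominant,
                         secondary, NA_real_, score = as.integer(score)))
  }
  sub <- if (d == 1 && s == 2) "3a" else if (d == 2 && s == 1) "3b"
         else NA_character_
  label <- if (score == 2) "PG0"
           else if (identical(sub, "3a")) "PG1"
           else if (identical(sub, "3b")) "PG2"
           else if (score == 4) "PG3"
           else if (score == 5) "PG4"
           else "PG5"
  .grade_result("PROG_SCORE", label, dominant, secondary, NA_real_,
                score = as.integer(score), score_sublabel = sub,
                purely_lepidic = score == 2)
}

#' Grade many cases at once
#'
#' Vectorized batch grading over a case set for one or more systems.
#'
#' @param comps list of `case_composition` objects, or an n x 6 matrix /
#'   data.frame of percentages with the pattern names as columns.
#' @param systems subset of
#'   `c("WHO","IASLC","IASLC_SIMPLIFIED","IASLC_MODIFIED","FOUR_TIER","PROG_SCORE")`.
#' @param codebook a [pattern_codebook()].
#' @param cfg a [grading_config()].
#' @return data.frame with one row per case per system: `case_id`, `system`,
#'   `grade_label`, `score`, `score_sublabel`, `base_grade`, `upgraded`,
#'   `high_grade_pct`, `dominant`, `secondary`.
#' @export
grade_cases <- function(comps, systems = .SYSTEMS,
                        codebook = pattern_codebook(),
                        cfg = grading_config()) {
  systems <- match.arg(systems, .SYSTEMS, several.ok = TRUE)
  pct <- .pct_matrix(comps)
  ids <- rownames(pct)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(pct)))
  g <- .grade_core(pct, codebook, cfg)
  n <- nrow(pct)
  out <- lapply(systems, function(sys) {
    res <- data.frame(case_id = ids, system = sys,
                      grade_label = NA_character_, score = NA_integer_,
                      score_sublabel = NA_character_,
                      base_grade = NA_character_, upgraded = FALSE,
                      high_grade_pct = g$hg_full, dominant = g$dominant,
                      secondary = g$secondary, stringsAsFactors = FALSE)
    if (sys == "WHO") {
      res$grade_label <- paste0("G", g$tier3)
    } else if (sys %in% c("IASLC", "IASLC_SIMPLIFIED", "IASLC_MODIFIED")) {
      hg_set <- switch(sys,
        IASLC = cfg$high_grade_set,
        IASLC_SIMPLIFIED = c("micropapillary", "solid"),
        IASLC_MODIFIED = cfg$high_grade_set)
      thr <- if (sys == "IASLC_MODIFIED") 50 else cfg$high_grade_threshold_pct
      hg <- rowSums(pct[, hg_set, drop = FALSE])
      base <- paste0("G", g$tier3)
      up <- g$tier3 < 3 & hg > thr
      res$grade_label <- ifelse(up, "G3", base)
      res$base_grade <- ifelse(up, base, NA_character_)
      res$upgraded <- up
      res$high_grade_pct <- hg
    } else if (sys == "FOUR_TIER") {
      res$grade_label <- paste0("G", g$tier4)
    } else { # PROG_SCORE
      tcol <- if (cfg$tiers == 3) "tier3" else "tier4"
      d <- codebook[[tcol]][match(g$dominant, codebook$name)]
      s <- codebook[[tcol]][match(g$secondary, codebook$name)]
      score <- d + s
      res$score <- as.integer(score)
      if (cfg$tiers == 3) {
        sub <- rep(NA_character_, n)
        sub[d == 1 & s == 2] <- "3a"
        sub[d == 2 & s == 1] <- "3b"
        res$score_sublabel <- sub
        lab <- rep(NA_character_, n)
        lab[score == 2] <- "PG0"
        lab[score == 3 & sub == "3a"] <- "PG1"
        lab[score == 3 & sub == "3b"] <- "PG2"
        lab[score == 4] <- "PG3"
        lab[score == 5] <- "PG4"
        lab[score == 6] <- "PG5"
        res$grade_label <- lab
      } else {
        res$grade_label <- paste0("S", score)
      }
    }
    res
  })
  do.call(rbind, out)
}

#' High-grade threshold sweep with survival read-out
#'
#' Systematic evaluation of upgrade cut-offs: for each threshold, all cases
#' are re-graded under the chosen threshold-based system, and the resulting
#' stratification is scored against survival (k-sample log-rank and
#' concordance index of the grade used as an ordinal predictor). Threshold
#' 100 makes the upgrade impossible, so the grading degenerates to WHO;
#' threshold 0 upgrades every G1/G2 case with any high-grade abundance.
#'
#' @param comps list of `case_composition`s or percentage matrix.
#' @param records survival data.frame (see [read_survival_table()]): columns
#'   `case_id`, `time`, `event` (already filtered to one endpoint), in the
#'   same case order or matched by `case_id`.
#' @param thresholds numeric vector of thresholds in \[0, 100\].
#' @param system one of "IASLC", "IASLC_SIMPLIFIED".
#' @param codebook,cfg see [grade_cases()].
#' @return data.frame with one row per threshold: group sizes (`n_G1`,
#'   `n_G2`, `n_G3`), `n_upgraded`, `logrank_chisq`, `logrank_df`,
#'   `logrank_p`, `concordance`.
#' @export
sweep_thresholds <- function(comps, records, thresholds = seq(0, 100, 10),
                             system = c("IASLC", "IASLC_SIMPLIFIED"),
                             codebook = pattern_codebook(),
                             cfg = grading_config()) {
  system <- match.arg(system)
  stopifnot(all(thresholds >= 0 & thresholds <= 100))
  pct <- .pct_matrix(comps)
  ids <- rownames(pct)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(pct)))
  i <- match(ids, as.character(records$case_id))
  if (anyNA(i) || anyNA(records$time[i]) || anyNA(records$event[i]))
    stop("endpoint missing for cases: ",
         paste(ids[is.na(i) | is.na(records$time[i]) |
                     is.na(records$event[i])], collapse = ", "))
  time <- records$time[i]; event <- records$event[i]
  rows <- lapply(thresholds, function(thr) {
    cfg$high_grade_threshold_pct <- thr
    gr <- grade_cases(pct, system, codebook, cfg)
    num <- as.integer(sub("G", "", gr$grade_label))
    tab <- table(factor(gr$grade_label, levels = c("G1", "G2", "G3")))
    lr <- c(chisq = NA_real_, df = NA_real_, p = NA_real_)
    if (length(unique(num)) >= 2) {
      sd <- survival::survdiff(survival::Surv(time, event) ~ num)
      df <- length(sd$n) - 1
      lr <- c(chisq = unname(sd$chisq), df = df,
              p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
    }
    cidx <- survival::concordance(survival::Surv(time, event) ~ num,
                                  reverse = TRUE)$concordance
    data.frame(threshold = thr, n_G1 = unname(tab["G1"]),
               n_G2 = unname(tab["G2"]), n_G3 = unname(tab["G3"]),
               n_upgraded = sum(gr$upgraded),
               logrank_chisq = lr["chisq"], logrank_df = lr["df"],
               logrank_p = lr["p"], concordance = cidx,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
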