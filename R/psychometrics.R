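# Psychometric evaluation: reliability (split-half, test-retest), validity
# correlations, and the rank-score composition that produces the dependent
# variables for the robust comparisons.

.PROPERTIES <- c("reliability_splithalf", "reliability_retest",
                 "validity_direct", "validity_indirect",
                 "validity_predictive")
.VALIDITY_PROPERTIES <- c("validity_direct", "validity_indirect",
                          "validity_predictive")

#' Split-half reliability of one scoring algorithm
#'
#' Splits each subject's trials odd/even by within-block presentation order
#' (block = pairing x phase), scores each half with the complete pipeline,
#' correlates the halves across subjects (Pearson), and applies the
#' Spearman-Brown correction 2r/(1+r), clamped to [-1, 1].
#'
#' @param table An `iat_trials` table.
#' @param spec An [algorithm_spec()].
#' @param session Session to use (default 1).
#' @return The corrected coefficient, or `NA` if fewer than 3 subjects have
#'   scores on both halves.
#' @export
split_half_reliability <- function(table, spec, session = 1L) {
  stopifnot(inherits(table, "iat_trials"))
  df <- as.data.frame(table)
  df <- df[df$session == session, , drop = FALSE]
  if (nrow(df) == 0L) return(NA_real_)
  block <- interaction(df$subject, df$pairing, df$phase, drop = TRUE)
  within_ord <- stats::ave(seq_len(nrow(df)), block, FUN = seq_along)
  odd <- within_ord %% 2L == 1L

  half_scores <- function(sel) {
    sub <- df[sel, , drop = FALSE]
    subjects <- unique(df$subject)
    out <- rep(NA_real_, length(subjects))
    names(out) <- subjects
    for (s in intersect(subjects, unique(sub$subject))) {
      out[s] <- score_subject(sub[sub$subject == s, , drop = FALSE], spec)$value
    }
    out
  }
  h1 <- half_scores(odd)
  h2 <- half_scores(!odd)
  ok <- is.finite(h1) & is.finite(h2)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(h1[ok]) == 0 || stats::sd(h2[ok]) == 0) return(NA_real_)
  r <- stats::cor(h1[ok], h2[ok])
  sb <- 2 * r / (1 + r)
  max(min(sb, 1), -1)
}

#' Test-retest correlation
#'
#' Pearson correlation between two sessions' scores over complete pairs.
#'
#' @param scores1,scores2 Named numeric vectors (names = subject ids) or
#'   unnamed vectors of equal length.
#' @return Pearson r, or `NA` with fewer than 3 complete pairs.
#' @export
test_retest <- function(scores1, scores2) {
  if (!is.null(names(scores1)) && !is.null(names(scores2))) {
    common <- intersect(names(scores1), names(scores2))
    scores1 <- scores1[common]; scores2 <- scores2[common]
  }
  stopifnot(length(scores1) == length(scores2))
  ok <- is.finite(scores1) & is.finite(scores2)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(scores1[ok]) == 0 || stats::sd(scores2[ok]) == 0) {
    return(NA_real_)
  }
  stats::cor(scores1[ok], scores2[ok])
}

#' Validity correlations of each algorithm with each criterion measure
#'
#' Pearson correlations (pairwise deletion) between every algorithm's scores
#' and every criterion measure in the panel, tagged with the measure's
#' property (`validity_direct`, `validity_indirect`, `validity_predictive`).
#' Criteria are assumed pre-oriented so that higher = stronger
#' target-consistent preference, hence higher correlations are better.
#'
#' @param scores An `iat_scores` table from [score_table()].
#' @param panel An [iat_criteria()] panel.
#' @return A data.frame (indicator table rows) with columns `algorithm`,
#'   `indicator`, `property`, `value`, `n`.
#' @export
validity_correlations <- function(scores, panel) {
  stopifnot(inherits(scores, "iat_scores"), inherits(panel, "iat_criteria"))
  roles <- attr(panel, "roles")
  measures <- names(roles)
  algs <- setdiff(names(scores), "subject")
  pan <- as.data.frame(panel)
  idx <- match(scores$subject, pan$subject)
  rows <- list()
  for (a in algs) {
    sc <- scores[[a]]
    for (m in measures) {
      cv <- pan[[m]][idx]
      ok <- is.finite(sc) & is.finite(cv)
      n <- sum(ok)
      val <- if (n >= 3L && stats::sd(sc[ok]) > 0 && stats::sd(cv[ok]) > 0) {
        stats::cor(sc[ok], cv[ok])
      } else NA_real_
      prop <- switch(roles[[m]], direct = "validity_direct",
                     indirect = "validity_indirect",
                     behavioral = "validity_predictive")
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = a, indicator = m, property = prop,
        value = val, n = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Assemble reliability indicator rows
#'
#' Computes split-half reliability (and test-retest when the table has two
#' or more sessions) for each algorithm, in the same indicator-table layout
#' as [validity_correlations()].
#'
#' @param table An `iat_trials` table.
#' @param specs List of [algorithm_spec()] objects.
#' @return Indicator-table rows (`algorithm`, `indicator`, `property`,
#'   `value`, `n`).
#' @export
reliability_indicators <- function(table, specs) {
  if (inherits(specs, "iat_algorithm")) specs <- list(specs)
  sessions <- sort(unique(as.data.frame(table)$session))
  rows <- list()
  for (sp in specs) {
    id <- spec_id(sp)
    sh <- split_half_reliability(table, sp, session = sessions[1])
    rows[[length(rows) + 1L]] <- data.frame(
      algorithm = id, indicator = "splithalf_oddeven",
      property = "reliability_splithalf", value = sh, n = NA_integer_,
      stringsAsFactors = FALSE)
    if (length(sessions) >= 2L) {
      s1 <- score_table(table, sp, session = sessions[1])
      s2 <- score_table(table, sp, session = sessions[2])
      v1 <- stats::setNames(s1[[id]], s1$subject)
      v2 <- stats::setNames(s2[[id]], s2$subject)
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = id, indicator = "retest_s1s2",
        property = "reliability_retest", value = test_retest(v1, v2),
        n = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Convert an indicator table to rank scores and composites
#'
#' Within each dataset and indicator, algorithms are ranked on the
#' indicator's value with midranks on ties, the highest rank corresponding
#' to the best performance. Ranks are averaged within each property; overall
#' validity is the unweighted mean of the three validity-property rank
#' scores (properties absent in a dataset are dropped from the mean), and
#' the reliability composite averages the available reliability properties.
#'
#' @param indicators A data.frame with columns `algorithm`, `indicator`,
#'   `property`, `value`, and optionally `dataset` (defaults to a single
#'   dataset).
#' @return A data.frame of class `iat_ranks`, one row per algorithm x
#'   dataset, with one column per property rank score plus `reliability`
#'   and `overall_validity` composites.
#' @export
rank_and_compose <- function(indicators) {
  stopifnot(all(c("algorithm", "indicator", "property", "value") %in%
                  names(indicators)))
  ind <- as.data.frame(indicators)
  if (!"dataset" %in% names(ind)) ind$dataset <- "dataset1"
  if (length(unique(ind$algorithm)) < 2L) {
    stop("rank scores need at least 2 algorithms", call. = FALSE)
  }
  out <- list()
  for (ds in unique(ind$dataset)) {
    sub <- ind[ind$dataset == ds, , drop = FALSE]
    algs <- sort(unique(sub$algorithm))
    # per-indicator midranks, higher value -> higher rank
    rank_cols <- list()
    for (ic in unique(sub$indicator)) {
      s2 <- sub[sub$indicator == ic, , drop = FALSE]
      v <- s2$value[match(algs, s2$algorithm)]
      if (all(is.na(v))) {
        warning("indicator '", ic, "' in dataset '", ds,
                "' is all-missing; excluded", call. = FALSE)
        next
      }
      rank_cols[[ic]] <- list(property = s2$property[1],
                              rank = rank(v, ties.method = "average",
                                          na.last = "keep"))
    }
    props <- vapply(rank_cols, `[[`, character(1), "property")
    prop_scores <- sapply(.PROPERTIES, function(p) {
      cols <- rank_cols[props == p]
      if (!length(cols)) return(rep(NA_real_, length(algs)))
      rowMeans(do.call(cbind, lapply(cols, `[[`, "rank")), na.rm = TRUE)
    })
    prop_scores[is.nan(prop_scores)] <- NA_real_
    reliability <- rowMeans(
      prop_scores[, c("reliability_splithalf", "reliability_retest"),
                  drop = FALSE], na.rm = TRUE)
    overall_validity <- rowMeans(
      prop_scores[, .VALIDITY_PROPERTIES, drop = FALSE], na.rm = TRUE)
    reliability[is.nan(reliability)] <- NA_real_
    overall_validity[is.nan(overall_validity)] <- NA_real_
    out[[ds]] <- data.frame(algorithm = algs, dataset = ds,
                            prop_scores, reliability = reliability,
                            overall_validity = overall_validity,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("iat_ranks", "data.frame")
  res
}
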