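# Parameter 3 (score formula), Parameter 4 (practice/test distinction),
# algorithm enumeration/deduplication, named presets, and the subject x
# algorithm score matrix.

.P1_CODES <- c("none", "fixed_trim", "fixed_winsor", "stat_trim",
               "stat_winsor", "stat_inverse_trim")
.P2_CODES <- c("ignore", "exclude", "recode_2sd", "separate", "recode_600")
.P3_CODES <- c("D", "G", "WPR", "MD", "MD_trim", "MD_winsor",
               "MD_inverse_trim")
.P4_CODES <- c("no_distinction", "distinction")

# latency options whose thresholds do not depend on the latency distribution;
# for these, ignore and separate are provably identical
.P1_DISTRIBUTION_FREE <- c("none", "fixed_trim", "fixed_winsor")

#' Define one scoring algorithm as a 4-tuple of option codes
#'
#' @param p1 Extreme-latency treatment: one of `"none"`, `"fixed_trim"`,
#'   `"fixed_winsor"`, `"stat_trim"`, `"stat_winsor"`, `"stat_inverse_trim"`.
#' @param p2 Error treatment: one of `"ignore"`, `"exclude"`, `"recode_2sd"`,
#'   `"separate"`, `"recode_600"`.
#' @param p3 Score formula: one of `"D"`, `"G"`, `"WPR"`, `"MD"`,
#'   `"MD_trim"`, `"MD_winsor"`, `"MD_inverse_trim"`.
#' @param p4 Practice/test pooling: `"no_distinction"` or `"distinction"`.
#' @param proportion Tail fraction for the statistical treatments and the
#'   mini-difference variants (default 0.10).
#' @return An object of class `iat_algorithm` with a canonical string id of
#'   the form `P1.x-P2.y-P3.z-P4.w`.
#' @export
#' @examples
#' algorithm_spec("fixed_trim", "ignore", "D", "distinction")  # the D2
algorithm_spec <- function(p1, p2, p3, p4, proportion = 0.10) {
  p1 <- match.arg(p1, .P1_CODES)
  p2 <- match.arg(p2, .P2_CODES)
  p3 <- match.arg(p3, .P3_CODES)
  p4 <- match.arg(p4, .P4_CODES)
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                 proportion = proportion),
            class = "iat_algorithm")
}

#' Canonical algorithm id
#'
#' @param spec An `iat_algorithm`.
#' @return String `"P1.x-P2.y-P3.z-P4.w"` where x..w are the 1-based option
#'   numbers within each parameter.
#' @export
spec_id <- function(spec) {
  stopifnot(inherits(spec, "iat_algorithm"))
  sprintf("P1.%d-P2.%d-P3.%d-P4.%d",
          match(spec$p1, .P1_CODES), match(spec$p2, .P2_CODES),
          match(spec$p3, .P3_CODES), match(spec$p4, .P4_CODES))
}

#' Parse a canonical algorithm id back into a spec
#'
#' @param id A string of the form `"P1.x-P2.y-P3.z-P4.w"`.
#' @return An `iat_algorithm`.
#' @export
parse_spec_id <- function(id) {
  m <- regmatches(id, regexec(
    "^P1\\.([1-6])-P2\\.([1-5])-P3\\.([1-7])-P4\\.([1-2])$", id))[[1]]
  if (length(m) != 5L) stop("malformed algorithm id: ", id, call. = FALSE)
  i <- as.integer(m[-1])
  algorithm_spec(.P1_CODES[i[1]], .P2_CODES[i[2]], .P3_CODES[i[3]],
                 .P4_CODES[i[4]])
}

#' @export
print.iat_algorithm <- function(x, ...) {
  cat(sprintf("<iat_algorithm> %s  [%s | %s | %s | %s]\n", spec_id(x),
              x$p1, x$p2, x$p3, x$p4))
  invisible(x)
}

#' @export
format.iat_algorithm <- function(x, ...) spec_id(x)

#' The D score
#'
#' Difference between the mean latencies of the two critical blocks divided
#' by the standard deviation of all latencies in both blocks (inclusive SD;
#' recoded error latencies are part of the pooled set). Positive scores mean
#' slower responding in the incompatible pairing.
#'
#' @param compatible,incompatible Treated latency vectors (ms), each with at
#'   least 2 values.
#' @return The score, or `NA` if the pooled SD is zero or a block is too
#'   small.
#' @export
#' @examples
#' score_d(c(600, 700), c(800, 900))
score_d <- function(compatible, incompatible) {
  if (length(compatible) < 2L || length(incompatible) < 2L) return(NA_real_)
  s <- stats::sd(c(compatible, incompatible))
  if (!is.finite(s) || s == 0) return(NA_real_)
  (mean(incompatible) - mean(compatible)) / s
}

#' The G score (Gaussian-rank latency difference)
#'
#' Pools both blocks, computes fractional ranks (rank - 0.5)/N with midranks
#' for ties, maps them through the standard-normal quantile function, and
#' returns the difference of the blocks' mean Gaussian ranks
#' (incompatible - compatible). Invariant under any strictly increasing
#' transform of the latencies.
#'
#' @inheritParams score_d
#' @return The score, or `NA` if either block is empty.
#' @export
score_g <- function(compatible, incompatible) {
  nc <- length(compatible); ni <- length(incompatible)
  if (nc < 1L || ni < 1L || nc + ni < 2L) return(NA_real_)
  pooled <- c(compatible, incompatible)
  fr <- (rank(pooled, ties.method = "average") - 0.5) / length(pooled)
  g <- stats::qnorm(fr)
  mean(g[seq.int(nc + 1L, nc + ni)]) - mean(g[seq_len(nc)])
}

#' The worst-performance-rule (WPR) score
#'
#' Difference between the 90th percentiles of the two critical blocks
#' divided by the SD of all latencies in both blocks. Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @inheritParams score_d
#' @param probs Upper quantile used (default 0.90).
#' @return The score, or `NA` if degenerate.
#' @export
score_wpr <- function(compatible, incompatible, probs = 0.90) {
  if (length(compatible) < 2L || length(incompatible) < 2L) return(NA_real_)
  s <- stats::sd(c(compatible, incompatible))
  if (!is.finite(s) || s == 0) return(NA_real_)
  (stats::quantile(incompatible, probs, names = FALSE, type = 7) -
     stats::quantile(compatible, probs, names = FALSE, type = 7)) / s
}

#' Mini-difference scores
#'
#' Forms all pairwise differences `incompatible_i - compatible_j` (60 trials
#' per block give 3600 difference indicators), optionally applies a
#' statistical treatment (10% trimming, winsorizing or inverse trimming,
#' reusing the Parameter-1 operators) to the difference distribution, and
#' returns the mean of the treated differences divided by their standard
#' deviation.
#'
#' @inheritParams score_d
#' @param variant One of `"plain"`, `"trim"`, `"winsor"`, `"inverse_trim"`.
#' @param proportion Tail fraction for the treated variants (default 0.10).
#' @return The score, or `NA` if fewer than 2 differences survive or their
#'   SD is zero.
#' @export
score_minidiff <- function(compatible, incompatible,
                           variant = c("plain", "trim", "winsor",
                                       "inverse_trim"),
                           proportion = 0.10) {
  variant <- match.arg(variant)
  if (length(compatible) < 1L || length(incompatible) < 1L) return(NA_real_)
  d <- as.vector(outer(incompatible, compatible, `-`))
  if (variant != "plain") {
    opt <- latency_option(switch(variant, trim = "stat_trim",
                                 winsor = "stat_winsor",
                                 inverse_trim = "stat_inverse_trim"),
                          proportion = proportion,
                          # bounds are irrelevant for the statistical codes but
                          # must satisfy the constructor; differences can be
                          # negative, which the statistical operators accept
                          lower_remove = 1, winsor_bounds = c(1, 2))
    d <- apply_latency_treatment(d, opt)$values
  }
  if (length(d) < 2L) return(NA_real_)
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) return(NA_real_)
  mean(d) / s
}

# formula dispatch on two treated blocks
.apply_formula <- function(compatible, incompatible, spec) {
  switch(spec$p3,
    D   = score_d(compatible, incompatible),
    G   = score_g(compatible, incompatible),
    WPR = score_wpr(compatible, incompatible),
    MD  = score_minidiff(compatible, incompatible, "plain"),
    MD_trim = score_minidiff(compatible, incompatible, "trim",
                             spec$proportion),
    MD_winsor = score_minidiff(compatible, incompatible, "winsor",
                               spec$proportion),
    MD_inverse_trim = score_minidiff(compatible, incompatible,
                                     "inverse_trim", spec$proportion))
}

# run pretreatment + formula on one pool of trials (one phase subset or all)
.score_pool <- function(latency, is_error, pairing, spec, l_opt, e_opt) {
  comp <- pairing == "compatible"
  tc <- treat_block(latency[comp], is_error[comp], e_opt, l_opt)
  ti <- treat_block(latency[!comp], is_error[!comp], e_opt, l_opt)
  # minimum-data rule: each block must retain >= 2 scored latencies
  if (length(tc$values) < 2L || length(ti$values) < 2L) {
    return(list(value = NA_real_,
                reason = if (tc$degenerate || ti$degenerate)
                  "degenerate_treatment" else "too_few_trials"))
  }
  v <- .apply_formula(tc$values, ti$values, spec)
  list(value = v,
       reason = if (is.na(v)) "zero_variance" else NA_character_)
}

#' Score one subject under one algorithm
#'
#' Runs the full pipeline (ceiling, Parameter 1 x 2 pretreatment per critical
#' block, Parameter 3 formula) on one subject's trials. Under
#' `no_distinction`, practice and test critical trials are pooled before
#' pretreatment; under `distinction`, the entire pipeline runs independently
#' on the practice and on the test subset and the final score is the
#' unweighted mean of the two phase scores (missing if either phase score is
#' missing).
#'
#' @param trials A data.frame (or `iat_trials` slice) with columns `pairing`,
#'   `phase`, `latency`, `error` for a single subject and session.
#' @param spec An [algorithm_spec()].
#' @return A list with `value` (score or `NA`) and `reason` (`NA` or a coded
#'   missing reason).
#' @export
score_subject <- function(trials, spec) {
  stopifnot(inherits(spec, "iat_algorithm"))
  l_opt <- latency_option(spec$p1, proportion = spec$proportion)
  e_opt <- error_option(spec$p2)
  lat <- as.numeric(trials$latency)
  err <- as.logical(trials$error)
  pai <- as.character(trials$pairing)
  if (!any(pai == "compatible") || !any(pai == "incompatible")) {
    return(list(value = NA_real_, reason = "missing_pairing"))
  }
  if (spec$p4 == "no_distinction") {
    return(.score_pool(lat, err, pai, spec, l_opt, e_opt))
  }
  pha <- as.character(trials$phase)
  parts <- lapply(.PHASES, function(ph) {
    sel <- pha == ph
    if (!any(sel)) return(list(value = NA_real_, reason = "missing_phase"))
    .score_pool(lat[sel], err[sel], pai[sel], spec, l_opt, e_opt)
  })
  vals <- vapply(parts, `[[`, numeric(1), "value")
  if (anyNA(vals)) {
    reason <- stats::na.omit(vapply(parts, `[[`, character(1), "reason"))[1]
    return(list(value = NA_real_, reason = reason))
  }
  list(value = mean(vals), reason = NA_character_)
}

#' Score every subject under a set of algorithms
#'
#' @param table An `iat_trials` table.
#' @param specs A single [algorithm_spec()] or a list of them.
#' @param session Which session to score (default 1).
#' @return A data.frame of class `iat_scores`: one row per subject, one
#'   column per canonical algorithm id, plus a `subject` column. Attribute
#'   `missing_reasons` holds a subject x algorithm character matrix of coded
#'   missing reasons (`NA` where the score is present).
#' @export
score_table <- function(table, specs, session = 1L) {
  stopifnot(inherits(table, "iat_trials"))
  if (inherits(specs, "iat_algorithm")) specs <- list(specs)
  ids <- vapply(specs, spec_id, character(1))
  df <- as.data.frame(table)
  df <- df[df$session == session, , drop = FALSE]
  if (nrow(df) == 0L) stop("no trials for session ", session, call. = FALSE)
  subjects <- unique(df$subject)
  slices <- split(df, factor(df$subject, levels = subjects))
  vals <- matrix(NA_real_, length(subjects), length(ids),
                 dimnames = list(subjects, ids))
  reasons <- matrix(NA_character_, length(subjects), length(ids),
                    dimnames = list(subjects, ids))
  for (i in seq_along(subjects)) {
    sl <- slices[[i]]
    for (j in seq_along(specs)) {
      r <- score_subject(sl, specs[[j]])
      vals[i, j] <- r$value
      reasons[i, j] <- r$reason
    }
  }
  out <- data.frame(subject = subjects, vals, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("iat_scores", "data.frame"),
            missing_reasons = reasons)
}

#' Write a score matrix (CSV + JSON bookkeeping sidecar)
#'
#' @param scores An `iat_scores` table from [score_table()].
#' @param path CSV output path; the sidecar with per-cell missing-reason
#'   codes is written to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "iat_scores"))
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  reasons <- attr(scores, "missing_reasons")
  cells <- which(!is.na(reasons), arr.ind = TRUE)
  missing_list <- lapply(seq_len(nrow(cells)), function(k) {
    list(subject = rownames(reasons)[cells[k, 1]],
         algorithm = colnames(reasons)[cells[k, 2]],
         reason = reasons[cells[k, 1], cells[k, 2]])
  })
  jsonlite::write_json(list(n_subjects = nrow(scores),
                            algorithms = setdiff(names(scores), "subject"),
                            missing = missing_list),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Enumerate the full algorithm family
#'
#' The full cross of the four parameters gives 6 x 5 x 7 x 2 = 420
#' algorithms. When the extreme-latency treatment does not depend on the
#' latency distribution (no treatment, fixed trimming, fixed winsorizing),
#' the ignore and separate error treatments are provably identical; with
#' `deduplicate = TRUE` each such separate spec is merged into its ignore
#' twin, leaving 378 unique algorithms.
#'
#' @param deduplicate Drop the separate-coded duplicates? Default `FALSE`.
#' @return A list of [algorithm_spec()] objects in deterministic
#'   (lexicographic-on-option-number) order.
#' @export
enumerate_algorithms <- function(deduplicate = FALSE) {
  grid <- expand.grid(p4 = .P4_CODES, p3 = .P3_CODES, p2 = .P2_CODES,
                      p1 = .P1_CODES, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("p1", "p2", "p3", "p4")]
  if (deduplicate) {
    dup <- grid$p2 == "separate" & grid$p1 %in% .P1_DISTRIBUTION_FREE
    grid <- grid[!dup, , drop = FALSE]
  }
  lapply(seq_len(nrow(grid)), function(i) {
    algorithm_spec(grid$p1[i], grid$p2[i], grid$p3[i], grid$p4[i])
  })
}

#' Named scoring presets
#'
#' The conventional D scores and their improved variants:
#' \describe{
#'   \item{`D2`}{fixed-value trimming, ignore errors, D formula,
#'     practice/test distinction (for built-in-penalty IATs).}
#'   \item{`D5`}{as D2 but errors recoded to correct mean + 2 SD.}
#'   \item{`D6`}{as D2 but errors recoded to correct mean + 600 ms.}
#'   \item{`G_standard`}{no latency treatment, ignore errors, G formula, no
#'     distinction.}
#'   \item{`D2_improved`, `D5_improved`, `D6_improved`}{the corresponding D
#'     preset with statistical winsorizing in place of fixed trimming and no
#'     practice/test distinction.}
#' }
#'
#' @param name Preset name.
#' @return An [algorithm_spec()].
#' @export
#' @examples
#' spec_id(preset("D2"))  # "P1.2-P2.1-P3.1-P4.2"
preset <- function(name) {
  presets <- list(
    D2 = c("fixed_trim", "ignore", "D", "distinction"),
    D5 = c("fixed_trim", "recode_2sd", "D", "distinction"),
    D6 = c("fixed_trim", "recode_600", "D", "distinction"),
    G_standard = c("none", "ignore", "G", "no_distinction"),
    D2_improved = c("stat_winsor", "ignore", "D", "no_distinction"),
    D5_improved = c("stat_winsor", "recode_2sd", "D", "no_distinction"),
    D6_improved = c("stat_winsor", "recode_600", "D", "no_distinction"))
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; valid names: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[name]]
  algorithm_spec(p[1], p[2], p[3], p[4])
}
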