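# Parameter 1 (extreme-latency treatment) and Parameter 2 (error treatment).
# All treatments operate within one critical block (one pairing, optionally one
# phase subset); the global 10 s ceiling is applied before either parameter.

#' Extreme-latency treatment option (Parameter 1)
#'
#' Describes one of the six ways of handling extreme latencies within a
#' critical block:
#' \describe{
#'   \item{`none`}{no treatment.}
#'   \item{`fixed_trim`}{eliminate latencies below 400 ms (the upper tail is
#'     handled by the unconditional 10 s ceiling).}
#'   \item{`fixed_winsor`}{recode latencies below 300 ms to 300 ms and above
#'     3000 ms to 3000 ms.}
#'   \item{`stat_trim`}{remove the `proportion` fastest and `proportion`
#'     slowest latencies (k = floor(proportion * n) per tail).}
#'   \item{`stat_winsor`}{replace those 2k tail values by the most extreme
#'     retained order statistics.}
#'   \item{`stat_inverse_trim`}{remove the k latencies immediately below and
#'     the k immediately above the median.}
#' }
#'
#' @param code One of `"none"`, `"fixed_trim"`, `"fixed_winsor"`,
#'   `"stat_trim"`, `"stat_winsor"`, `"stat_inverse_trim"`.
#' @param proportion Fraction removed/replaced per tail for the statistical
#'   options; default 0.10.
#' @param lower_remove Fixed trimming lower bound in ms (default 400).
#' @param winsor_bounds Fixed winsorizing bounds in ms (default c(300, 3000)).
#' @param ceiling Global latency ceiling in ms (default 10000); latencies
#'   above it are always discarded, for correct and error trials alike.
#' @return An object of class `latency_option`.
#' @export
#' @examples
#' latency_option("stat_winsor")
latency_option <- function(code = c("none", "fixed_trim", "fixed_winsor",
                                    "stat_trim", "stat_winsor",
                                    "stat_inverse_trim"),
                           proportion = 0.10,
                           lower_remove = 400,
                           winsor_bounds = c(300, 3000),
                           ceiling = 10000) {
  code <- match.arg(code)
  stopifnot(proportion >= 0, proportion < 0.5,
            lower_remove > 0, ceiling > 0,
            length(winsor_bounds) == 2L,
            all(winsor_bounds > 0), winsor_bounds[1] < winsor_bounds[2])
  structure(list(code = code, proportion = proportion,
                 lower_remove = lower_remove,
                 winsor_bounds = winsor_bounds, ceiling = ceiling),
            class = "latency_option")
}

#' Error-latency treatment option (Parameter 2)
#'
#' @param code One of:
#' \describe{
#'   \item{`ignore`}{no correct/error distinction; Parameter 1 applies to the
#'     pooled latencies.}
#'   \item{`exclude`}{error latencies are dropped; Parameter 1 applies to
#'     correct latencies only.}
#'   \item{`recode_2sd`}{each error latency is replaced by the block's treated
#'     correct-latency mean plus `penalty_sd` standard deviations.}
#'   \item{`separate`}{Parameter 1 is applied independently to the correct and
#'     the error subset; both are retained.}
#'   \item{`recode_600`}{each error latency is replaced by the treated correct
#'     mean plus `penalty_ms` (600 ms).}
#' }
#' @param penalty_ms Additive penalty for `recode_600`, in ms.
#' @param penalty_sd SD multiplier for `recode_2sd`.
#' @return An object of class `error_option`.
#' @export
error_option <- function(code = c("ignore", "exclude", "recode_2sd",
                                  "separate", "recode_600"),
                         penalty_ms = 600, penalty_sd = 2) {
  code <- match.arg(code)
  stopifnot(penalty_ms > 0, penalty_sd > 0)
  structure(list(code = code, penalty_ms = penalty_ms,
                 penalty_sd = penalty_sd),
            class = "error_option")
}

#' @export
print.latency_option <- function(x, ...) {
  cat("<latency_option>", x$code,
      if (startsWith(x$code, "stat")) sprintf("(p = %g per tail)", x$proportion),
      "\n")
  invisible(x)
}

#' @export
print.error_option <- function(x, ...) {
  cat("<error_option>", x$code, "\n")
  invisible(x)
}

# index positions (per tail) removed by statistical trimming on a sorted
# vector of length n
.stat_trim_k <- function(n, proportion) floor(proportion * n)

#' Apply an extreme-latency treatment to one block's latencies
#'
#' Applies a Parameter-1 option to a latency vector (ceiling removal is
#' assumed to have happened upstream; see [treat_block()]). Winsorizing
#' preserves the count exactly; trimming removes exactly `k = floor(p * n)`
#' values per tail.
#'
#' @param latencies Numeric vector of latencies in ms (may be empty).
#' @param option A [latency_option()].
#' @return A list with `values` (the treated latencies), and bookkeeping
#'   fields `n_input`, `n_treatment_removed`, `n_winsorized`, `degenerate`.
#' @export
#' @examples
#' apply_latency_treatment(c(250, 500, 3500), latency_option("fixed_winsor"))
apply_latency_treatment <- function(latencies, option) {
  stopifnot(inherits(option, "latency_option"))
  x <- as.numeric(latencies)
  n <- length(x)
  out <- list(values = x, n_input = n, n_treatment_removed = 0L,
              n_winsorized = 0L, degenerate = FALSE)
  if (n == 0L) return(out)

  switch(option$code,
    none = out,
    fixed_trim = {
      keep <- x >= option$lower_remove
      out$values <- x[keep]
      out$n_treatment_removed <- sum(!keep)
      out
    },
    fixed_winsor = {
      lo <- option$winsor_bounds[1]; hi <- option$winsor_bounds[2]
      out$n_winsorized <- sum(x < lo | x > hi)
      out$values <- pmin(pmax(x, lo), hi)
      out
    },
    stat_trim = {
      k <- .stat_trim_k(n, option$proportion)
      if (k == 0L) return(out)
      if (n <= 2L * k) {       # nothing retained
        out$values <- numeric(0)
        out$n_treatment_removed <- n
        out$degenerate <- TRUE
        return(out)
      }
      ord <- order(x)
      drop <- c(ord[seq_len(k)], ord[seq.int(n - k + 1L, n)])
      out$values <- x[-drop]
      out$n_treatment_removed <- 2L * k
      out
    },
    stat_winsor = {
      k <- .stat_trim_k(n, option$proportion)
      if (k == 0L) return(out)
      if (n <= 2L * k) {
        out$values <- numeric(0)
        out$n_treatment_removed <- n
        out$degenerate <- TRUE
        return(out)
      }
      xs <- sort(x)
      lo <- xs[k + 1L]; hi <- xs[n - k]
      out$n_winsorized <- sum(x < lo | x > hi)
      out$values <- pmin(pmax(x, lo), hi)
      out
    },
    stat_inverse_trim = {
      k <- .stat_trim_k(n, option$proportion)
      if (k == 0L) return(out)
      # central positions: for even n the two middle order statistics, for
      # odd n the positions flanking the (retained) median
      lower <- floor(n / 2)
      upper <- n + 1L - lower
      drop_idx <- c(seq.int(lower - k + 1L, lower),
                    seq.int(upper, upper + k - 1L))
      bad <- drop_idx < 1L | drop_idx > n
      if (any(bad)) {
        drop_idx <- unique(drop_idx[!bad])
        out$degenerate <- TRUE
      }
      ord <- order(x)          # stable: ties broken by input position
      out$values <- x[-ord[drop_idx]]
      out$n_treatment_removed <- length(drop_idx)
      out
    })
}

#' Ceiling filter: discard latencies above 10 s
#'
#' Applied unconditionally before any other treatment, to correct and error
#' trials alike.
#'
#' @param latencies Numeric latency vector (ms).
#' @param is_error Logical vector of the same length.
#' @param ceiling Cutoff in ms (default 10000).
#' @return List with `latency`, `is_error` (filtered) and `n_over_ceiling`.
#' @export
ceiling_filter <- function(latencies, is_error, ceiling = 10000) {
  stopifnot(length(latencies) == length(is_error))
  keep <- latencies <= ceiling
  list(latency = latencies[keep], is_error = is_error[keep],
       n_over_ceiling = sum(!keep))
}

#' Apply the error treatment composed with a latency treatment
#'
#' Implements the Parameter 1 x Parameter 2 composition for one critical
#' block. The ceiling must have been applied upstream (see [treat_block()]
#' for the full wrapper). For the recode options the replacement baseline is
#' the mean (and SD) of the \emph{treated} correct latencies; recoded values
#' are not re-subjected to the latency treatment.
#'
#' @param latencies Numeric latencies (ms), post-ceiling.
#' @param is_error Logical error flags, same length.
#' @param e_opt An [error_option()].
#' @param l_opt A [latency_option()].
#' @return List with `values` (scored latencies) and bookkeeping: `n_input`,
#'   `n_treatment_removed`, `n_winsorized`, `n_errors_excluded`,
#'   `n_errors_recoded`, `degenerate`, `reason`.
#' @export
apply_error_treatment <- function(latencies, is_error, e_opt, l_opt) {
  stopifnot(inherits(e_opt, "error_option"), inherits(l_opt, "latency_option"),
            length(latencies) == length(is_error))
  is_error <- as.logical(is_error)
  n <- length(latencies)
  book <- list(n_input = n, n_treatment_removed = 0L, n_winsorized = 0L,
               n_errors_excluded = 0L, n_errors_recoded = 0L,
               degenerate = FALSE, reason = NA_character_)

  finish <- function(values, ...) {
    upd <- list(...)
    book[names(upd)] <- upd
    c(list(values = values), book)
  }

  switch(e_opt$code,
    ignore = {
      t <- apply_latency_treatment(latencies, l_opt)
      finish(t$values, n_treatment_removed = t$n_treatment_removed,
             n_winsorized = t$n_winsorized, degenerate = t$degenerate)
    },
    exclude = {
      t <- apply_latency_treatment(latencies[!is_error], l_opt)
      finish(t$values, n_treatment_removed = t$n_treatment_removed,
             n_winsorized = t$n_winsorized,
             n_errors_excluded = sum(is_error), degenerate = t$degenerate)
    },
    separate = {
      tc <- apply_latency_treatment(latencies[!is_error], l_opt)
      te <- apply_latency_treatment(latencies[is_error], l_opt)
      finish(c(tc$values, te$values),
             n_treatment_removed = tc$n_treatment_removed + te$n_treatment_removed,
             n_winsorized = tc$n_winsorized + te$n_winsorized,
             degenerate = tc$degenerate || te$degenerate)
    },
    recode_2sd = ,
    recode_600 = {
      tc <- apply_latency_treatment(latencies[!is_error], l_opt)
      n_err <- sum(is_error)
      if (length(tc$values) < 2L) {
        return(finish(numeric(0),
                      n_treatment_removed = tc$n_treatment_removed,
                      degenerate = TRUE, reason = "recode_sd_unavailable"))
      }
      base <- if (e_opt$code == "recode_2sd") {
        mean(tc$values) + e_opt$penalty_sd * stats::sd(tc$values)
      } else {
        mean(tc$values) + e_opt$penalty_ms
      }
      finish(c(tc$values, rep(base, n_err)),
             n_treatment_removed = tc$n_treatment_removed,
             n_winsorized = tc$n_winsorized,
             n_errors_recoded = n_err, degenerate = tc$degenerate)
    })
}

#' Full pretreatment of one critical block
#'
#' Convenience wrapper: applies the 10 s ceiling, then the Parameter-2 /
#' Parameter-1 composition, and assembles the complete bookkeeping record.
#' The bookkeeping satisfies
#' `n_input = length(values) + n_over_ceiling + n_treatment_removed +
#' n_errors_excluded` for count-changing treatments.
#'
#' @inheritParams apply_error_treatment
#' @return As [apply_error_treatment()], plus `n_over_ceiling`.
#' @export
treat_block <- function(latencies, is_error, e_opt, l_opt) {
  n0 <- length(latencies)
  cf <- ceiling_filter(latencies, is_error, l_opt$ceiling)
  res <- apply_error_treatment(cf$latency, cf$is_error, e_opt, l_opt)
  res$n_input <- n0
  res$n_over_ceiling <- cf$n_over_ceiling
  res
}
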