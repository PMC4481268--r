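# Seeded generator of synthetic IAT sessions and criterion panels.
#
# Latencies follow an ex-Gaussian (Gaussian + exponential tail), the
# standard positively skewed reaction-time family. Each subject carries a
# latent preference theta ~ N(0, 1); the incompatible/compatible latency
# gap is delta_ms * theta, split +/- half across the two pairings, and the
# per-trial error probability moves with theta in the same direction, so
# errors carry preference signal. Optional contamination injects fast
# guesses and attention lapses; built-in mode adds a positive correction
# time to error latencies.

#' Configuration for the synthetic IAT generator
#'
#' Defaults emulate a classic 7-block IAT's critical blocks: 20 practice and
#' 40 test trials per pairing (60 trials per critical block).
#'
#' @param n_subjects Number of subjects.
#' @param trials_practice,trials_test Trials per pairing per phase
#'   (defaults 20 and 40).
#' @param mu,sigma,tau Ex-Gaussian parameters in ms (defaults 600/100/150).
#' @param subject_sd SD of the per-subject general-speed offset, ms
#'   (default 100).
#' @param delta_ms Latent-preference effect: the expected incompatible minus
#'   compatible latency gap per unit of theta, in ms (default 150), split
#'   +/- half across pairings.
#' @param error_base Baseline per-trial error probability (default 0.05).
#' @param error_beta Increment of the error probability per unit theta in
#'   the incompatible pairing (and decrement in the compatible one);
#'   default 0.04. Probabilities are clamped to [0.01, 0.5].
#' @param built_in Built-in penalty procedure? When `TRUE`, error latencies
#'   are the base latency plus a positive correction time.
#' @param correction_shift,correction_mean Correction-time distribution for
#'   built-in mode: `correction_shift + Exp(mean = correction_mean)` ms.
#' @param fast_rate,lapse_rate Contamination rates: fast guesses
#'   (uniform 100-300 ms) and lapses (uniform 3000-9500 ms); defaults
#'   0.02 and 0.01.
#' @param n_direct,n_indirect,n_behavioral Number of criterion measures per
#'   role.
#' @param loading_direct,loading_indirect,loading_behavioral Correlation of
#'   each criterion measure with theta (defaults 0.5, 0.35, 0.25); noise SD
#'   is `sqrt(1 - loading^2)` so measures are standardized.
#' @param sessions 1 or 2; with 2, session-2 theta is
#'   `retest_cor * theta + sqrt(1 - retest_cor^2) * new draw`.
#' @param retest_cor Latent session stability (default 0.8).
#' @param dataset_label Label carried into the trial table.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 100,
                         trials_practice = 20, trials_test = 40,
                         mu = 600, sigma = 100, tau = 150,
                         subject_sd = 100, delta_ms = 150,
                         error_base = 0.05, error_beta = 0.04,
                         built_in = FALSE,
                         correction_shift = 300, correction_mean = 300,
                         fast_rate = 0.02, lapse_rate = 0.01,
                         n_direct = 2, n_indirect = 2, n_behavioral = 1,
                         loading_direct = 0.5, loading_indirect = 0.35,
                         loading_behavioral = 0.25,
                         sessions = 1, retest_cor = 0.8,
                         dataset_label = "synthetic", seed = 1L) {
  stopifnot(n_subjects >= 1, trials_practice >= 1, trials_test >= 1,
            sigma >= 0, tau >= 0, subject_sd >= 0,
            sessions %in% 1:2)
  rates <- c(error_base, error_beta, fast_rate, lapse_rate)
  if (any(rates < 0) || any(rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (retest_cor < -1 || retest_cor > 1) {
    stop("retest_cor must lie in [-1, 1]", call. = FALSE)
  }
  loadings <- c(loading_direct, loading_indirect, loading_behavioral)
  if (any(abs(loadings) > 1)) stop("loadings must lie in [-1, 1]",
                                   call. = FALSE)
  structure(mget(names(formals())), class = "synth_config")
}

.rexgauss <- function(n, mu, sigma, tau) {
  mu + stats::rnorm(n, 0, sigma) + stats::rexp(n, rate = 1 / tau)
}

#' Generate one synthetic IAT dataset
#'
#' @param config A [synth_config()].
#' @return A list with `trials` (an `iat_trials` table, including a
#'   `session` column when `config$sessions == 2`), `criteria` (an
#'   [iat_criteria()] panel) and `theta` (the latent preferences, for
#'   recovery studies).
#' @export
#' @examples
#' d <- generate_iat(synth_config(n_subjects = 5, seed = 42))
#' table(d$trials$pairing, d$trials$phase) / 5
generate_iat <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  set.seed(cf$seed)
  subjects <- sprintf("S%03d", seq_len(cf$n_subjects))
  theta <- stats::rnorm(cf$n_subjects)
  offset <- stats::rnorm(cf$n_subjects, 0, cf$subject_sd)

  phase_n <- c(practice = cf$trials_practice, test = cf$trials_test)
  rows <- vector("list", cf$n_subjects * cf$sessions)
  k <- 0L
  for (i in seq_len(cf$n_subjects)) {
    for (s in seq_len(cf$sessions)) {
      th <- if (s == 1L) theta[i] else {
        cf$retest_cor * theta[i] +
          sqrt(1 - cf$retest_cor^2) * stats::rnorm(1)
      }
      for (pairing in c("compatible", "incompatible")) {
        dir <- if (pairing == "incompatible") 1 else -1
        shift <- dir * cf$delta_ms * th / 2
        for (phase in c("practice", "test")) {
          n <- phase_n[[phase]]
          lat <- .rexgauss(n, cf$mu + offset[i] + shift, cf$sigma, cf$tau)
          # contamination replaces the intended latency
          u <- stats::runif(n)
          fast <- u < cf$fast_rate
          lapse <- !fast & u < cf$fast_rate + cf$lapse_rate
          lat[fast] <- stats::runif(sum(fast), 100, 300)
          lat[lapse] <- stats::runif(sum(lapse), 3000, 9500)
          p_err <- pmin(pmax(cf$error_base + dir * cf$error_beta * th,
                             0.01), 0.5)
          err <- stats::runif(n) < p_err
          if (cf$built_in && any(err)) {
            lat[err] <- lat[err] + cf$correction_shift +
              stats::rexp(sum(err), rate = 1 / cf$correction_mean)
          }
          lat <- pmax(lat, 100)
          k <- k + 1L
          rows[[k]] <- data.frame(subject = subjects[i], session = s,
                                  pairing = pairing, phase = phase,
                                  latency = lat, error = err,
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  trials <- iat_trials(do.call(rbind, rows[seq_len(k)]),
                       built_in_penalty = cf$built_in,
                       dataset_label = cf$dataset_label)

  measure <- function(prefix, count, loading) {
    out <- list()
    for (j in seq_len(count)) {
      out[[paste0(prefix, j)]] <-
        loading * theta + sqrt(1 - loading^2) * stats::rnorm(cf$n_subjects)
    }
    out
  }
  meas <- c(measure("direct", cf$n_direct, cf$loading_direct),
            measure("indirect", cf$n_indirect, cf$loading_indirect),
            measure("behavior", cf$n_behavioral, cf$loading_behavioral))
  roles <- c(rep("direct", cf$n_direct), rep("indirect", cf$n_indirect),
             rep("behavioral", cf$n_behavioral))
  names(roles) <- names(meas)
  criteria <- iat_criteria(data.frame(subject = subjects, meas,
                                      stringsAsFactors = FALSE),
                           roles)
  list(trials = trials, criteria = criteria,
       theta = stats::setNames(theta, subjects))
}

#' Generate a multi-dataset design
#'
#' Emulates the 3 built-in + 3 no-built-in dataset structure used to form
#' algorithm x dataset analysis units for the rank-based comparisons.
#'
#' @param configs A list of [synth_config()] objects, or `NULL` to build the
#'   default 3 + 3 design from `base_config`.
#' @param base_config Template config used when `configs` is `NULL`.
#' @param seed Base seed; dataset d uses `seed + d`.
#' @return A named list of [generate_iat()] outputs; each element also
#'   carries `built_in` and `dataset` fields.
#' @export
generate_multidataset <- function(configs = NULL,
                                  base_config = synth_config(),
                                  seed = 1L) {
  if (is.null(configs)) {
    configs <- lapply(seq_len(6L), function(d) {
      cf <- base_config
      cf$built_in <- d <= 3L
      cf$sessions <- if (d <= 3L) 2L else 1L   # retest only with built-in
      cf$dataset_label <- sprintf("%s_%d",
                                  if (d <= 3L) "builtin" else "nobuiltin",
                                  d)
      cf$seed <- seed + d
      cf
    })
  }
  if (!length(configs)) stop("need at least one config", call. = FALSE)
  out <- lapply(configs, function(cf) {
    d <- generate_iat(cf)
    d$built_in <- cf$built_in
    d$dataset <- cf$dataset_label
    d
  })
  names(out) <- vapply(configs, function(cf) cf$dataset_label, character(1))
  out
}
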