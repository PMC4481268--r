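# In-code fixtures: tiny trial tables built programmatically.

# one subject, one session, arbitrary latencies per pairing x phase
make_subject_trials <- function(subject = "s1",
                                compatible_practice = c(600, 650),
                                compatible_test = c(600, 700),
                                incompatible_practice = c(800, 850),
                                incompatible_test = c(800, 900),
                                errors = FALSE, session = 1L) {
  blocks <- list(
    list("compatible", "practice", compatible_practice),
    list("compatible", "test", compatible_test),
    list("incompatible", "practice", incompatible_practice),
    list("incompatible", "test", incompatible_test))
  do.call(rbind, lapply(blocks, function(b) {
    n <- length(b[[3]])
    data.frame(subject = subject, session = session,
               pairing = b[[1]], phase = b[[2]], latency = b[[3]],
               error = if (length(errors) == 1L) rep(errors, n) else errors,
               stringsAsFactors = FALSE)
  }))
}

# random multi-subject table with errors, seeded
make_random_table <- function(n_subjects = 6, n_per_block = 15, seed = 1,
                              built_in = FALSE) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    for (pairing in c("compatible", "incompatible")) {
      for (phase in c("practice", "test")) {
        lat <- 300 + rexp(n_per_block, 1 / 300) + runif(n_per_block, 0, 400)
        err <- runif(n_per_block) < 0.12
        rows[[length(rows) + 1L]] <- data.frame(
          subject = paste0("s", i), session = 1L, pairing = pairing,
          phase = phase, latency = lat, error = err,
          stringsAsFactors = FALSE)
      }
    }
  }
  iat_trials(do.call(rbind, rows), built_in_penalty = built_in)
}
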