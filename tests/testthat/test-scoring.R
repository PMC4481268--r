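test_that("score formulas reproduce hand-computed oracles", {
  # D: 200 / sd(600,700,800,900) = 200 / 129.099...
  expect_equal(score_d(c(600, 700), c(800, 900)),
               200 / sd(c(600, 700, 800, 900)), tolerance = 1e-12)
  expect_equal(score_d(c(600, 700), c(800, 900)), 1.549193, tolerance = 1e-6)
  # G: fractional ranks .125/.375/.625/.875 -> Gaussian ranks
  g_expected <- mean(qnorm(c(.625, .875))) - mean(qnorm(c(.125, .375)))
  expect_equal(score_g(c(500, 600), c(700, 800)), g_expected,
               tolerance = 1e-12)
  expect_equal(score_g(c(500, 600), c(700, 800)), 1.4689, tolerance = 1e-4)
  # WPR numerator with interpolated (type 7) quantiles: 970 - 770 = 200
  comp <- c(500, 600, 700, 800); incomp <- c(700, 800, 900, 1000)
  expect_equal(score_wpr(comp, incomp) * sd(c(comp, incomp)), 200,
               tolerance = 1e-9)
  # mini differences: {100,200,200,300}, mean 200, sample SD 81.65
  expect_equal(score_minidiff(c(500, 600), c(700, 800)),
               200 / sd(c(100, 200, 200, 300)), tolerance = 1e-12)
  expect_equal(score_minidiff(c(500, 600), c(700, 800)), 2.449, tolerance = 1e-3)
})

test_that("formula invariances hold: symmetry, scaling, rank invariance", {
  set.seed(21)
  comp <- 400 + rexp(30, 1 / 300); incomp <- 450 + rexp(30, 1 / 300)
  # identical blocks score 0
  expect_equal(score_d(comp, comp), 0)
  expect_equal(score_g(comp, comp), 0)
  expect_equal(score_wpr(comp, comp), 0)
  # swapping pairing labels negates every formula
  expect_equal(score_d(incomp, comp), -score_d(comp, incomp))
  expect_equal(score_g(incomp, comp), -score_g(comp, incomp))
  expect_equal(score_wpr(incomp, comp), -score_wpr(comp, incomp))
  expect_equal(score_minidiff(incomp, comp), -score_minidiff(comp, incomp))
  # D and WPR invariant under positive affine transforms
  expect_equal(score_d(3 * comp + 50, 3 * incomp + 50),
               score_d(comp, incomp))
  expect_equal(score_wpr(3 * comp + 50, 3 * incomp + 50),
               score_wpr(comp, incomp))
  # G invariant under any strictly increasing transform
  f <- function(x) log(x)^3
  expect_equal(score_g(f(comp), f(incomp)), score_g(comp, incomp))
  # mini-diff variants invariant under positive affine transforms
  for (v in c("plain", "trim", "winsor", "inverse_trim")) {
    expect_equal(score_minidiff(2 * comp + 10, 2 * incomp + 10, v),
                 score_minidiff(comp, incomp, v), info = v)
  }
  # quantile shift-equivariance: +100 ms shifts the WPR numerator by 100
  s <- sd(c(comp, comp + 100))
  expect_equal(score_wpr(comp, comp + 100) * s, 100, tolerance = 1e-9)
})

test_that("plain mini-difference numerator equals the D numerator", {
  set.seed(22)
  comp <- 400 + rexp(40, 1 / 250); incomp <- 500 + rexp(40, 1 / 250)
  d <- as.vector(outer(incomp, comp, `-`))
  expect_equal(mean(d), mean(incomp) - mean(comp), tolerance = 1e-10)
  expect_equal(score_minidiff(comp, incomp) * sd(d),
               mean(incomp) - mean(comp), tolerance = 1e-10)
})

test_that("60-trial blocks yield 3600 mini differences", {
  comp <- seq_len(60) + 500; incomp <- seq_len(60) + 600
  expect_length(as.vector(outer(incomp, comp, `-`)), 3600)
})

test_that("the practice/test distinction averages the two phase scores", {
  df <- make_subject_trials(
    compatible_practice = c(600, 650), compatible_test = c(500, 700),
    incompatible_practice = c(800, 850), incompatible_test = c(900, 1100))
  spec_d <- algorithm_spec("none", "ignore", "D", "distinction")
  spec_n <- algorithm_spec("none", "ignore", "D", "no_distinction")
  prac <- score_d(c(600, 650), c(800, 850))
  test <- score_d(c(500, 700), c(900, 1100))
  expect_equal(score_subject(df, spec_d)$value, mean(c(prac, test)))
  # no_distinction pools all trials
  expect_equal(score_subject(df, spec_n)$value,
               score_d(c(600, 650, 500, 700), c(800, 850, 900, 1100)))
  # empty practice subset -> missing under distinction
  df_test_only <- df[df$phase == "test", ]
  r <- score_subject(df_test_only, spec_d)
  expect_true(is.na(r$value))
  expect_equal(r$reason, "missing_phase")
  expect_false(is.na(score_subject(df_test_only, spec_n)$value))
})

test_that("degenerate inputs yield coded missing scores", {
  df <- make_subject_trials(compatible_practice = c(700, 700),
                            compatible_test = c(700, 700),
                            incompatible_practice = c(700, 700),
                            incompatible_test = c(700, 700))
  r <- score_subject(df, algorithm_spec("none", "ignore", "D", "no_distinction"))
  expect_true(is.na(r$value))
  expect_equal(r$reason, "zero_variance")
  # too few trials after trimming
  small <- make_subject_trials(compatible_practice = c(600, 700),
                               compatible_test = 650,
                               incompatible_practice = c(800, 900),
                               incompatible_test = 850)
  r <- score_subject(small[small$phase == "test", , drop = FALSE],
                     algorithm_spec("none", "ignore", "D", "no_distinction"))
  expect_true(is.na(r$value))
  expect_equal(r$reason, "too_few_trials")
})

test_that("enumeration yields 420 specs, 378 after deduplication, in stable order", {
  full <- enumerate_algorithms(FALSE)
  uniq <- enumerate_algorithms(TRUE)
  expect_length(full, 420)
  expect_length(uniq, 378)
  ids_full <- vapply(full, spec_id, character(1))
  expect_equal(anyDuplicated(ids_full), 0L)
  expect_identical(ids_full, sort(ids_full))  # lexicographic on codes
  # dropped specs are exactly the separate twins of distribution-free options
  dropped <- setdiff(ids_full, vapply(uniq, spec_id, character(1)))
  expect_length(dropped, 42)
  expect_true(all(grepl("-P2\\.4-", dropped)))
  expect_true(all(grepl("^P1\\.[1-3]", dropped)))
})

test_that("merged duplicate pairs give bit-identical score columns", {
  tab <- make_random_table(n_subjects = 5, seed = 33)
  for (p1 in c("none", "fixed_trim", "fixed_winsor")) {
    s_ign <- score_table(tab, algorithm_spec(p1, "ignore", "G", "distinction"))
    s_sep <- score_table(tab, algorithm_spec(p1, "separate", "G", "distinction"))
    expect_identical(s_ign[[2]], s_sep[[2]], info = p1)
  }
  # distribution-dependent treatment may (and here does) differ
  s_ign <- score_table(tab, algorithm_spec("stat_trim", "ignore", "D",
                                           "no_distinction"))
  s_sep <- score_table(tab, algorithm_spec("stat_trim", "separate", "D",
                                           "no_distinction"))
  expect_false(identical(s_ign[[2]], s_sep[[2]]))
})

test_that("presets resolve to their documented option tuples", {
  expect_equal(spec_id(preset("D2")), "P1.2-P2.1-P3.1-P4.2")
  expect_equal(spec_id(preset("D5")), "P1.2-P2.3-P3.1-P4.2")
  expect_equal(spec_id(preset("D6")), "P1.2-P2.5-P3.1-P4.2")
  expect_equal(spec_id(preset("D2_improved")), "P1.5-P2.1-P3.1-P4.1")
  expect_equal(spec_id(preset("D5_improved")), "P1.5-P2.3-P3.1-P4.1")
  expect_equal(spec_id(preset("D6_improved")), "P1.5-P2.5-P3.1-P4.1")
  expect_error(preset("D9"), "valid names")
  # ids parse back to the same spec
  for (nm in c("D2", "D6", "G_standard")) {
    sp <- preset(nm)
    expect_equal(parse_spec_id(spec_id(sp))[1:4], sp[1:4])
  }
})

test_that("score tables carry missing reasons and serialize with a sidecar", {
  tab <- make_random_table(n_subjects = 4, n_per_block = 3, seed = 9)
  specs <- list(preset("D2"), preset("D6"))
  sc <- score_table(tab, specs)
  expect_s3_class(sc, "iat_scores")
  expect_equal(dim(attr(sc, "missing_reasons")), c(4L, 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores(sc, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$n_subjects, 4L)
})
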