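test_that("cell relative effects average to 0.5 with cell-size weights", {
  set.seed(30)
  for (rep in 1:5) {
    nA <- sample(2:4, 1); nB <- 2
    n_cell <- sample(5:20, nA * nB, replace = TRUE)
    # unbalanced design, cells in A-major order
    A <- unlist(mapply(rep, rep(seq_len(nA), each = nB), n_cell))
    B <- unlist(mapply(rep, rep(seq_len(nB), times = nA), n_cell))
    x <- rnorm(length(A), mean = A * 0.3)
    r <- bdm_two_way(x, A, B)
    rel <- attr(r, "relative_effects")
    w <- attr(r, "cell_n") / sum(attr(r, "cell_n"))
    expect_equal(sum(rel * w), 0.5, tolerance = 1e-12)
    expect_true(all(rel > 0 & rel < 1))
  }
})

test_that("the ATS detects a strong location shift and reports fractional dfs", {
  set.seed(31)
  x <- c(rnorm(100), rnorm(100, 3))
  A <- rep(1:2, each = 100); B <- rep(rep(1:2, each = 50), 2)
  r <- bdm_two_way(x, A, B)
  expect_lt(r$p[r$effect == "factorA"], 1e-6)
  expect_gt(r$p[r$effect == "interaction"], 0.01)
  expect_true(all(r$df1 > 0 & r$df2 > 0))
  expect_true(all(r$eta_p2 >= 0 & r$eta_p2 <= 1))
  # dfs need not be integers in general (3-level factor, unequal spread)
  set.seed(32)
  x3 <- c(rnorm(20, 0, 1), rnorm(25, 0, 3), rnorm(30, 0, 1),
          rnorm(22, 0, 2), rnorm(28, 0, 1), rnorm(24, 0, 4))
  A3 <- rep(1:3, times = c(45, 52, 52))
  B3 <- c(rep(1:2, times = c(20, 25)), rep(1:2, times = c(30, 22)),
          rep(1:2, times = c(28, 24)))
  r3 <- bdm_two_way(x3, A3, B3)
  # factorB spans one contrast, so its df1 is exactly 1; the 3-level factor
  # and the interaction get fractional Box-approximated df under
  # heteroscedasticity
  expect_equal(r3$df1[r3$effect == "factorB"], 1)
  frac <- r3$df1[r3$effect %in% c("factorA", "interaction")]
  expect_false(any(abs(frac - round(frac)) < 1e-8))
  expect_false(any(abs(r3$df2 - round(r3$df2)) < 1e-8))
})

test_that("the ATS is invariant under strictly increasing transforms", {
  set.seed(33)
  x <- rexp(80); A <- rep(1:2, each = 40); B <- rep(rep(1:2, each = 20), 2)
  r1 <- bdm_two_way(x, A, B)
  r2 <- bdm_two_way(log(x + 1)^2, A, B)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("balanced factor exchange swaps the main effects", {
  set.seed(34)
  x <- rnorm(80, rep(c(0, .5), each = 40))
  A <- rep(1:2, each = 40); B <- rep(rep(1:2, each = 20), 2)
  r1 <- bdm_two_way(x, A, B)
  r2 <- bdm_two_way(x, B, A)
  expect_equal(r1$statistic[r1$effect == "factorA"],
               r2$statistic[r2$effect == "factorB"], tolerance = 1e-10)
  expect_equal(r1$statistic[r1$effect == "interaction"],
               r2$statistic[r2$effect == "interaction"], tolerance = 1e-10)
})

test_that("empty or undersized cells are rejected by name", {
  x <- rnorm(30)
  A <- rep(1:2, each = 15)
  B <- c(rep(1, 15), rep(1, 14), 2)   # cell (1,2) empty, cell (2,2) size 1
  expect_error(bdm_two_way(x, A, B), "cell")
})

test_that("relative-effect contrasts: identity, separation, antisymmetry", {
  set.seed(35)
  x <- rnorm(40)
  g <- rep(c("a", "b"), each = 20)
  con <- tukey_relative_contrasts(c(x, x), rep(c("a", "b"), each = 40))
  expect_equal(con$effect, 0, tolerance = 1e-12)
  expect_false(con$significant)
  # complete separation at decent n: effect near the boundary, significant
  con2 <- tukey_relative_contrasts(c(rnorm(50), rnorm(50) + 100),
                                   rep(c("lo", "hi"), each = 50))
  expect_true(con2$significant)
  expect_equal(abs(con2$effect), 0.5, tolerance = 1e-9)
  expect_true(all(con2$ci_low <= con2$effect & con2$effect <= con2$ci_high))
  # a stochastic ordering produces a significant transitive chain
  set.seed(36)
  x3 <- c(rnorm(60), rnorm(60, 1.2), rnorm(60, 2.4))
  g3 <- rep(c("g1", "g2", "g3"), each = 60)
  con3 <- tukey_relative_contrasts(x3, g3)
  expect_true(all(con3$significant))
  rel <- attr(con3, "relative_effects")
  expect_true(rel["g1"] < rel["g2"] && rel["g2"] < rel["g3"])
  expect_error(tukey_relative_contrasts(rnorm(3), c("a", "a", "b")),
               "at least 2 observations")
})

test_that("Patel-Hoel: null, crossing interaction, and level-exchange antisymmetry", {
  set.seed(37)
  # same A ordering and magnitude at both B levels -> delta near 0
  x <- c(rnorm(40), rnorm(40, 1), rnorm(40), rnorm(40, 1))
  A <- rep(rep(1:2, each = 40), 2); B <- rep(1:2, each = 80)
  ph <- patel_hoel(x, A, B)
  expect_lt(abs(ph$delta), 0.25)
  expect_true(ph$ci_low <= 0 && ph$ci_high >= 0)
  # crossing interaction -> |delta| large, CI excludes 0
  xc <- c(rnorm(40), rnorm(40, 2), rnorm(40, 2), rnorm(40))
  phc <- patel_hoel(xc, A, B)
  expect_gt(abs(phc$delta), 0.5)
  expect_true(phc$ci_low > 0 || phc$ci_high < 0)
  # exchanging the two B levels negates delta
  ph_sw <- patel_hoel(xc, A, ifelse(B == 1, 2, 1))
  expect_equal(ph_sw$delta, -phc$delta, tolerance = 1e-12)
  expect_error(patel_hoel(rnorm(10), rep(1:2, 5), rep(1, 10)),
               "2 levels")
})

test_that("T-graphs drop transitively implied edges but keep reachability", {
  set.seed(38)
  x3 <- c(rnorm(80), rnorm(80, 1.5), rnorm(80, 3))
  g3 <- rep(c("X", "Y", "Z"), each = 80)
  con <- tukey_relative_contrasts(x3, g3)
  expect_true(all(con$significant))  # X < Y < Z stochastically
  tg <- build_tgraph(con)
  expect_equal(nrow(tg$edges_full), 3L)
  expect_equal(nrow(tg$edges), 2L)   # direct Z -> X edge omitted
  expect_setequal(paste(tg$edges$from, tg$edges$to),
                  c("Z Y", "Y X"))
  expect_equal(tgraph_reachability(tg), tgraph_reachability(tg, full = TRUE))
  # no significant contrasts -> edgeless graph
  set.seed(39)
  con0 <- tukey_relative_contrasts(rnorm(60), rep(c("a", "b", "c"), each = 20))
  tg0 <- build_tgraph(con0)
  expect_equal(nrow(tg0$edges), 0L)
  expect_length(tg0$nodes, 3L)
  # exports
  dot <- tgraph_dot(tg)
  expect_match(dot, "digraph")
  expect_match(dot, "\"Z\" -> \"Y\"", fixed = TRUE)
  js <- jsonlite::fromJSON(tgraph_json(tg))
  expect_equal(nrow(js$links), 2L)
})

test_that("a significance cycle is rejected", {
  fake <- data.frame(group_i = c("a", "b", "c"), group_j = c("b", "c", "a"),
                     effect = c(.2, .2, .2), se = .01,
                     ci_low = .1, ci_high = .3, p = 0, significant = TRUE)
  fake <- structure(fake, class = c("iat_contrasts", "data.frame"),
                    relative_effects = c(a = .5, b = .5, c = .5))
  expect_error(build_tgraph(fake), "cycle")
})
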