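test_that("uncorrected Pearson chi-square reproduces published statistics", {
  # arm-comparison counts printed with their statistics: 19/42 vs 14/45
  # (1.8), 20/42 vs 18/45 (0.5), 18/42 vs 14/45 (1.3), 5/14 vs 0/8 (3.7)
  expect_equal(round(chi_square_2x2(contingency_2x2(19, 23, 14, 31))$statistic,
                     1), 1.8)
  expect_equal(round(chi_square_2x2(contingency_2x2(20, 22, 18, 27))$statistic,
                     1), 0.5)
  expect_equal(round(chi_square_2x2(contingency_2x2(18, 24, 14, 31))$statistic,
                     1), 1.3)
  expect_equal(chi_square_2x2(contingency_2x2(5, 9, 0, 8))$statistic,
               3.70, tolerance = 0.005 / 3.70)
  expect_equal(chi_square_2x2(contingency_2x2(1, 1, 1, 1))$statistic, 0)
})

test_that("the continuity-corrected statistic is never produced", {
  # regression pinned to the published tables: Yates correction would give
  # different values, and must disagree with ours on every table
  tables <- list(c(19, 23, 14, 31), c(20, 22, 18, 27), c(18, 24, 14, 31),
                 c(5, 9, 0, 8))
  for (tb in tables) {
    ours <- chi_square_2x2(do.call(contingency_2x2, as.list(tb)))$statistic
    m <- matrix(tb, 2, byrow = TRUE)
    yates <- suppressWarnings(stats::chisq.test(m, correct = TRUE)$statistic)
    plain <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$statistic)
    expect_equal(ours, unname(plain), tolerance = 1e-12)
    expect_false(isTRUE(all.equal(ours, unname(yates), tolerance = 1e-3)))
  }
})

test_that("chi-square is symmetric and matches the reference on random tables", {
  set.seed(19)
  for (rep in 1:300) {
    tb <- stats::rpois(4, 10) + 1
    a <- tb[1]; b <- tb[2]; c <- tb[3]; d <- tb[4]
    ours <- chi_square_2x2(contingency_2x2(a, b, c, d))
    swapped_rows <- chi_square_2x2(contingency_2x2(c, d, a, b))
    swapped_cols <- chi_square_2x2(contingency_2x2(b, a, d, c))
    expect_equal(ours$statistic, swapped_rows$statistic, tolerance = 1e-12)
    expect_equal(ours$statistic, swapped_cols$statistic, tolerance = 1e-12)
    ref <- suppressWarnings(
      stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                        correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("chi-square rejects degenerate tables", {
  expect_error(chi_square_2x2(contingency_2x2(0, 0, 3, 4)), "margin")
  expect_error(chi_square_2x2(contingency_2x2(0, 3, 0, 4)), "margin")
  expect_error(contingency_2x2(-1, 1, 1, 1), "non-negative")
  expect_error(contingency_2x2(0, 0, 0, 0), "at least one")
})

test_that("Mann-Whitney U matches exact enumeration on small samples", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)

  r <- mann_whitney_u(5, c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.5, tolerance = 1e-12)

  # complete ties: U = n1 n2 / 2
  r <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$statistic, 9 / 2)

  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("U and its complement always sum to n1*n2", {
  set.seed(23)
  for (rep in 1:50) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    xs <- sample(1:5, n1, replace = TRUE)
    ys <- sample(1:5, n2, replace = TRUE)
    u_xy <- trialtalk:::u_statistic(xs, ys)
    u_yx <- trialtalk:::u_statistic(ys, xs)
    expect_equal(u_xy + u_yx, n1 * n2)
    expect_lte(mann_whitney_u(xs, ys)$statistic, n1 * n2 / 2)
  }
})

test_that("small samples use exact enumeration that matches the reference", {
  set.seed(29)
  for (n1 in 2:5) for (n2 in 2:5) {
    if (n1 + n2 < 4 || n1 + n2 > 10) next
    for (rep in 1:10) {
      vals <- sample(1:100, n1 + n2)  # tie-free
      xs <- vals[1:n1]; ys <- vals[-(1:n1)]
      r <- mann_whitney_u(xs, ys)
      # reference exact test (tie-free, small n -> wilcox.test is exact)
      w <- stats::wilcox.test(xs, ys)
      expect_equal(r$statistic,
                   min(unname(w$statistic),
                       n1 * n2 - unname(w$statistic)))
      expect_equal(r$p_value, w$p.value, tolerance = 1e-9)
    }
  }
})

test_that("the large-sample path matches the reference normal approximation", {
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(8:25, 1); n2 <- sample(8:25, 1)
    xs <- sample(1:7, n1, replace = TRUE)  # ordinal with ties
    ys <- sample(1:7, n2, replace = TRUE)
    r <- mann_whitney_u(xs, ys)
    w <- suppressWarnings(stats::wilcox.test(xs, ys, exact = FALSE,
                                             correct = TRUE))
    expect_equal(r$p_value, w$p.value, tolerance = 1e-9)
    expect_equal(r$statistic,
                 min(unname(w$statistic), n1 * n2 - unname(w$statistic)))
  }
})

test_that("outcome summaries tally arms exactly", {
  tb <- data.frame(
    arm = rep(c("agent", "control"), each = 10),
    completed = c(rep(TRUE, 10), rep(TRUE, 5), rep(FALSE, 5)),
    declared_found = rep(c(TRUE, FALSE), 10),
    found_correct = rep(FALSE, 20),
    rating_satisfaction = rep(c(5L, 3L), each = 10))
  s <- summarize_outcomes(tb)
  expect_identical(unname(s$n), c(10L, 10L))
  comp <- s$counts[s$counts$measure == "completed", ]
  expect_identical(comp$agent, "10 (100%)")
  expect_identical(comp$control, "5 (50%)")
  expect_equal(s$ratings$agent_mean, 5)
  expect_equal(s$ratings$agent_sd, 0)

  expect_error(summarize_outcomes(tb, arms = "agent"), "unknown arm")

  empty <- tb[0, ]
  s0 <- summarize_outcomes(empty, arms = c("agent", "control"))
  expect_true(all(s0$counts$agent_n == 0L))
  expect_true(all(is.na(s0$ratings$agent_mean)))
})

test_that("summaries agree with an independent recount of generated data", {
  tb <- generate_rct_outcomes(rct_config(seed = 31))
  s <- summarize_outcomes(tb)
  for (m in c("completed", "declared_found", "found_correct")) {
    row <- s$counts[s$counts$measure == m, ]
    for (a in c("agent", "control")) {
      manual <- 0L
      for (i in seq_len(nrow(tb)))
        if (tb$arm[i] == a && tb[[m]][i]) manual <- manual + 1L
      expect_identical(row[[paste0(a, "_n")]], manual)
    }
  }
  expect_equal(s$ratings$agent_mean,
               mean(tb$rating_satisfaction[tb$arm == "agent"]))
  expect_equal(s$ratings$control_sd,
               stats::sd(tb$rating_satisfaction[tb$arm == "control"]))
})
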