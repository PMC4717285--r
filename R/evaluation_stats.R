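#' A 2x2 contingency table of arm by binary outcome
#'
#' Rows are the two study arms, columns the yes/no outcome:
#' `a` = arm 1 yes, `b` = arm 1 no, `c` = arm 2 yes, `d` = arm 2 no.
#'
#' @param a,b,c,d Non-negative integer counts; total >= 1.
#' @return A `contingency_2x2`.
#' @examples
#' contingency_2x2(19, 23, 14, 31)  # declared-found counts, 42 vs 45
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1) stop("table must contain at least one count",
                            call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(as.list(counts), class = "contingency_2x2")
}

#' Uncorrected Pearson chi-square test on a 2x2 table
#'
#' The statistic is the classical Pearson form without continuity
#' correction,
#' \deqn{\chi^2 = \frac{n(ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)},}
#' with the p value from the chi-square distribution with 1 degree of
#' freedom. No Yates correction is applied: that is the convention under
#' which printed statistics for published 2x2 arm-comparison counts
#' reproduce exactly.
#'
#' @param table A `contingency_2x2`.
#' @return A `test_result`: list with `statistic`, `p_value`, `method`.
#' @examples
#' chi_square_2x2(contingency_2x2(19, 23, 14, 31))  # ~1.8
#' @export
chi_square_2x2 <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop("chi-square undefined: zero marginal total", call. = FALSE)
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / prod(as.numeric(margins))
  test_result(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
              "CHI_SQUARE_2x2")
}

test_result <- function(statistic, p_value, method) {
  structure(list(statistic = statistic, p_value = p_value, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  invisible(x)
}

## Mann-Whitney U of x over y via midranks (handles ties).
u_statistic <- function(xs, ys) {
  r <- rank(c(xs, ys))  # midranks
  n1 <- length(xs)
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

## Exact two-sided p by enumerating all choose(n, n1) group assignments of
## the pooled values (midranks make this valid under ties too).
mw_exact_p <- function(xs, ys) {
  pooled <- c(xs, ys)
  n <- length(pooled)
  n1 <- length(xs)
  u_obs <- u_statistic(xs, ys)
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, function(idx)
    u_statistic(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  p_low <- mean(us <= u_obs + eps)
  p_high <- mean(us >= u_obs - eps)
  min(1, 2 * min(p_low, p_high))
}

## Normal approximation with tie correction and a 0.5 continuity
## correction (the large-sample convention of the reference
## implementation).
mw_normal_p <- function(xs, ys, u) {
  n1 <- length(xs); n2 <- length(ys); n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(c(xs, ys))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)  # all values identical
  z <- u - mu
  z <- sign(z) * max(0, abs(z) - 0.5)
  2 * stats::pnorm(-abs(z) / sqrt(sigma2))
}

#' Mann-Whitney U test for two independent samples
#'
#' U counts, over all pairs, the times an `xs` value exceeds a `ys` value
#' (half for ties, via midranks); the reported statistic is the conventional
#' `min(U, n1*n2 - U)`. For small samples (`n1 + n2 <= 10`) the two-sided
#' p value is computed by exact enumeration of all group assignments of the
#' pooled values — at these sizes no normal approximation is adequate;
#' otherwise by the normal approximation with tie and continuity
#' corrections.
#'
#' @param xs,ys Non-empty numeric (or ordinal-coded) samples.
#' @return A `test_result` with the min-form U statistic and two-sided p.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(xs, ys) {
  if (length(xs) == 0 || length(ys) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  u <- u_statistic(xs, ys)
  u_min <- min(u, length(xs) * length(ys) - u)
  p <- if (length(xs) + length(ys) <= 10) mw_exact_p(xs, ys)
       else mw_normal_p(xs, ys, u)
  test_result(u_min, p, "MANN_WHITNEY_U")
}

#' Summarize a per-participant outcome table by arm
#'
#' Produces, per arm, the count and percentage of participants who completed
#' the task, declared they found a trial, and found a correct trial, plus
#' the mean and sample standard deviation (n-1 denominator) of every
#' `rating_*` column.
#'
#' @param table Data frame in the outcomes dialect of
#'   [generate_rct_outcomes()]: columns `arm`, `completed`,
#'   `declared_found`, `found_correct`, and zero or more `rating_*`.
#' @param arms Optional expected arm labels; an arm label in the table
#'   outside this set is an error.
#' @return An `outcome_summary`: list with `n` per arm, `counts` (data
#'   frame measure x arm of `k (pct%)` strings plus numeric columns) and
#'   `ratings` (data frame of means/SDs).
#' @export
summarize_outcomes <- function(table, arms = NULL) {
  needed <- c("arm", "completed", "declared_found", "found_correct")
  if (!all(needed %in% names(table)))
    stop("outcome table needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (is.null(arms)) arms <- unique(table$arm)
  unknown <- setdiff(unique(table$arm), arms)
  if (length(unknown))
    stop("unknown arm label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- vapply(arms, function(a) sum(table$arm == a), integer(1))
  count_measures <- c("completed", "declared_found", "found_correct")
  counts <- do.call(rbind, lapply(count_measures, function(m) {
    k <- vapply(arms, function(a) sum(table[[m]][table$arm == a]),
                integer(1))
    pct <- ifelse(n > 0, 100 * k / n, NA_real_)
    df <- data.frame(measure = m, stringsAsFactors = FALSE)
    for (a in arms) {
      df[[paste0(a, "_n")]] <- k[[a]]
      df[[paste0(a, "_pct")]] <- pct[[a]]
      df[[a]] <- if (n[[a]] > 0)
        sprintf("%d (%.0f%%)", k[[a]], pct[[a]]) else "0"
    }
    df
  }))
  rating_cols <- grep("^rating_", names(table), value = TRUE)
  ratings <- do.call(rbind, lapply(rating_cols, function(m) {
    df <- data.frame(measure = m, stringsAsFactors = FALSE)
    for (a in arms) {
      vals <- table[[m]][table$arm == a]
      df[[paste0(a, "_mean")]] <- if (length(vals)) mean(vals) else NA_real_
      df[[paste0(a, "_sd")]] <- if (length(vals) > 1) stats::sd(vals)
                                else NA_real_
    }
    df
  }))
  if (is.null(ratings))
    ratings <- data.frame(measure = character(0), stringsAsFactors = FALSE)
  structure(list(arms = arms, n = n, counts = counts, ratings = ratings),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("Per-arm n:", paste(sprintf("%s=%d", names(x$n), x$n),
                          collapse = ", "), "\n")
  print(x$counts[, c("measure", x$arms)], row.names = FALSE)
  if (nrow(x$ratings)) print(x$ratings, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Chi-square arm comparison for one binary outcome column
#'
#' Convenience wrapper: tallies the 2x2 table of `arms[1]` vs `arms[2]` for
#' the given outcome column and runs [chi_square_2x2()].
#'
#' @param table Outcomes data frame.
#' @param measure Name of a logical column.
#' @param arms Length-2 arm labels (default: order of appearance).
#' @return A `test_result`.
#' @export
compare_arms_chisq <- function(table, measure, arms = NULL) {
  if (is.null(arms)) arms <- unique(table$arm)
  stopifnot(length(arms) == 2)
  yes <- vapply(arms, function(a) sum(table[[measure]][table$arm == a]),
                integer(1))
  tot <- vapply(arms, function(a) sum(table$arm == a), integer(1))
  chi_square_2x2(contingency_2x2(yes[1], tot[1] - yes[1],
                                 yes[2], tot[2] - yes[2]))
}
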