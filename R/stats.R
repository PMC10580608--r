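#' Signed level-error table
#'
#' Per CHC domain, compares predicted against expert game levels: the count
#' of cases at or below the expert level (`difference <= 0`, the clinically
#' safe side), the count above it (`difference > 0`, the patient may start
#' beyond capability), and the percentage of positive errors.
#'
#' @param expert,predicted Data frames with one row per patient and the nine
#'   CHC level columns (integers 1-6), aligned row by row.
#' @return A tibble of class `chc_error_table` with columns `domain`,
#'   `n_le0`, `n_gt0`, `total`, `pct_gt0` (percent, 2 decimals).
#' @export
#' @examples
#' lv <- tibble::as_tibble(setNames(as.list(rep(3L, 9)), chc_domains()))
#' level_errors(lv, lv)
level_errors <- function(expert, predicted) {
  e <- level_matrix(expert)
  p <- level_matrix(predicted)
  if (!all(dim(e) == dim(p))) {
    abort("Expert and predicted level tables must have the same shape.",
      class = "chclevels_validation_error"
    )
  }
  d <- p - e
  out <- tibble(
    domain = chc_domains(),
    n_le0 = unname(colSums(d <= 0)),
    n_gt0 = unname(colSums(d > 0)),
    total = nrow(d)
  )
  out$pct_gt0 <- round(100 * out$n_gt0 / out$total, 2)
  structure(out, class = c("chc_error_table", class(tibble())))
}

#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA over two or more groups, returning the F
#' statistic and p-value. When every value is identical across all groups
#' the result is defined as `F = 0, p = 1` (no evidence of a difference
#' rather than an indeterminate 0/0).
#'
#' @param groups A list of two or more numeric vectors.
#' @return A tibble with columns `statistic` (F) and `p_value`.
#' @export
#' @examples
#' anova_oneway(list(rnorm(10), rnorm(10, 1)))
anova_oneway <- function(groups) {
  check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  if (all(values == values[1])) {
    return(tibble(statistic = 0, p_value = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  tibble(
    statistic = unname(ft$statistic),
    p_value = unname(ft$p.value)
  )
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction; the p-value comes from the
#' chi-square distribution with `k - 1` degrees of freedom. When the pooled
#' values are all identical the result is defined as `H = 0, p = 1`.
#'
#' @inheritParams anova_oneway
#' @return A tibble with columns `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  if (all(values == values[1])) {
    return(tibble(statistic = 0, p_value = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  tibble(
    statistic = unname(kt$statistic),
    p_value = unname(kt$p.value)
  )
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(lengths(groups) < 1) ||
      !all(vapply(groups, is.numeric, logical(1)))) {
    abort("Need a list of >= 2 nonempty numeric groups.",
      class = "chclevels_validation_error"
    )
  }
}

# Two-sided Bonferroni critical value for all k(k-1)/2 pairwise comparisons:
# the Student t quantile at 1 - alpha / (k (k - 1)) on the error df. Beyond
# the classically tabulated range (df > 120) the standard normal quantile is
# used, matching legacy multiple-comparison reports.
bonferroni_critical <- function(k, alpha, df_error) {
  p <- 1 - alpha / (k * (k - 1))
  if (df_error > 120) qnorm(p) else qt(p, df_error)
}

#' Bonferroni all-pairwise multiple comparison
#'
#' Report-style all-pairwise comparison of `k` group means after a one-way
#' ANOVA: pair `(i, j)` is declared different when
#' `|mean_i - mean_j| / sqrt(MSE (1/n_i + 1/n_j))` exceeds the two-sided
#' Bonferroni critical value (see Details). With zero mean-square error all
#' unequal-mean pairs are flagged and a warning is raised.
#'
#' @details The critical value is the Student t quantile at
#'   `1 - alpha / (k (k - 1))` with the ANOVA error degrees of freedom; for
#'   error df beyond the classical tabulated range (> 120) the limiting
#'   standard-normal quantile is used, matching the behaviour of legacy
#'   multiple-comparison software.
#'
#' @param data A data frame in long format.
#' @param value,group Column names (strings) holding the response values and
#'   the group labels.
#' @param alpha Familywise significance level (default 0.05).
#' @return A list of class `chc_pairwise` with `alpha`, `df_error`, `mse`,
#'   `critical_value`, `groups` (per-group count, mean and the groups each
#'   differs from) and `pairs` (every pair with its t statistic and flag).
#' @export
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b"), each = 5), y = c(1:5, 11:15))
#' bonferroni_pairwise(d, "y", "g")
bonferroni_pairwise <- function(data, value, group, alpha = 0.05) {
  data <- as_tibble(data)
  y <- data[[value]]
  g <- factor(data[[group]])
  k <- nlevels(g)
  if (k < 2) {
    abort("Need at least two groups.", class = "chclevels_validation_error")
  }
  n_i <- as.vector(table(g))
  m_i <- tapply(y, g, mean)
  df_error <- length(y) - k
  if (df_error < 1) {
    abort("Error degrees of freedom must be >= 1.",
      class = "chclevels_validation_error"
    )
  }
  sse <- sum((y - m_i[g])^2)
  mse <- sse / df_error
  crit <- bonferroni_critical(k, alpha, df_error)
  pairs <- utils::combn(seq_len(k), 2)
  se <- sqrt(mse * (1 / n_i[pairs[1, ]] + 1 / n_i[pairs[2, ]]))
  tstat <- abs(m_i[pairs[1, ]] - m_i[pairs[2, ]]) / se
  if (mse == 0) {
    warn("Zero mean-square error; flagging every pair with unequal means.")
    different <- m_i[pairs[1, ]] != m_i[pairs[2, ]]
  } else {
    different <- tstat > crit
  }
  pair_tbl <- tibble(
    group1 = levels(g)[pairs[1, ]], group2 = levels(g)[pairs[2, ]],
    statistic = unname(tstat), different = unname(different)
  )
  differs_from <- lapply(levels(g), function(gr) {
    with(pair_tbl, sort(unique(c(
      group2[different & group1 == gr], group1[different & group2 == gr]
    ))))
  })
  groups_tbl <- tibble(
    group = levels(g), count = n_i, mean = unname(m_i),
    differs_from = differs_from
  ) |>
    dplyr::arrange(.data$mean)
  structure(
    list(
      alpha = alpha, df_error = df_error, mse = mse, critical_value = crit,
      groups = groups_tbl, pairs = pair_tbl
    ),
    class = "chc_pairwise"
  )
}

#' @export
print.chc_pairwise <- function(x, ...) {
  cat("Bonferroni (All-Pairwise) Multiple Comparison Test\n")
  cat(sprintf(
    "Alpha = %.3f  Error DF = %d  MSE = %s  Critical Value = %.4f\n",
    x$alpha, x$df_error, format(x$mse, digits = 7), x$critical_value
  ))
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf(
      "%-6s n=%-5d mean=%-12.5g differs from: %s\n",
      g$group[i], g$count[i], g$mean[i],
      paste(g$differs_from[[i]], collapse = ", ")
    ))
  }
  invisible(x)
}

#' Compare predicted against expert levels
#'
#' The full comparison methodology: the signed level-error table plus a
#' per-domain statistical screen in which the expert and predicted level
#' sets are treated as two independent groups and compared by one-way ANOVA
#' and the Kruskal-Wallis test. A domain's verdict is `"REJECT"` when either
#' test is significant at the 5% level, otherwise `"ACCEPT"`.
#'
#' @inheritParams level_errors
#' @return A list of class `chc_comparison` with elements `error_table` (a
#'   [level_errors()] result) and `stat_report` (tibble per domain: expert
#'   and predicted mean levels, difference, both p-values, significance
#'   flags, verdict).
#' @export
#' @examples
#' coh <- simulate_cohort(n = 40, male = 20,
#'   education = c(10, 10, 10, 10), seed = 1)
#' pred <- recommend_levels(coh)
#' cmp <- compare_levels(coh, pred)
#' cmp$stat_report
compare_levels <- function(expert, predicted) {
  e <- level_matrix(expert)
  p <- level_matrix(predicted)
  if (!all(dim(e) == dim(p))) {
    abort("Expert and predicted level tables must have the same shape.",
      class = "chclevels_validation_error"
    )
  }
  stat_report <- purrr::map_dfr(chc_domains(), function(dom) {
    ge <- e[, dom]
    gp <- p[, dom]
    a <- anova_oneway(list(ge, gp))
    kw <- kruskal_wallis(list(ge, gp))
    tibble(
      domain = dom,
      expert_mean = mean(ge), predicted_mean = mean(gp),
      difference = mean(ge) - mean(gp),
      p_anova = a$p_value, p_kw = kw$p_value,
      signif_anova = a$p_value < 0.05, signif_kw = kw$p_value < 0.05,
      verdict = ifelse(a$p_value < 0.05 | kw$p_value < 0.05,
        "REJECT", "ACCEPT"
      )
    )
  })
  structure(
    list(error_table = level_errors(expert, predicted), stat_report = stat_report),
    class = "chc_comparison"
  )
}

#' @export
print.chc_comparison <- function(x, ...) {
  cat("Level comparison (predicted vs expert)\n\nError table:\n")
  print(as_tibble(x$error_table))
  cat("\nStatistical screen:\n")
  print(x$stat_report)
  invisible(x)
}

#' @method tidy chc_comparison
#' @export
tidy.chc_comparison <- function(x, ...) {
  dplyr::left_join(
    x$stat_report, as_tibble(x$error_table),
    by = "domain"
  )
}

#' @method glance chc_comparison
#' @export
glance.chc_comparison <- function(x, ...) {
  tibble(
    n = x$error_table$total[1],
    n_domains = nrow(x$stat_report),
    n_reject = sum(x$stat_report$verdict == "REJECT"),
    pct_gt0_overall = round(
      100 * sum(x$error_table$n_gt0) / sum(x$error_table$total), 2
    )
  )
}
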