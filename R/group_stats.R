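#' Group summary: mean +/- SEM over terminals
#'
#' Statistics are computed over individual terminals (`n_t`), the sampling
#' unit of the reference protocol; the number of animals is carried as
#' metadata only. Note this treats terminals within an animal as independent
#' (pseudo-replication), reproduced here deliberately to match the protocol.
#'
#' @param values per-terminal rates, %/min (non-empty).
#' @param group group label.
#' @param n_animals optional animal count (metadata).
#' @return a one-row data.frame: group, n_t, n_animals, mean, sem (sample SD
#'   over sqrt(n_t); 0 for a single value, which is flagged).
#' @export
group_summary <- function(values, group = "", n_animals = NA_integer_) {
  if (length(values) == 0L)
    stop_netrate("cannot summarise an empty group", "netrate_value_error")
  sem <- if (length(values) > 1L) sd(values) / sqrt(length(values)) else 0
  out <- data.frame(group = group, n_t = length(values),
                    n_animals = n_animals, mean = mean(values), sem = sem)
  if (length(values) == 1L) attr(out, "degenerate") <- TRUE
  out
}

# Lilliefors-corrected KS normality screen. The Kolmogorov-Smirnov test with
# parameters estimated from the sample requires n >= 5; smaller groups cannot
# reject normality and return NA (treated as "no evidence against").
normality_p <- function(x) {
  if (length(x) < 5L || sd(x) == 0) return(NA_real_)
  nortest::lillie.test(x)$p.value
}

#' Two-group comparison with protocol test selection
#'
#' Reproduces the reference decision rule: screen both groups for normality
#' with a Kolmogorov-Smirnov test (Lilliefors variant, since parameters are
#' estimated from the sample); if either group deviates (p < alpha) use the
#' Mann-Whitney test, otherwise test equality of variances with an F test and
#' use Welch's t-test if variances differ (p < alpha), else Student's
#' unpaired t-test. All tests are two-sided. The full decision trail is
#' returned.
#'
#' @param x,y per-terminal values for the two groups (each >= 3 values).
#' @param alpha significance level for the screening decisions (0.05).
#' @param labels length-2 character vector of group names.
#' @return an object of class `net_comparison`: `test_used` (one of
#'   `"student_t"`, `"welch_t"`, `"mann_whitney"`), `statistic`, `p_value`,
#'   `normality_p` (per group), `variance_p`, and per-group summaries.
#' @export
compare_two <- function(x, y, alpha = 0.05, labels = c("group1", "group2")) {
  if (length(x) < 3L || length(y) < 3L)
    stop_netrate("each group needs at least 3 values", "netrate_value_error")
  np <- c(normality_p(x), normality_p(y))
  non_normal <- any(!is.na(np) & np < alpha)
  vp <- NA_real_
  if (non_normal) {
    ht <- suppressWarnings(wilcox.test(x, y))
    used <- "mann_whitney"
  } else {
    vp <- var.test(x, y)$p.value
    if (vp < alpha) {
      ht <- t.test(x, y, var.equal = FALSE)
      used <- "welch_t"
    } else {
      ht <- t.test(x, y, var.equal = TRUE)
      used <- "student_t"
    }
  }
  structure(list(
    test_used = used, statistic = unname(ht$statistic),
    p_value = ht$p.value, normality_p = setNames(np, labels),
    variance_p = vp, alpha = alpha, labels = labels,
    summary = rbind(group_summary(x, labels[1]), group_summary(y, labels[2]))),
    class = "net_comparison")
}

#' @export
print.net_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s: %.1f +/- %.1f %%/min (n_t = %d) vs. %s: %.1f +/- %.1f %%/min (n_t = %d)\n",
              s$group[1], s$mean[1], s$sem[1], s$n_t[1],
              s$group[2], s$mean[2], s$sem[2], s$n_t[2]))
  cat(sprintf("  %s: statistic = %.4g, p %s\n", x$test_used, x$statistic,
              format_p(x$p_value)))
  cat(sprintf("  decision trail: normality p = %s; variance-equality p = %s\n",
              paste(signif(x$normality_p, 3), collapse = ", "),
              signif(x$variance_p, 3)))
  invisible(x)
}

format_p <- function(p) {
  if (is.na(p)) return("= NA")
  if (p < 1e-4) "< 0.0001"
  else if (p < 0.001) "< 0.001"
  else if (p < 0.01) "< 0.01"
  else if (p < 0.05) "< 0.05"
  else sprintf("= %.3g", p)
}

# Dunn's post-hoc z tests.
# Unpaired (after Kruskal-Wallis): pooled ranks, tie-corrected variance
#   z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))
#   with T = sum(t^3 - t) over tie groups.
# Paired (after Friedman): within-block rank sums,
#   z_ij = (R_i - R_j) / sqrt(n k (k+1) / 6).
# p-values are two-sided normal, Bonferroni-adjusted over the tested pairs.
dunn_posthoc <- function(groups, paired) {
  k <- length(groups)
  labels <- names(groups)
  pairs <- utils::combn(k, 2)
  if (paired) {
    y <- do.call(cbind, groups)
    rk <- t(apply(y, 1, rank))
    rs <- colSums(rk)
    n <- nrow(y)
    se <- sqrt(n * k * (k + 1) / 6)
    z <- (rs[pairs[1, ]] - rs[pairs[2, ]]) / se
  } else {
    all_v <- unlist(groups)
    rk <- rank(all_v)
    gi <- rep(seq_len(k), lengths(groups))
    rbar <- tapply(rk, gi, mean)
    n_i <- lengths(groups)
    N <- length(all_v)
    ties <- table(all_v)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    s2 <- N * (N + 1) / 12 - tie_term
    z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) /
      sqrt(s2 * (1 / n_i[pairs[1, ]] + 1 / n_i[pairs[2, ]]))
  }
  p_un <- 2 * pnorm(-abs(z))
  data.frame(group1 = labels[pairs[1, ]], group2 = labels[pairs[2, ]],
             z = as.numeric(z), p_unadjusted = as.numeric(p_un),
             p_adjusted = pmin(1, as.numeric(p_un) * ncol(pairs)),
             row.names = NULL)
}

#' Multi-group comparison: Friedman or Kruskal-Wallis with Dunn's post-hoc
#'
#' For paired designs (the same terminals measured under each condition, or
#' matched sets such as the four cardiac chambers of the same animals) the
#' omnibus test is Friedman's; for independent groups it is Kruskal-Wallis.
#' Dunn's multiple-comparison z tests on rank sums follow, with
#' Bonferroni-adjusted p-values over all tested pairs.
#'
#' @param groups named list of >= 3 numeric vectors; paired designs require
#'   equal lengths.
#' @param paired logical.
#' @param alpha significance level recorded in the result.
#' @return an object of class `net_multi_comparison`: `test_used`,
#'   `statistic`, `p_value` (omnibus), and `posthoc` (data.frame of pairwise
#'   Dunn results).
#' @export
compare_multi <- function(groups, paired = FALSE, alpha = 0.05) {
  if (length(groups) < 3L)
    stop_netrate("compare_multi needs at least 3 groups",
                 "netrate_value_error")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (paired && length(unique(lengths(groups))) != 1L)
    stop_netrate("paired comparison requires equal group lengths",
                 "netrate_value_error")
  if (paired) {
    y <- do.call(cbind, groups)
    om <- friedman.test(y)
    used <- "friedman_dunn"
  } else {
    om <- kruskal.test(groups)
    used <- "kruskal_dunn"
  }
  p_omni <- om$p.value
  if (is.nan(p_omni)) p_omni <- 1   # all values tied: no evidence at all
  structure(list(
    test_used = used, statistic = unname(om$statistic), p_value = p_omni,
    alpha = alpha,
    summary = do.call(rbind, Map(group_summary, groups, names(groups))),
    posthoc = dunn_posthoc(groups, paired)),
    class = "net_multi_comparison")
}

#' @export
print.net_multi_comparison <- function(x, ...) {
  cat(sprintf("%s omnibus: statistic = %.4g, p %s\n",
              x$test_used, x$statistic, format_p(x$p_value)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %.1f +/- %.1f %%/min (n_t = %d)\n",
                s$group[i], s$mean[i], s$sem[i], s$n_t[i]))
  cat("Dunn's multiple comparisons (Bonferroni-adjusted):\n")
  ph <- x$posthoc
  ph$z <- signif(ph$z, 4); ph$p_unadjusted <- signif(ph$p_unadjusted, 3)
  ph$p_adjusted <- signif(ph$p_adjusted, 3)
  print(ph, row.names = FALSE)
  invisible(x)
}
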