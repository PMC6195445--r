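#' Two-tailed unpaired Student's t-test
#'
#' Classical pooled-variance two-sample t-test (the textbook "Student's"
#' form; Welch's unequal-variance variant is available via
#' `var_equal = FALSE`). Degrees of freedom are `n_a + n_b - 2` and the
#' p-value is two-sided. When both samples are constant with equal means the
#' statistic is defined as 0 with p = 1.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param var_equal Pool the variance (classical Student's test, default) or
#'   use Welch's approximation.
#' @param metric,group_a,group_b Labels carried into the result.
#' @return A one-row data frame: `metric`, `group_a`, `group_b`,
#'   `statistic`, `df`, `p_value`, `n_a`, `n_b`.
#' @examples
#' ttest_unpaired(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
ttest_unpaired <- function(a, b, var_equal = TRUE, metric = "metric",
                           group_a = "a", group_b = "b") {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("insufficient data: each sample needs at least 2 finite values",
         call. = FALSE)
  }
  ht <- tryCatch(stats::t.test(a, b, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(ht)) {
    # essentially-constant data: zero pooled variance
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      stat <- 0; p <- 1
    } else {
      stat <- sign(mean(a) - mean(b)) * Inf; p <- 0
    }
    df <- length(a) + length(b) - 2
  } else {
    stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  }
  data.frame(metric = metric, group_a = group_a, group_b = group_b,
             statistic = stat, df = df, p_value = p,
             n_a = length(a), n_b = length(b))
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, p * m)`. Unlike [stats::p.adjust()], the family size `m` is given
#' explicitly rather than taken as `length(p)`, because per-lag MSD
#' comparisons adjust for the number of lags in the family regardless of how
#' many p-values are passed at once.
#'
#' @param p Raw p-value(s).
#' @param m Number of comparisons in the family (>= 1).
#' @return Adjusted p-value(s), capped at 1.
#' @export
bonferroni_adjust <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]",
                                             call. = FALSE)
  if (m < 1) stop("family size m must be >= 1", call. = FALSE)
  pmin(1, p * m)
}

#' Two-way ANOVA and per-lag comparisons of MSD curves
#'
#' Reproduces the usual MSD statistics: an overall two-way ANOVA with
#' factors group and lag (cells as replicates, interaction included), plus
#' per-lag between-group comparisons Bonferroni-adjusted for the number of
#' lags. With two groups the per-lag comparison is the pooled-variance
#' t-test; with more, a one-way ANOVA F-test.
#'
#' Cells are treated as independent replicates at each lag even though each
#' cell contributes to several lags (repeated measures); this matches the
#' conventional "two-way ANOVA with Bonferroni" analysis of MSD curves but
#' is anticonservative for the lag factor -- a caveat worth keeping in mind.
#' Lags missing from some group are dropped from the shared grid with a
#' warning (listwise deletion per lag; no imputation).
#'
#' @param per_cell Long table of per-cell MSD values with columns `cell_id`,
#'   `lag_min`, `msd_um2`, `group` — typically `rbind()` of
#'   [per_cell_msd_table()] outputs for the groups being compared.
#' @param m_rule Family size for the Bonferroni adjustment: `"lags"` (the
#'   default; m = number of shared lags) or `"lags_x_pairs"`
#'   (m = lags x group pairs).
#' @return List of class `msd_anova`: `overall` (data frame with the ANOVA
#'   table rows for group, lag and interaction), `per_lag` (data frame with
#'   `lag_min`, `statistic`, `df`, `p_value`, `adjusted_p`, per-group `n`),
#'   `m` (family size used).
#' @export
msd_anova <- function(per_cell, m_rule = c("lags", "lags_x_pairs")) {
  m_rule <- match.arg(m_rule)
  needed <- c("cell_id", "lag_min", "msd_um2", "group")
  if (!all(needed %in% names(per_cell))) {
    stop("per_cell table must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  groups <- unique(per_cell$group)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  per_group_n <- tapply(per_cell$cell_id, per_cell$group,
                        function(x) length(unique(x)))
  if (any(per_group_n < 2)) stop("need at least 2 cells per group",
                                 call. = FALSE)

  lag_sets <- lapply(split(per_cell$lag_min, per_cell$group), unique)
  shared <- Reduce(intersect, lag_sets)
  all_lags <- sort(unique(per_cell$lag_min))
  if (length(shared) < length(all_lags)) {
    warning("dropping ", length(all_lags) - length(shared),
            " lag(s) absent from at least one group", call. = FALSE)
  }
  dat <- per_cell[per_cell$lag_min %in% shared, ]
  dat$group <- factor(dat$group)
  dat$lag_f <- factor(dat$lag_min)

  fit <- stats::aov(msd_um2 ~ group * lag_f, data = dat)
  tab <- summary(fit)[[1]]
  term <- trimws(rownames(tab))
  overall <- data.frame(term = c("group", "lag", "group:lag"),
                        df = tab$Df[match(c("group", "lag_f", "group:lag_f"),
                                          term)],
                        statistic = tab$`F value`[
                          match(c("group", "lag_f", "group:lag_f"), term)],
                        p_value = tab$`Pr(>F)`[
                          match(c("group", "lag_f", "group:lag_f"), term)])

  lags <- sort(shared)
  n_pairs <- choose(length(groups), 2)
  m <- if (m_rule == "lags") length(lags) else length(lags) * n_pairs
  per_lag <- do.call(rbind, lapply(lags, function(l) {
    sub <- dat[dat$lag_min == l, ]
    if (length(groups) == 2) {
      gs <- levels(sub$group)
      r <- ttest_unpaired(sub$msd_um2[sub$group == gs[1]],
                          sub$msd_um2[sub$group == gs[2]],
                          metric = "msd", group_a = gs[1], group_b = gs[2])
      data.frame(lag_min = l, statistic = r$statistic, df = r$df,
                 p_value = r$p_value, n_a = r$n_a, n_b = r$n_b)
    } else {
      a1 <- stats::aov(msd_um2 ~ group, data = sub)
      s <- summary(a1)[[1]]
      data.frame(lag_min = l, statistic = s$`F value`[1], df = s$Df[1],
                 p_value = s$`Pr(>F)`[1], n_a = nrow(sub),
                 n_b = NA_integer_)
    }
  }))
  per_lag$adjusted_p <- bonferroni_adjust(per_lag$p_value, m)
  structure(list(overall = overall, per_lag = per_lag, m = m,
                 groups = as.character(groups)),
            class = "msd_anova")
}

#' @export
print.msd_anova <- function(x, digits = 4, ...) {
  cat("Two-way ANOVA of MSD (groups: ",
      paste(x$groups, collapse = ", "), ")\n\nOverall:\n", sep = "")
  print(format(x$overall, digits = digits), row.names = FALSE)
  cat("\nPer-lag comparisons (Bonferroni m = ", x$m, "):\n", sep = "")
  print(format(x$per_lag, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Empirical type-I error of the two-group comparison
#'
#' Simulation harness validating the statistical stack: repeatedly draws two
#' equal groups from a standard normal and records how often the unpaired
#' t-test rejects at level `alpha`. Under the null the rejection rate should
#' match `alpha` to binomial sampling error.
#'
#' @param alpha Significance level.
#' @param n_reps Number of null replicates (>= 100).
#' @param n_per_group Values per group in each replicate.
#' @param seed Integer seed (the rate is deterministic given it).
#' @return List with `rate`, the 95% binomial confidence interval `ci`, and
#'   `n_reps`.
#' @export
type1_error_suite <- function(alpha = 0.05, n_reps = 1000L,
                              n_per_group = 30L, seed = 1L) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (n_reps < 100) stop("n_reps must be >= 100", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  p <- vapply(seq_len(n_reps), function(i) {
    ttest_unpaired(stats::rnorm(n_per_group),
                   stats::rnorm(n_per_group))$p_value
  }, numeric(1))
  k <- sum(p < alpha)
  ci <- as.numeric(stats::binom.test(k, n_reps)$conf.int)
  list(rate = k / n_reps, ci = ci, n_reps = n_reps)
}
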