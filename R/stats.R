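# stats_tests module: group comparisons, Fisher's exact test with Bonferroni
# correction, odds ratios with Wald confidence intervals, and delta-delta-Ct
# relative expression.

#' Compare groups of per-implantation-site measurements
#'
#' Wraps the omnibus and pairwise tests used for implantation-site readouts:
#' one-way ANOVA with Tukey post-hoc, Welch's independent t-test (two
#' groups), pairwise Mann-Whitney U, Kruskal-Wallis with Dunn post-hoc, and
#' pairwise Kolmogorov-Smirnov. Pairwise p-values are Bonferroni-adjusted
#' over the number of pairs when `correction = "bonferroni"` (adjusted
#' `p = min(1, raw * m)`). Tukey intervals carry their own family-wise
#' adjustment and are reported as-is.
#'
#' @param samples named list: group label -> numeric vector of per-site
#'   measurements (each non-empty; at least two groups).
#' @param method one of `"anova_tukey"`, `"ttest"`, `"mannwhitney_pairwise"`,
#'   `"kruskal_dunn"`, `"ks_dunn"`.
#' @param correction `"bonferroni"` or `"none"` for the pairwise p-values.
#' @return A `group_test` report: method, omnibus statistic and p-value
#'   (where defined), pairwise table with raw and adjusted p-values, number
#'   of comparisons `m`, and per-group sizes.
#' @export
group_compare <- function(samples,
                          method = c("anova_tukey", "ttest",
                                     "mannwhitney_pairwise", "kruskal_dunn",
                                     "ks_dunn"),
                          correction = c("bonferroni", "none")) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  if (!is.list(samples) || is.null(names(samples)) || any(names(samples) == ""))
    stop("samples must be a named list of numeric vectors", call. = FALSE)
  if (length(samples) < 2L)
    stop("need at least two groups to compare", call. = FALSE)
  if (any(vapply(samples, length, integer(1)) < 2L))
    stop("each group needs n >= 2", call. = FALSE)
  groups <- names(samples)
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(groups, vapply(samples, length, integer(1))),
              levels = groups)
  pairs <- utils::combn(groups, 2)
  m <- ncol(pairs)
  adjust <- function(p) if (correction == "bonferroni") pmin(1, p * m) else p

  omnibus <- list(statistic = NA_real_, p = NA_real_, test = NA_character_)
  if (method == "anova_tukey") {
    if (any(vapply(samples, stats::sd, numeric(1)) == 0))
      stop("zero-variance group: parametric ANOVA undefined; use a ",
           "rank-based method (kruskal_dunn or mannwhitney_pairwise)",
           call. = FALSE)
    fit <- stats::aov(x ~ g)
    an <- summary(fit)[[1]]
    omnibus <- list(statistic = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                    test = "one-way ANOVA")
    tk <- stats::TukeyHSD(fit)$g
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
    key <- paste(pw$group2, pw$group1, sep = "-")
    key2 <- paste(pw$group1, pw$group2, sep = "-")
    row <- ifelse(key %in% rownames(tk), key, key2)
    pw$statistic <- tk[row, "diff"]
    pw$p_raw <- tk[row, "p adj"]
    pw$p_adj <- tk[row, "p adj"]   # Tukey is already family-wise
  } else if (method == "ttest") {
    if (length(samples) != 2L)
      stop("ttest requires exactly two groups", call. = FALSE)
    if (any(vapply(samples, stats::sd, numeric(1)) == 0))
      stop("zero-variance group: t-test undefined; use a rank-based method",
           call. = FALSE)
    tt <- stats::t.test(samples[[1]], samples[[2]])
    omnibus <- list(statistic = unname(tt$statistic), p = tt$p.value,
                    test = "Welch t-test")
    pw <- data.frame(group1 = groups[1], group2 = groups[2],
                     statistic = unname(tt$statistic), p_raw = tt$p.value,
                     p_adj = adjust(tt$p.value))
  } else if (method == "mannwhitney_pairwise") {
    pw <- .pairwise(samples, pairs, adjust, function(a, b) {
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                correct = TRUE))
      c(unname(wt$statistic), wt$p.value)
    })
  } else if (method == "kruskal_dunn") {
    kw <- stats::kruskal.test(x, g)
    omnibus <- list(statistic = unname(kw$statistic), p = kw$p.value,
                    test = "Kruskal-Wallis")
    dn <- .dunn_test(x, g)
    pw <- data.frame(group1 = dn$group1, group2 = dn$group2,
                     statistic = dn$z, p_raw = dn$p,
                     p_adj = adjust(dn$p))
  } else { # ks_dunn: pairwise Kolmogorov-Smirnov distances
    pw <- .pairwise(samples, pairs, adjust, function(a, b) {
      ks <- suppressWarnings(stats::ks.test(a, b))
      c(unname(ks$statistic), ks$p.value)
    })
  }
  structure(list(method = method, correction = correction, m = m,
                 n_per_group = vapply(samples, length, integer(1)),
                 omnibus = omnibus, pairwise = pw),
            class = "group_test")
}

.pairwise <- function(samples, pairs, adjust, fun) {
  res <- apply(pairs, 2, function(pr) fun(samples[[pr[1]]], samples[[pr[2]]]))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             statistic = res[1, ], p_raw = res[2, ],
             p_adj = adjust(res[2, ]))
}

# Dunn's rank-based post-hoc z tests with tie correction.
.dunn_test <- function(x, g) {
  N <- length(x)
  rk <- rank(x)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rk <- tapply(rk, g, mean)
  n_g <- tapply(rk, g, length)
  pairs <- utils::combn(levels(g), 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / n_g[pr[1]] + 1 / n_g[pr[2]]))
    (mean_rk[pr[1]] - mean_rk[pr[2]]) / se
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p = 2 * stats::pnorm(-abs(z)))
}

#' @export
print.group_test <- function(x, ...) {
  cat("Group comparison:", x$method, "(correction:", x$correction, ")\n")
  if (!is.na(x$omnibus$p))
    cat(sprintf("  omnibus %s: statistic %.4g, p = %.4g\n",
                x$omnibus$test, x$omnibus$statistic, x$omnibus$p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by full enumeration of the conditional
#' hypergeometric distribution over tables with the observed margins: the
#' p-value sums the probabilities of all tables no more probable than the
#' observed one (with the conventional 1 + 1e-7 relative guard against
#' floating-point ties), followed by a Bonferroni adjustment over
#' `correction_m` hypotheses.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param correction_m number of hypotheses in the family (default 1).
#' @return List with `p`, `p_adj = min(1, p * correction_m)`, the table and
#'   `m`.
#' @export
fisher_exact <- function(table, correction_m = 1) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("fisher_exact handles 2x2 tables only; got ",
         paste(dim(table), collapse = "x"), call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers", call. = FALSE)
  stopifnot(correction_m >= 1)
  a <- table[1, 1]
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1]); n <- sum(table)
  if (n == 0L) stop("table is empty", call. = FALSE)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[match(a, support)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  list(p = p, p_adj = min(1, p * correction_m), table = table,
       m = correction_m)
}

#' Odds ratio with 95% Wald confidence interval
#'
#' `OR = ad / bc` with a log-scale Wald interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Tables containing a
#' zero cell receive the Haldane-Anscombe continuity correction (0.5 added
#' to every cell), flagged in the output.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param conf_level confidence level (default 0.95).
#' @return List with `or`, `ci_low`, `ci_high`, `continuity_corrected`.
#' @export
odds_ratio_ci <- function(table, conf_level = 0.95) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("odds_ratio_ci handles 2x2 tables only", call. = FALSE)
  if (any(table < 0)) stop("table entries must be non-negative", call. = FALSE)
  corrected <- any(table == 0)
  tb <- if (corrected) table + 0.5 else table
  or <- (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])
  se <- sqrt(sum(1 / tb))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       conf_level = conf_level, continuity_corrected = corrected)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct_target - Ct_housekeeping`; `ddCt` subtracts the
#' arithmetic mean `dCt` of the reference group; relative expression is
#' `2^(-ddCt)`, so the reference group averages a fold change of 1 (its
#' geometric mean is exactly 1 by construction).
#'
#' @param cts data frame with columns `ct_target`, `ct_housekeeping`,
#'   `group` (and optionally `sample_id`).
#' @param reference name of the reference group.
#' @return The input with `dct`, `ddct` and `fold` columns appended.
#' @export
delta_delta_ct <- function(cts, reference = attr(cts, "reference")) {
  stopifnot(is.data.frame(cts),
            all(c("ct_target", "ct_housekeeping", "group") %in% names(cts)))
  if (is.null(reference) || !reference %in% cts$group)
    stop("reference group ", if (is.null(reference)) "(unset)" else
      paste0("'", reference, "'"), " not present in table", call. = FALSE)
  bad <- !is.finite(cts$ct_target) | !is.finite(cts$ct_housekeeping) |
    cts$ct_target <= 0 | cts$ct_housekeeping <= 0
  if (any(bad)) {
    who <- if ("sample_id" %in% names(cts)) cts$sample_id[bad] else which(bad)
    stop("missing or invalid Ct value(s) for sample(s): ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  out <- cts
  out$dct <- out$ct_target - out$ct_housekeeping
  ref_mean <- mean(out$dct[out$group == reference])
  out$ddct <- out$dct - ref_mean
  out$fold <- 2^(-out$ddct)
  attr(out, "reference") <- reference
  out
}
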