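#' Lilliefors-type normality check
#'
#' One-sample Kolmogorov-Smirnov test of composite normality: the KS
#' distance is computed against a normal with the sample's own mean and
#' standard deviation, and the p-value comes from a Monte-Carlo null
#' table (normal samples of the same size, same statistic) rather than
#' the classical KS distribution, which is badly anticonservative when
#' parameters are estimated.  The Monte-Carlo draw is internally seeded
#' by `n`, so the function is deterministic.
#'
#' @param sample Numeric vector, n >= 5.
#' @param nsim Monte-Carlo replicates for the null table.
#' @return List: `statistic` (KS D), `p`, `degenerate` (TRUE for a
#'   zero-variance sample, in which case `p` is `NA`).
#' @export
normality_check <- function(sample, nsim = 2000) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  if (n < 5) stop("need at least 5 observations")
  if (stats::sd(sample) == 0) {
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  d_obs <- lillie_stat(sample)
  null_d <- lillie_null_table(n, nsim)
  list(statistic = d_obs,
       p = (1 + sum(null_d >= d_obs)) / (nsim + 1),
       degenerate = FALSE)
}

# Monte-Carlo null table of the Lilliefors statistic, cached per (n, nsim);
# internally seeded by n, so the table (and hence the p-value) is a pure
# function of the sample
.lillie_cache <- new.env(parent = emptyenv())

lillie_null_table <- function(n, nsim) {
  key <- paste0(n, "_", nsim)
  if (is.null(.lillie_cache[[key]])) {
    .lillie_cache[[key]] <- withr::with_seed(10007L + n, {
      vapply(seq_len(nsim), function(i) lillie_stat(stats::rnorm(n)), 0)
    })
  }
  .lillie_cache[[key]]
}

# KS distance of a sample from N(mean(x), sd(x))
lillie_stat <- function(x) {
  n <- length(x)
  p <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Friedman omnibus test for a repeated-measures feature matrix
#'
#' Within-participant mid-ranks across the condition columns, then
#' `chi2 = 12 / (n k (k+1)) * sum(R_j^2) - 3 n (k+1)` with `R_j` the
#' column rank sums, referred to a chi-square with `k - 1` degrees of
#' freedom.  No tie correction is applied (mid-ranks only), matching the
#' plain form of the statistic.
#'
#' @param m Numeric matrix or data.frame, participants x conditions,
#'   k >= 3 columns, no missing cells.
#' @return List: `chi2`, `df`, `p`.
#' @examples
#' # perfectly consistent ordering over 10 participants, 4 conditions
#' m <- matrix(rep(1:4, each = 10), 10)
#' friedman_omnibus(m)$chi2  # 30
#' @export
friedman_omnibus <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2) stop("need at least 2 participants")
  if (k < 3) stop("need at least 3 conditions")
  if (any(!is.finite(m))) stop("missing cells are not allowed in the omnibus")
  ranks <- t(apply(m, 1, rank))
  rj <- colSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  list(chi2 = chi2, df = k - 1L,
       p = stats::pchisq(chi2, k - 1, lower.tail = FALSE))
}

#' Wilcoxon signed-rank post-hoc comparison
#'
#' Paired signed-rank test in the form used for the follow-up contrasts:
#' zero differences are dropped (Wilcoxon's original method), absolute
#' differences are mid-ranked, `T = min(W+, W-)`, and
#' `Z = (T - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` — the normal
#' approximation without continuity correction, the variant that yields
#' `Z = -2.80` when all 10 differences share a sign.  The two-sided p is
#' compared against a Bonferroni-adjusted level `alpha / family_size`.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param family_size Number of planned comparisons in the family
#'   (default 4, giving the 0.05/4 = 0.0125 adjusted level).
#' @param alpha Family-wise significance level.
#' @return List: `Z`, `p`, `n` (non-zero differences), `level`
#'   (adjusted per-comparison level), `significant`.
#' @examples
#' wilcoxon_posthoc(rep(0, 10), 1:10)  # all-positive differences: Z = -2.80
#' @export
wilcoxon_posthoc <- function(a, b, family_size = 4, alpha = 0.05) {
  stopifnot(length(a) == length(b))
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  if (n < 5) stop("need at least 5 non-zero differences")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  t_stat <- min(w_plus, w_minus)
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  z <- (t_stat - mu) / sigma
  p <- min(2 * stats::pnorm(z), 1)
  level <- alpha / family_size
  list(Z = z, p = p, n = n, level = level, significant = p < level)
}

#' Run the full statistical battery over cohort feature matrices
#'
#' For each feature matrix: a per-condition normality screen, the
#' Friedman omnibus, and the planned Wilcoxon post-hoc contrasts with
#' Bonferroni adjustment.  For the standard four-condition design the
#' planned family is baseline-vs-easy/medium/hard plus easy-vs-hard
#' (family size 4); for any other column set, all pairwise contrasts are
#' used with the family sized accordingly.
#'
#' @param features Named list of participants x conditions matrices (or
#'   data.frames), all sharing row order.
#' @param alpha Family-wise level (default 0.05).
#' @return An object of class `stats_report`: list of tidy data.frames
#'   `normality`, `omnibus`, `posthoc`.
#' @export
characterize <- function(features, alpha = 0.05) {
  stopifnot(is.list(features), length(names(features)) == length(features))
  standard <- c("baseline", "easy", "medium", "hard")
  norm_rows <- list()
  omni_rows <- list()
  post_rows <- list()
  for (feat in names(features)) {
    m <- as.matrix(features[[feat]])
    conds <- colnames(m)
    if (is.null(conds)) conds <- paste0("c", seq_len(ncol(m)))
    for (j in seq_len(ncol(m))) {
      nc <- normality_check(m[, j])
      norm_rows[[length(norm_rows) + 1L]] <- data.frame(
        feature = feat, condition = conds[j], ks_d = nc$statistic,
        p = nc$p, degenerate = nc$degenerate)
    }
    om <- friedman_omnibus(m)
    omni_rows[[length(omni_rows) + 1L]] <- data.frame(
      feature = feat, chi2 = om$chi2, df = om$df, p = om$p)
    if (identical(conds, standard)) {
      pairs <- list(c("baseline", "easy"), c("baseline", "medium"),
                    c("baseline", "hard"), c("easy", "hard"))
    } else {
      pairs <- utils::combn(conds, 2, simplify = FALSE)
    }
    for (pr in pairs) {
      wt <- wilcoxon_posthoc(m[, pr[1]], m[, pr[2]],
                             family_size = length(pairs), alpha = alpha)
      post_rows[[length(post_rows) + 1L]] <- data.frame(
        feature = feat, pair = paste(pr, collapse = " vs "),
        Z = wt$Z, p = wt$p, level = wt$level, significant = wt$significant)
    }
  }
  structure(list(normality = do.call(rbind, norm_rows),
                 omnibus = do.call(rbind, omni_rows),
                 posthoc = do.call(rbind, post_rows)),
            class = "stats_report")
}
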