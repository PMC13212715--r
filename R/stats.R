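#' Repeated-measures correlation
#'
#' Common within-subject linear association between two variables, estimated
#' by analysis of covariance with subject as a categorical factor and a
#' common slope. Equivalent to correlating the within-subject-centred data:
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))`, with error degrees
#' of freedom `df = N_total - n_subjects - 1`. The p value comes from
#' `F(1, df)`; the 95% CI from a Fisher z interval with
#' `SE = 1 / sqrt(df - 1)`.
#'
#' @param data data.frame with columns `subject`, `x`, `y` (long format; one
#'   row per observation).
#' @param conf_level confidence level for the CI (default 0.95).
#' @return An object of class `rmcorr_result`: `r_rm`, `df`, `p`, `ci`,
#'   `slope`, `n_subjects`, `n_obs`.
#' @export
rmcorr <- function(data, conf_level = 0.95) {
  stopifnot(is.data.frame(data), all(c("subject", "x", "y") %in% names(data)))
  if (!all(is.finite(data$x)) || !all(is.finite(data$y)))
    stop("x and y must be finite")
  subj <- factor(data$subject)
  if (nlevels(subj) < 2L) stop("rmcorr needs >= 2 subjects")
  counts <- table(subj)
  if (any(counts < 2L))
    stop("subject(s) with < 2 observations: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  xc <- data$x - stats::ave(data$x, subj)
  yc <- data$y - stats::ave(data$y, subj)
  sxx <- sum(xc^2)
  if (sxx <= 0) stop("x has no within-subject variance")
  sxy <- sum(xc * yc)
  slope <- sxy / sxx
  ss_effect <- sxy^2 / sxx
  ss_error <- sum(yc^2) - ss_effect
  df <- nrow(data) - nlevels(subj) - 1L
  if (df < 1L) stop("non-positive error degrees of freedom")
  r <- sign(slope) * sqrt(ss_effect / (ss_effect + ss_error))
  Fstat <- ss_effect / (ss_error / df)
  p <- stats::pf(Fstat, 1, df, lower.tail = FALSE)
  ci <- if (df > 1L) {
    z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
    zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
    tanh(z + c(-1, 1) * zcrit / sqrt(df - 1))
  } else c(NA_real_, NA_real_)
  structure(list(r_rm = r, df = df, p = p, ci = ci, slope = slope,
                 n_subjects = nlevels(subj), n_obs = nrow(data),
                 ci_method = "fisher-z (SE = 1/sqrt(df - 1))"),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("r_rm(%d) = %.3f [95%% CI: %.3f to %.3f], p = %.4g (n = %d subjects, %d obs)\n",
              x$df, x$r_rm, x$ci[1], x$ci[2], x$p, x$n_subjects, x$n_obs))
  invisible(x)
}

# subjects x cells response matrix from long data; errors on duplicates and
# drops subjects with missing cells (complete-case) with a warning.
cell_matrix <- function(data, value, factors) {
  subj <- factor(data$subject)
  cell <- interaction(data[factors], drop = FALSE, lex.order = TRUE)
  tab <- table(subj, cell)
  if (any(tab > 1L)) stop("duplicated (subject, cell) observations")
  complete <- rowSums(tab) == nlevels(cell)
  if (!all(complete))
    warning(sum(!complete), " subject(s) dropped for missing cells (complete-case analysis)")
  keep <- levels(subj)[complete]
  m <- matrix(NA_real_, length(keep), nlevels(cell),
              dimnames = list(keep, levels(cell)))
  rows <- match(as.character(subj), keep)
  ok <- !is.na(rows)
  m[cbind(rows[ok], as.integer(cell)[ok])] <- data[[value]][ok]
  m
}

# orthonormal contrast matrix (k x (k-1)) spanning the effect space
orthonormal_contrasts <- function(k) {
  h <- stats::contr.helmert(k)
  sweep(h, 2, sqrt(colSums(h^2)), "/")
}

# Mauchly's sphericity test and Greenhouse-Geisser epsilon on the covariance
# of orthonormally transformed responses. Y: subjects x k cell means.
sphericity <- function(Y, C) {
  n <- nrow(Y); q <- ncol(C)
  Z <- Y %*% C
  S <- stats::cov(Z)
  eps <- sum(diag(S))^2 / (q * sum(S^2))
  W <- NA_real_; p <- NA_real_
  if (n - 1L > q) {
    detS <- det(S)
    if (detS > 0) {
      # chi-square approximation with Box's second-order correction,
      # matching stats::mauchly.test
      nd <- n - 1
      W <- detS / (sum(diag(S)) / q)^q
      rho <- 1 - (2 * q^2 + q + 2) / (6 * q * nd)
      w2 <- (q + 2) * (q - 1) * (q - 2) * (2 * q^3 + 6 * q^2 + 3 * q + 2) /
        (288 * (nd * q * rho)^2)
      z <- -nd * rho * log(W)
      f <- q * (q + 1) / 2 - 1
      pr1 <- stats::pchisq(z, f, lower.tail = FALSE)
      pr2 <- stats::pchisq(z, f + 4, lower.tail = FALSE)
      p <- pr1 + w2 * (pr2 - pr1)
    } else p <- 0  # singular covariance: sphericity untenable
  }
  list(W = W, p = p, epsilon_gg = min(eps, 1))
}

#' Repeated-measures ANOVA (one or two within-subject factors)
#'
#' Complete-case repeated-measures ANOVA with sums-of-squares partitioning;
#' each within-subject effect is tested against its own subject-interaction
#' error term. Mauchly's test is run per effect; when it rejects at
#' `sphericity_alpha` the Greenhouse-Geisser epsilon scales both degrees of
#' freedom. Effects with two levels are spherical by construction
#' (epsilon = 1, no correction).
#'
#' @param data data.frame with columns `subject`, `value`, and the factor
#'   column(s) named in `factors`.
#' @param factors character vector of 1 or 2 within-subject factor names.
#' @param sphericity_alpha alpha for Mauchly's test (default 0.05).
#' @return List of `rm_anova_result` objects (one per effect, plus the
#'   interaction in the two-way case), each with `effect`, `F`, `df_num`,
#'   `df_den`, `epsilon_gg`, `mauchly_p`, `p`, `corrected`, and the
#'   uncorrected `p_uncorrected`; the list carries attributes `n_subjects`
#'   and `ms_error` (per effect) used by the pairwise comparisons.
#' @export
rm_anova <- function(data, factors, sphericity_alpha = 0.05) {
  stopifnot(is.data.frame(data), "subject" %in% names(data),
            "value" %in% names(data))
  if (!length(factors) %in% 1:2) stop("factors must name 1 or 2 columns")
  if (!all(factors %in% names(data))) stop("missing factor column(s)")
  for (f in factors)
    if (length(unique(data[[f]])) < 2L)
      stop("factor '", f, "' has < 2 levels")
  Y <- cell_matrix(data, "value", factors)
  n <- nrow(Y)
  if (n < 3L) stop("fewer than 3 subjects after complete-case filtering")
  ka <- length(unique(data[[factors[1]]]))
  kb <- if (length(factors) == 2L) length(unique(data[[factors[2]]])) else 1L
  grand <- mean(Y)
  subj_mean <- rowMeans(Y)

  one_effect <- function(effect, Ccells, Yeff, k) {
    # Yeff: subjects x k matrix of cell means for this effect
    eff_mean <- colMeans(Yeff)
    mult <- ncol(Y) / k  # observations per (subject, level of this effect)
    ss_eff <- n * mult * sum((eff_mean - grand)^2)
    ss_err <- mult * sum((Yeff - outer(subj_mean, rep(1, k)) -
                            outer(rep(1, n), eff_mean) + grand)^2)
    df1 <- k - 1
    df2 <- (k - 1) * (n - 1)
    Fstat <- if (ss_eff <= 0) 0 else (ss_eff / df1) / (ss_err / df2)
    if (!is.finite(Fstat)) Fstat <- Inf
    sp <- sphericity(Y, Ccells)
    corrected <- is.finite(sp$p) && !is.na(sp$p) && sp$p < sphericity_alpha
    eps <- if (corrected) sp$epsilon_gg else 1
    p_unc <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    p <- stats::pf(Fstat, df1 * eps, df2 * eps, lower.tail = FALSE)
    structure(list(effect = effect, F = Fstat, df_num = df1 * eps,
                   df_den = df2 * eps, epsilon_gg = sp$epsilon_gg,
                   mauchly_w = sp$W, mauchly_p = sp$p,
                   p = if (corrected) p else p_unc,
                   p_uncorrected = p_unc, corrected = corrected,
                   ss_effect = ss_eff, ss_error = ss_err,
                   ms_error = ss_err / df2, df_error = df2),
              class = "rm_anova_result")
  }

  out <- list()
  if (length(factors) == 1L) {
    C <- orthonormal_contrasts(ka)
    out[[factors[1]]] <- one_effect(factors[1], C, Y, ka)
  } else {
    # cells ordered lexicographically: factor A slow, factor B fast
    Ma <- orthonormal_contrasts(ka); Mb <- orthonormal_contrasts(kb)
    ua <- rep(1, ka) / sqrt(ka); ub <- rep(1, kb) / sqrt(kb)
    Ya <- t(sapply(seq_len(n), function(i)
      colMeans(matrix(Y[i, ], nrow = kb))))      # n x ka subject-by-A means
    Yb <- t(sapply(seq_len(n), function(i)
      rowMeans(matrix(Y[i, ], nrow = kb))))      # n x kb subject-by-B means
    out[[factors[1]]] <- one_effect(factors[1], kronecker(Ma, ub), Ya, ka)
    out[[factors[2]]] <- one_effect(factors[2], kronecker(ua, Mb), Yb, kb)
    # interaction, tested against its subject-interaction residual
    Cab <- kronecker(Ma, Mb)
    cellm <- colMeans(Y)
    A_idx <- rep(seq_len(ka), each = kb)
    B_idx <- rep(seq_len(kb), times = ka)
    am <- colMeans(Ya); bm <- colMeans(Yb)
    ss_ab <- n * sum((cellm - am[A_idx] - bm[B_idx] + grand)^2)
    resid <- Y -
      Ya[, A_idx, drop = FALSE] - Yb[, B_idx, drop = FALSE] -
      matrix(cellm, n, ka * kb, byrow = TRUE) +
      matrix(am[A_idx], n, ka * kb, byrow = TRUE) +
      matrix(bm[B_idx], n, ka * kb, byrow = TRUE) +
      subj_mean - grand
    ss_int_err <- sum(resid^2)
    df1 <- (ka - 1) * (kb - 1)
    df2 <- df1 * (n - 1)
    Fstat <- if (ss_ab <= 0) 0 else (ss_ab / df1) / (ss_int_err / df2)
    if (!is.finite(Fstat)) Fstat <- Inf
    sp <- sphericity(Y, Cab)
    corrected <- is.finite(sp$p) && !is.na(sp$p) && sp$p < sphericity_alpha
    eps <- if (corrected) sp$epsilon_gg else 1
    p_unc <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    inm <- paste(factors, collapse = ":")
    out[[inm]] <- structure(
      list(effect = inm, F = Fstat, df_num = df1 * eps, df_den = df2 * eps,
           epsilon_gg = sp$epsilon_gg, mauchly_w = sp$W, mauchly_p = sp$p,
           p = if (corrected) stats::pf(Fstat, df1 * eps, df2 * eps,
                                        lower.tail = FALSE) else p_unc,
           p_uncorrected = p_unc, corrected = corrected,
           ss_effect = ss_ab, ss_error = ss_int_err,
           ms_error = ss_int_err / df2, df_error = df2),
      class = "rm_anova_result")
  }
  attr(out, "n_subjects") <- n
  out
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("%s: F(%.4g, %.4g) = %.3f, p = %.4g%s (epsilon_GG = %.3f, Mauchly p = %s)\n",
              x$effect, x$df_num, x$df_den, x$F, x$p,
              if (x$corrected) " [GG-corrected]" else "",
              x$epsilon_gg,
              if (is.na(x$mauchly_p)) "NA" else sprintf("%.3g", x$mauchly_p)))
  invisible(x)
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the m raw p values ascending, adjusts the i-th smallest to
#' `1 - (1 - p_(i))^(m - i + 1)`, and enforces monotone non-decreasing
#' adjusted values down the sequence.
#'
#' @param p_values numeric vector of raw p values in `[0, 1]`.
#' @param alpha significance level for the flags (default 0.05).
#' @return data.frame with `p_raw`, `p_adjusted`, `significant`, in the
#'   original order.
#' @export
holm_sidak <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stop("empty p value list")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  padj <- 1 - (1 - p_values[ord])^(m - seq_len(m) + 1)
  padj <- cummax(padj)
  out <- numeric(m); out[ord] <- padj
  data.frame(p_raw = p_values, p_adjusted = out,
             significant = out < alpha)
}

#' Pairwise Holm-Sidak comparisons among within-subject conditions
#'
#' Paired t statistics for every (or a requested subset of) condition pair,
#' followed by the Holm-Sidak step-down adjustment. When sphericity holds,
#' a single pooled error variance (the ANOVA's MS_error with its error df)
#' is used for every pair; when it is violated, each pair uses its own
#' difference-score variance with `n - 1` df.
#'
#' @param data data.frame with `subject`, `value`, and the condition column.
#' @param factor name of the condition column.
#' @param pairs optional list of length-2 character vectors naming the
#'   comparisons; default all pairs.
#' @param pooled_variance use the pooled ANOVA error variance (set this from
#'   the Mauchly outcome: pooled when sphericity was not violated).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per comparison: levels, mean difference,
#'   t, df, raw and adjusted p, significance flag.
#' @export
pairwise_holm_sidak <- function(data, factor, pairs = NULL,
                                pooled_variance = TRUE, alpha = 0.05) {
  Y <- cell_matrix(data, "value", factor)
  lev <- colnames(Y); n <- nrow(Y)
  if (is.null(pairs))
    pairs <- utils::combn(lev, 2, simplify = FALSE)
  an <- rm_anova(data, factor)
  mse <- an[[factor]]$ms_error; dfe <- an[[factor]]$df_error
  rows <- lapply(pairs, function(pr) {
    d <- Y[, pr[1]] - Y[, pr[2]]
    md <- mean(d)
    if (pooled_variance) {
      t <- md / sqrt(2 * mse / n); df <- dfe
    } else {
      t <- md / (stats::sd(d) / sqrt(n)); df <- n - 1
    }
    data.frame(level1 = pr[1], level2 = pr[2], mean_diff = md, t = t,
               df = df, p_raw = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  hs <- holm_sidak(out$p_raw, alpha = alpha)
  out$p_adjusted <- hs$p_adjusted
  out$significant <- hs$significant
  out
}

#' Power of a two-tailed paired t test
#'
#' Exact power via the noncentral t distribution with noncentrality
#' `dz * sqrt(n)` and `n - 1` degrees of freedom.
#'
#' @param dz standardized paired effect size (mean difference / SD of
#'   differences), >= 0.
#' @param n number of pairs (>= 2).
#' @param alpha two-tailed alpha level (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
paired_power <- function(dz, n, alpha = 0.05) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("invalid alpha")
  if (n < 2) stop("n must be >= 2")
  if (dz < 0) stop("dz must be >= 0")
  df <- n - 1
  ncp <- dz * sqrt(n)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}

#' Minimum sample size for a paired design
#'
#' Smallest n with `paired_power(dz, n, alpha) >= power_target`. Reproduces
#' the planning numbers n = 10 (80% power) and n = 13 (90% power) for
#' dz = 1 at two-tailed alpha 0.05.
#'
#' @param dz standardized paired effect size (> 0).
#' @param power_target target power in (0, 1).
#' @param alpha two-tailed alpha (default 0.05).
#' @param n_max search bound (default 10000).
#' @return Integer sample size.
#' @export
min_sample_size <- function(dz, power_target = 0.8, alpha = 0.05,
                            n_max = 10000L) {
  if (!is.finite(power_target) || power_target <= 0 || power_target >= 1)
    stop("power_target must be in (0, 1)")
  if (dz <= 0) stop("target unreachable: dz must be > 0")
  for (n in 2:n_max)
    if (paired_power(dz, n, alpha) >= power_target) return(n)
  stop("power target not reached by n = ", n_max)
}
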