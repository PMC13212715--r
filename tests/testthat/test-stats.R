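# Repeated-measures statistics: rmcorr, RM-ANOVA with sphericity handling,
# Holm-Sidak, paired power.

test_that("rmcorr equals the brute-force ANCOVA oracle", {
  # independent oracle: design-matrix least squares via lm(y ~ subject + x)
  set.seed(21)
  for (rep in 1:5) {
    ns <- sample(3:6, 1); no <- sample(3:6, 1)
    d <- data.frame(subject = rep(paste0("s", 1:ns), each = no),
                    x = rnorm(ns * no), y = rnorm(ns * no))
    fit <- stats::lm(y ~ subject + x, d)
    a <- stats::anova(fit)
    ss_x <- a["x", "Sum Sq"]; ss_e <- a["Residuals", "Sum Sq"]
    r_oracle <- unname(sign(stats::coef(fit)["x"])) *
      sqrt(ss_x / (ss_x + ss_e))
    r <- rmcorr(d)
    expect_equal(r$r_rm, r_oracle, tolerance = 1e-10)
    expect_equal(r$df, a["Residuals", "Df"])
    expect_equal(r$p, a["x", "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("rmcorr is exact on within-subject linear data and offset-invariant", {
  set.seed(22)
  d <- data.frame(subject = rep(1:4, each = 5), x = rnorm(20))
  d$y <- 2 * d$x + rep(c(10, -3, 0, 7), each = 5)
  r <- rmcorr(d)
  expect_equal(r$r_rm, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-12)

  d2 <- data.frame(subject = rep(1:5, each = 4),
                   x = rnorm(20), y = rnorm(20))
  base <- rmcorr(d2)
  d3 <- d2
  d3$x <- d3$x + rep(runif(5, -50, 50), each = 4)
  d3$y <- d3$y + rep(runif(5, -50, 50), each = 4)
  shifted <- rmcorr(d3)
  expect_equal(shifted$r_rm, base$r_rm, tolerance = 1e-9)
  expect_equal(shifted$df, base$df)
  # CI contains the estimate
  expect_between(base$r_rm, base$ci[1], base$ci[2])
})

test_that("rmcorr df reproduces N(k-1) - 1 for the four printed designs", {
  set.seed(23)
  shapes <- list(c(13, 8, 90), c(14, 6, 69), c(11, 4, 32), c(12, 3, 23))
  for (s in shapes) {
    d <- data.frame(subject = rep(seq_len(s[1]), each = s[2]),
                    x = rnorm(s[1] * s[2]), y = rnorm(s[1] * s[2]))
    expect_identical(rmcorr(d)$df, as.integer(s[3]))
  }
  expect_error(rmcorr(data.frame(subject = c(1, 1, 2), x = 1:3, y = 1:3)),
               "< 2 observations")
})

test_that("one-way rm_anova matches aov and stats::mauchly.test oracles", {
  set.seed(24)
  n <- 9; k <- 4
  Y <- matrix(rnorm(n * k), n, k) + outer(rnorm(n, sd = 2), rep(1, k)) +
    outer(rep(1, n), c(0, 0.5, 1, 0.2)) +
    outer(rnorm(n), c(0, 0.2, 1, 2))  # induces non-sphericity
  d <- data.frame(subject = rep(1:n, k),
                  cond = rep(letters[1:k], each = n),
                  value = as.vector(Y))
  res <- rm_anova(d, "cond")[["cond"]]
  aovf <- summary(stats::aov(value ~ cond + Error(factor(subject) / cond),
                             d))[["Error: factor(subject):cond"]][[1]]
  expect_equal(res$F, aovf["cond", "F value"], tolerance = 1e-10)
  expect_equal(res$p_uncorrected, aovf["cond", "Pr(>F)"], tolerance = 1e-10)

  # stats::mauchly.test's second-order Box term uses the ambient dimension
  # where the textbook formula uses the contrast dimension; the p values
  # agree to ~1e-4
  mt <- stats::mauchly.test(stats::lm(Y ~ 1), X = ~1)
  expect_equal(res$mauchly_p, mt$p.value, tolerance = 1e-3)

  # Greenhouse-Geisser epsilon against a direct covariance-based oracle
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  S <- stats::cov(Y %*% C)
  eps_oracle <- sum(diag(S))^2 / ((k - 1) * sum(S^2))
  expect_equal(res$epsilon_gg, eps_oracle, tolerance = 1e-12)
  expect_between(res$epsilon_gg, 1 / (k - 1), 1)
})

test_that("rm_anova degenerate cases behave as specified", {
  # identical values in all cells -> F = 0
  d0 <- expand.grid(subject = 1:5, cond = letters[1:3])
  d0$value <- 7
  expect_equal(rm_anova(d0, "cond")[["cond"]]$F, 0)

  # two-level factor: spherical by construction, no correction
  set.seed(25)
  d2 <- expand.grid(subject = 1:8, cond = c("a", "b"))
  d2$value <- rnorm(16)
  r2 <- rm_anova(d2, "cond")[["cond"]]
  expect_equal(r2$epsilon_gg, 1)
  expect_false(r2$corrected)

  # F = t^2 against the paired t test
  Y <- matrix(rnorm(16), 8, 2)
  dl <- data.frame(subject = rep(1:8, 2),
                   cond = rep(c("a", "b"), each = 8), value = as.vector(Y))
  res <- rm_anova(dl, "cond")[["cond"]]
  tt <- stats::t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  expect_error(rm_anova(d0[d0$cond == "a", ], "cond"), "< 2 levels")
  expect_error(rm_anova(d2[d2$subject < 3, ], "cond"), "fewer than 3")
})

test_that("two-way rm_anova matches the aov partitioning", {
  set.seed(26)
  n <- 7; ka <- 3; kb <- 2
  d <- expand.grid(subject = 1:n, condition = letters[1:ka],
                   hold = c("h1", "h2"))
  d$value <- rnorm(nrow(d)) + as.integer(d$condition) +
    0.5 * as.integer(d$hold) + rnorm(n)[d$subject]
  res <- rm_anova(d, c("condition", "hold"))
  aovf <- summary(stats::aov(
    value ~ condition * hold +
      Error(factor(subject) / (condition * hold)), d))
  fa <- aovf[["Error: factor(subject):condition"]][[1]]
  fb <- aovf[["Error: factor(subject):hold"]][[1]]
  fab <- aovf[["Error: factor(subject):condition:hold"]][[1]]
  expect_equal(res$condition$F, fa["condition", "F value"], tolerance = 1e-9)
  expect_equal(res$hold$F, fb["hold", "F value"], tolerance = 1e-9)
  expect_equal(res$`condition:hold`$F,
               fab["condition:hold", "F value"], tolerance = 1e-9)
  expect_equal(res$condition$p_uncorrected, fa["condition", "Pr(>F)"],
               tolerance = 1e-9)
})

test_that("complete-case filtering drops subjects with missing cells", {
  set.seed(27)
  d <- expand.grid(subject = 1:6, cond = letters[1:3])
  d$value <- rnorm(18)
  d_missing <- d[-1, ]  # subject 1 loses cell 'a'
  expect_warning(res <- rm_anova(d_missing, "cond"), "complete-case")
  expect_equal(attr(res, "n_subjects"), 5)
})

test_that("holm_sidak equals direct enumeration and is monotone", {
  # closed-form oracle evaluated independently for m = 3
  p <- c(0.01, 0.03, 0.04)
  adj <- holm_sidak(p)$p_adjusted
  expect_equal(adj[1], 1 - 0.99^3, tolerance = 1e-12)
  expect_equal(adj[2], max(1 - 0.99^3, 1 - 0.97^2), tolerance = 1e-12)
  expect_equal(adj[3], max(adj[2], 1 - 0.96), tolerance = 1e-12)

  expect_equal(holm_sidak(0.03)$p_adjusted, 0.03)
  expect_equal(holm_sidak(rep(1, 4))$p_adjusted, rep(1, 4))
  expect_error(holm_sidak(numeric(0)), "empty")
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")

  # property: adjusted >= raw, monotone in rank, order-independent
  set.seed(28)
  for (rep in 1:10) {
    p <- runif(sample(2:8, 1))
    out <- holm_sidak(p)
    expect_true(all(out$p_adjusted >= out$p_raw - 1e-15))
    o <- order(out$p_raw)
    expect_true(all(diff(out$p_adjusted[o]) >= -1e-15))
  }
})

test_that("pairwise comparisons use pooled or individual variances", {
  set.seed(29)
  n <- 10
  Y <- matrix(rnorm(3 * n), n, 3) + outer(rep(1, n), c(0, 1, 0))
  d <- data.frame(subject = rep(1:n, 3),
                  cond = rep(c("a", "b", "c"), each = n),
                  value = as.vector(Y))
  ind <- pairwise_holm_sidak(d, "cond", pooled_variance = FALSE)
  # individual-variance rows equal plain paired t tests
  tt <- stats::t.test(Y[, 1], Y[, 2], paired = TRUE)
  row <- ind[ind$level1 == "a" & ind$level2 == "b", ]
  expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(row$p_raw, tt$p.value, tolerance = 1e-10)
  expect_equal(row$df, n - 1)
  pooled <- pairwise_holm_sidak(d, "cond", pooled_variance = TRUE)
  expect_true(all(pooled$df == 2 * (n - 1)))
})

test_that("paired power matches the planning numbers and is monotone", {
  # under the null the rejection rate equals alpha
  expect_equal(paired_power(0, 15), 0.05, tolerance = 1e-9)
  expect_gte(paired_power(1, 10), 0.80)
  expect_gte(paired_power(1, 13), 0.90)
  expect_lt(paired_power(1, 9), 0.80)   # 10 really is the minimum
  expect_lt(paired_power(1, 12), 0.90)

  n_grid <- 2:40
  pw <- sapply(n_grid, function(n) paired_power(1, n))
  expect_true(all(diff(pw) > 0))
  expect_lt(paired_power(0.5, 20), paired_power(1, 20))
  expect_error(paired_power(1, 10, alpha = 1.5), "invalid alpha")
})

test_that("min_sample_size reproduces the printed 10 and 13", {
  expect_identical(min_sample_size(1, 0.80, 0.05), 10L)
  expect_identical(min_sample_size(1, 0.90, 0.05), 13L)
  # brute-force scan oracle for dz = 2
  scan <- which(sapply(2:50, function(n) paired_power(2, n) >= 0.8))[1] + 1L
  expect_identical(min_sample_size(2, 0.80, 0.05), scan)
  expect_error(min_sample_size(0, 0.8), "unreachable")
})
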