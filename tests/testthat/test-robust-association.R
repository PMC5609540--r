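# The robust machinery must reduce to ordinary least squares when the data
# give it no reason to reweight, and must shrug off gross contamination.

make_linear_data <- function(n = 500, seed = 1, noise_sd = 0) {
  set.seed(seed)
  g <- factor(sample(paste0("g", 1:5), n, replace = TRUE))
  x <- rnorm(n)
  beta <- c(2, -1, 0.5, 1.5, -0.5)
  y <- beta[as.integer(g)] + 0.8 * x + rnorm(n, 0, noise_sd)
  list(X = model.matrix(~ g + x), y = y)
}

test_that("robust IRLS reproduces least squares exactly on noise-free data", {
  d <- make_linear_data(n = 500, seed = 4, noise_sd = 0)
  rob <- endoxpred:::.robust_irls(d$X, d$y)
  ols <- lm.fit(d$X, d$y)
  expect_lt(max(abs(rob$coefficients - ols$coefficients)), 1e-6)
  expect_true(all(rob$weights == 1))
  fit <- structure(c(rob, list(y = d$y, n = nrow(d$X), p = ncol(d$X))),
                   class = "robust_fit")
  expect_equal(robust_adjusted_r2(fit), 1, tolerance = 1e-10)
})

test_that("gross outliers get near-zero weights and barely move the coefficients", {
  d <- make_linear_data(n = 500, seed = 4, noise_sd = 0.5)
  clean <- endoxpred:::.robust_irls(d$X, d$y)
  y_c <- d$y
  set.seed(99)
  idx <- sample(length(y_c), 25)  # 5% contamination
  y_c[idx] <- y_c[idx] + 40
  rob <- endoxpred:::.robust_irls(d$X, y_c)
  expect_true(all(rob$weights[idx] < 1e-4))
  # robust coefficients shift by well under 10%
  expect_lt(max(abs(rob$coefficients - clean$coefficients) /
                  pmax(abs(clean$coefficients), 0.5)), 0.1)
  # least squares is dragged far away
  ols <- lm.fit(d$X, y_c)
  expect_gt(max(abs(ols$coefficients - clean$coefficients)), 0.5)
})

test_that("weighted adjusted R2 reduces to the classical formula at unit weights", {
  co <- tiny_cohort(n = 250, seed = 21)
  fit <- fit_robust_linear(co, "E_over_DMT", "diplotype",
                           estimator = "ordinary")
  expect_true(all(fit$weights == 1))
  df <- data.frame(y = fit$y, as.data.frame(fit$X[, -1]))
  classical <- summary(lm(y ~ ., data = df))$adj.r.squared
  expect_equal(robust_adjusted_r2(fit), classical, tolerance = 1e-10)
})

test_that("a response exactly linear in the activity score gives R2 = 1", {
  co <- tiny_cohort(n = 200, seed = 3)
  co$e_ngml <- exp(0.5 + 1.2 * co$as_standard)
  co$dmt_ngml <- 1
  fit <- fit_robust_linear(co, "E_over_DMT", "AS", covariates = FALSE)
  expect_equal(robust_adjusted_r2(fit), 1, tolerance = 1e-10)
})

test_that("degenerate designs raise informative errors", {
  co <- tiny_cohort(n = 120, seed = 13)
  co$cyp2c9_class <- co$cyp3a5_class      # aliased covariate
  expect_error(fit_robust_linear(co, "E_over_DMT", "diplotype"),
               "rank-deficient")
  expect_error(endoxpred:::.robust_irls(cbind(1, diag(5)), rnorm(5)),
               "more observations than parameters")
  expect_error(fit_robust_linear(co, "E_over_DMT", "nonsense"),
               "unknown predictor")
})

test_that("phenotype-scheme R2 never beats the full diplotype factor on average", {
  r2 <- sapply(1:4, function(s) {
    co <- simulate_cohort(n = 900, seed = 40 + s)
    dip <- robust_adjusted_r2(fit_robust_linear(co, "E_over_DMT", "diplotype"))
    sch <- sapply(c("Codeine", "TAM1", "TAM2", "TAM3", "TAM4"), function(sc)
      robust_adjusted_r2(fit_robust_linear(co, "E_over_DMT", sc)))
    c(dip = dip, max_scheme = max(sch))
  })
  expect_true(all(r2["dip", ] >= r2["max_scheme", ] - 0.01))
  expect_gt(mean(r2["dip", ] - r2["max_scheme", ]), 0)
})

test_that("bootstrap R2 interval collapses at one replicate and is stable across seeds", {
  co <- tiny_cohort(n = 300, seed = 55)
  one <- bootstrap_r2_ci(co, replicates = 1, seed = 7)
  expect_identical(one$ci[1], one$estimate)
  expect_identical(one$ci[2], one$estimate)
  a <- bootstrap_r2_ci(co, replicates = 400, seed = 1)
  b <- bootstrap_r2_ci(co, replicates = 400, seed = 2)
  expect_lt(abs(a$boot_median - b$boot_median), 0.025)
  expect_true(a$ci[1] <= a$boot_median && a$boot_median <= a$ci[2])
  # deterministic given the seed
  a2 <- bootstrap_r2_ci(co, replicates = 400, seed = 1)
  expect_identical(a$boot_r2, a2$boot_r2)
})

test_that("analysis of deviance rejects degenerate or non-nested comparisons", {
  co <- tiny_cohort(n = 250, seed = 17)
  f1 <- fit_robust_linear(co, "E_over_DMT", "AS")
  f2 <- fit_robust_linear(co, "E_over_DMT", "diplotype")
  expect_error(compare_models_deviance(f1, f1), "degenerate nesting")
  # AS is not spanned by the covariate-only part of another endpoint's fit
  f3 <- fit_robust_linear(co, "E", "AS")
  expect_error(compare_models_deviance(f1, f3), "same response")
})

test_that("adding the true generative factor is detected with high power", {
  co <- simulate_cohort(n = 900, seed = 61)
  reduced <- fit_robust_linear(co, "E_over_DMT", "Codeine")
  full <- fit_robust_linear(co, "E_over_DMT", "diplotype")
  # Codeine phenotype is a coarsening of the diplotype factor: nested
  d2 <- endoxpred:::.build_design(co, "E_over_DMT", "Codeine")
  X_full <- endoxpred:::.drop_aliased(cbind(d2$X, full$X[, -1]))
  f12 <- endoxpred:::.robust_irls(X_full, full$y)
  f12 <- structure(c(f12, list(y = full$y, X = X_full, n = nrow(X_full),
                               p = ncol(X_full))), class = "robust_fit")
  cmp <- compare_models_deviance(reduced, f12)
  expect_lt(cmp$p_value, 1e-3)
  expect_identical(cmp$df, f12$p - reduced$p)
})

test_that("deviance test keeps its nominal size under the null", {
  # pure-noise second predictor; rejection rate at alpha = .05 stays within
  # the binomial envelope
  n <- 150
  reps <- 600
  pvals <- numeric(reps)
  for (i in seq_len(reps)) {
    set.seed(2000 + i)
    g <- factor(sample(1:4, n, replace = TRUE))
    y <- rnorm(n) + as.integer(g) * 0.5
    X0 <- model.matrix(~ g)
    noise <- factor(sample(1:3, n, replace = TRUE))
    X1 <- cbind(X0, model.matrix(~ noise)[, -1])
    f0 <- endoxpred:::.robust_irls(X0, y)
    f1 <- endoxpred:::.robust_irls(X1, y)
    f0 <- structure(c(f0, list(y = y, X = X0, n = n, p = ncol(X0))),
                    class = "robust_fit")
    f1 <- structure(c(f1, list(y = y, X = X1, n = n, p = ncol(X1))),
                    class = "robust_fit")
    pvals[i] <- compare_models_deviance(f0, f1)$p_value
  }
  rate <- mean(pvals < 0.05)
  # 99.7% binomial envelope around .05 at 600 replicates
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
})

test_that("covariate screen null case and empty-group handling", {
  cfg <- cohort_config(cyp3a5_dmt_multiplier = 1, cyp2c9_ohtam_multiplier = 1)
  co <- simulate_cohort(cfg, n = 4000, seed = 71, filter_compliance = FALSE)
  scr <- covariate_effect_screen(co)
  expect_lt(max(abs(scr$reduction_pct)), 4)
  # a cohort with no wild-type CYP3A5 patients skips that contrast
  cfg2 <- cohort_config(cyp3a5_freq = c("*1" = 0, "*3" = 1))
  co2 <- simulate_cohort(cfg2, n = 300, seed = 72, filter_compliance = FALSE)
  expect_warning(scr2 <- covariate_effect_screen(co2), "skipped")
  expect_true(is.na(scr2$reduction_pct[scr2$gene == "CYP3A5"]))
})
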