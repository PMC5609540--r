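test_that("outcome binarization applies the documented boundary convention", {
  co <- tiny_cohort(n = 50, seed = 12)
  co$e_ngml[1] <- 5.9      # exactly at threshold counts as above
  co$e_ngml[2] <- 5.8999
  out <- binarize_outcome(co)
  expect_true(out$above[1])
  expect_false(out$above[2])
  expect_identical(attr(out, "threshold_ngml"), 5.9)
  expect_identical(attr(out, "n_above") + attr(out, "n_below"), nrow(co))
  co$e_ngml <- 0
  expect_false(any(binarize_outcome(co)$above))
})

test_that("ROC over diplotype ranks produces the stated cutoff structure", {
  out <- random_outcomes(400, seed = 5)
  roc <- roc_diplotype_ranks(out)
  # seven level cutoffs plus the all-positive endpoint
  expect_identical(nrow(roc), 8L)
  expect_identical(roc$sensitivity[roc$cutoff == -Inf], 1)
  expect_identical(roc$specificity[roc$cutoff == -Inf], 0)
  expect_identical(roc$sensitivity[roc$cutoff == 3], 0)
  expect_identical(roc$specificity[roc$cutoff == 3], 1)
  # sensitivity non-increasing as the cutoff rises
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$specificity) >= 0))
  # the >0.5 cutoff declares exactly the five upper categories positive
  pos_at_05 <- sum(out$activity > 0.5)
  r05 <- roc[roc$cutoff == 0.5, ]
  expect_identical(r05$tp + r05$fp, pos_at_05)
  expect_match(r05$label, "IM/IM")
  # degenerate single-class outcomes are refused
  out$above <- TRUE
  expect_error(roc_diplotype_ranks(out), "ROC undefined")
})

test_that("ROC points agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  out <- random_outcomes(600, seed = 9)
  roc <- roc_diplotype_ranks(out)
  ref <- pROC::roc(response = out$above, predictor = out$activity,
                   direction = "<", quiet = TRUE)
  cc <- pROC::coords(ref, x = "all", ret = c("sensitivity", "specificity"))
  mine <- paste(signif(roc$sensitivity, 12), signif(roc$specificity, 12))
  theirs <- paste(signif(cc$sensitivity, 12), signif(cc$specificity, 12))
  expect_true(all(mine %in% theirs))
})

test_that("Youden selection equals exhaustive search with the specificity tie rule", {
  for (s in 1:25) {
    out <- random_outcomes(80, seed = 100 + s)
    roc <- roc_diplotype_ranks(out)
    best <- youden_optimal_cutoff(roc)
    # brute force over every candidate cutoff
    expect_equal(best$youden_j, max(roc$youden_j), tolerance = 1e-12)
    champs <- roc[abs(roc$youden_j - max(roc$youden_j)) < 1e-12, ]
    expect_equal(best$specificity, max(champs$specificity))
  }
  # constructed tie with unequal specificity: prefer the more specific cutoff
  out <- data.frame(above = rep(c(TRUE, FALSE), c(3, 3)),
                    activity = c(2, 2, 0.75, 0.75, 0, 0))
  roc <- roc_diplotype_ranks(out)
  ties <- roc[abs(roc$youden_j - max(roc$youden_j)) < 1e-12, ]
  expect_gt(length(unique(ties$specificity)), 1L)
  best <- youden_optimal_cutoff(roc)
  expect_equal(best$specificity, 1)
  expect_equal(best$sensitivity, 2 / 3)
  # among equal-specificity ties the higher cutoff wins
  expect_equal(best$cutoff, 1.5)
})

test_that("diagnostic metrics satisfy the J and FDR identities", {
  out <- random_outcomes(500, seed = 41)
  for (cc in c(0, 0.5, 1, 2)) {
    m <- diagnostic_metrics(out, cc)
    expect_equal(m$youden_j, m$sensitivity + m$specificity - 1,
                 tolerance = 1e-12)
    prev <- mean(out$above)
    expect_equal(m$fdr,
                 fdr_from_rates(m$sensitivity, m$specificity, prev),
                 tolerance = 1e-12)
    expect_identical(m$tp + m$fp + m$tn + m$fn, nrow(out))
  }
})

test_that("worked examples: PM/PM proportion and the all-cohort FDR identity", {
  # 45 of 50 poor metabolizers below threshold -> 90%
  pmpm <- data.frame(above = rep(c(FALSE, TRUE), c(45, 5)),
                     activity = rep(0, 50))
  expect_equal(100 * mean(!pmpm$above), 90)
  # closed form from sensitivity 96%, specificity 57%, prevalence 82.3%
  fdr <- fdr_from_rates(0.96, 0.57, 0.823)
  expect_equal(fdr, 0.088, tolerance = 0.005)
  expect_identical(round(100 * fdr), 9)
})

test_that("perfect separation yields a perfect cutoff", {
  out <- data.frame(above = rep(c(FALSE, TRUE), c(30, 70)),
                    activity = rep(c(0, 2), c(30, 70)))
  roc <- roc_diplotype_ranks(out)
  best <- youden_optimal_cutoff(roc)
  expect_equal(best$sensitivity, 1)
  expect_equal(best$specificity, 1)
  m <- diagnostic_metrics(out, best$cutoff)
  expect_equal(m$fdr, 0)
})

test_that("undefined metrics are flagged rather than silently computed", {
  out <- data.frame(above = rep(TRUE, 10), activity = rep(0, 10))
  m <- diagnostic_metrics(out, 2)   # nothing test-positive
  expect_true(is.na(m$fdr))
  expect_false(m$defined)
})

test_that("bootstrap metric intervals collapse at one replicate and are deterministic", {
  out <- random_outcomes(300, seed = 77)
  one <- bootstrap_metric_ci(out, 0.5, replicates = 1, seed = 3)
  expect_identical(unname(one$ci["sensitivity", "lower"]),
                   one$point$sensitivity)
  expect_identical(unname(one$ci["fdr", "upper"]), one$point$fdr)
  a <- bootstrap_metric_ci(out, 0.5, replicates = 500, seed = 11)
  b <- bootstrap_metric_ci(out, 0.5, replicates = 500, seed = 11)
  expect_identical(a$ci, b$ci)
  expect_true(all(a$ci >= 0 & a$ci <= 1))
  # point estimates sit inside their own intervals
  expect_true(a$ci["sensitivity", 1] <= a$point$sensitivity &&
                a$point$sensitivity <= a$ci["sensitivity", 2])
})
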