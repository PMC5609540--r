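test_that("cohort generation is deterministic given config and seed", {
  cfg <- cohort_config()
  a <- simulate_cohort(cfg, n = 400, seed = 123)
  b <- simulate_cohort(cfg, n = 400, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_cohort(cfg, n = 400, seed = 124)
  expect_false(identical(a$e_ngml, c$e_ngml))
})

test_that("config validation rejects inconsistent inputs", {
  f <- pooled_frequencies()
  expect_error(cohort_config(diplotype_frequencies = f * 0.9), "sum to 1")
  f2 <- f; names(f2)[1] <- "ZZ/ZZ"
  expect_error(cohort_config(diplotype_frequencies = f2), "unknown diplotype")
  expect_error(cohort_config(tam_median_ngml = -1), "must be > 0")
  expect_error(cohort_config(tam_sdlog = -0.1), "must be >= 0")
  expect_error(cohort_config(target_r2 = 1.2), "target_r2")
})

test_that("degenerate frequencies produce a single-stratum cohort", {
  f <- setNames(rep(0, 10), names(pooled_frequencies()))
  f["PM/PM"] <- 1
  cfg <- cohort_config(diplotype_frequencies = f)
  dip <- sample_diplotypes(cfg, 5, seed = 9)
  expect_identical(dip$category, rep("PM/PM", 5))
})

test_that("category sampling reproduces the configured stratum frequencies", {
  cfg <- cohort_config()
  dip <- sample_diplotypes(cfg, 1e5, seed = 31)
  # EM/EM observed at 33.4% in the emulated study composition
  expect_equal(mean(dip$category == "EM/EM"), 0.334, tolerance = 0.015)
  expect_equal(mean(dip$label == "*10/*10"), 45 / 898, tolerance = 0.05)
})

test_that("Hardy-Weinberg sampling matches the q^2 homozygote expectation", {
  cfg <- cohort_config()
  dip <- sample_diplotypes(cfg, 1e5, seed = 11, mode = "hardy_weinberg",
                           allele_freq = c("*10" = 0.5, "*1" = 0.5))
  expect_equal(mean(dip$label == "*10/*10"), 0.25, tolerance = 0.02)
  expect_equal(mean(dip$category == "EM/EM"), 0.25, tolerance = 0.02)
  expect_error(
    sample_diplotypes(cfg, 10, mode = "hardy_weinberg",
                      allele_freq = c("*10" = 0.5, "*1" = 0.4)),
    "sum to 1")
  expect_error(
    sample_diplotypes(cfg, 10, mode = "hardy_weinberg",
                      allele_freq = c("*99" = 1)),
    "unsupported allele")
})

test_that("median endoxifen and E/DMT are non-decreasing in standard activity score", {
  co <- simulate_cohort(n = 5e4, seed = 77, filter_compliance = FALSE)
  ratio <- co$e_ngml / co$dmt_ngml
  med_e <- tapply(co$e_ngml, co$as_standard, median)
  med_r <- tapply(ratio, co$as_standard, median)
  expect_true(all(diff(med_e[order(as.numeric(names(med_e)))]) >= 0))
  expect_true(all(diff(med_r[order(as.numeric(names(med_r)))]) >= 0))
})

test_that("zero-noise limit makes transformed E/DMT an exact function of the stratum", {
  cfg <- cohort_config(ratio_sdlog = 0, tam_sdlog = 0, dmt_tam_sdlog = 0)
  co <- simulate_cohort(cfg, n = 400, seed = 5, filter_compliance = FALSE)
  ratio <- log(co$e_ngml / co$dmt_ngml)
  spread <- tapply(ratio, co$label, function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
  # variance explained is then exactly 1
  fit <- fit_robust_linear(co, "E_over_DMT", "diplotype")
  expect_equal(robust_adjusted_r2(fit), 1, tolerance = 1e-10)
})

test_that("target_r2 = 1 calibrates to zero noise and lower targets to more noise", {
  cfg1 <- cohort_config(target_r2 = 1)
  expect_equal(calibrate_ratio_sdlog(cfg1), 0)
  s75 <- calibrate_ratio_sdlog(cohort_config(target_r2 = 0.75))
  s50 <- calibrate_ratio_sdlog(cohort_config(target_r2 = 0.50))
  expect_gt(s50, s75)
  expect_gt(s75, 0)
  # the moment form is the analytic lower bound here
  expect_lte(calibrate_ratio_sdlog(cohort_config(), method = "moment"), s75)
})

test_that("compliance filter removes records at or below 150 nM strictly", {
  co <- simulate_cohort(n = 50, seed = 2, filter_compliance = FALSE)
  # force three informative records: below, exactly at, and above threshold
  co$tam_ngml[1] <- nmol_to_ngml(140, "TAM")
  co$tam_ngml[2] <- nmol_to_ngml(150, "TAM")
  co$tam_ngml[3] <- nmol_to_ngml(150.0001, "TAM")
  kept <- apply_compliance_filter(co, 150)
  expect_false(co$id[1] %in% kept$id)
  expect_false(co$id[2] %in% kept$id)  # "above 150 nM" is strict
  expect_true(co$id[3] %in% kept$id)
  rep <- attr(kept, "compliance")
  expect_identical(rep$n_in, nrow(co))
  expect_identical(rep$n_kept + rep$n_removed, nrow(co))
  # threshold 0 is the identity
  expect_identical(nrow(apply_compliance_filter(co, 0)), nrow(co))
})

test_that("PM/PM patients fall below the clinical threshold about 90% of the time", {
  co <- simulate_cohort(n = 4e4, seed = 19)
  pm <- co$e_ngml[co$label == "PM/PM"]
  expect_gt(length(pm), 1500)
  expect_equal(mean(pm < 5.9), 0.90, tolerance = 0.05)
})

test_that("covariate effects recover the 12% and 26% median ratio reductions across seeds", {
  red <- sapply(1:10, function(s) {
    co <- simulate_cohort(n = 900, seed = 300 + s, filter_compliance = FALSE)
    scr <- covariate_effect_screen(co)
    setNames(scr$reduction_pct, scr$gene)
  })
  expect_lt(abs(median(red["CYP3A5", ]) - 12), 4)
  expect_lt(abs(median(red["CYP2C9", ]) - 26), 4)
})

test_that("metabolite sampling demands ratio parameters for every stratum present", {
  cfg <- cohort_config()
  cfg$ratio_medians <- cfg$ratio_medians[-1]   # drop EM/UM
  dip <- parse_diplotype(c("*1x2/*1", "*1/*1"))
  expect_error(sample_metabolites(dip, cfg, seed = 1), "EM/UM")
})

test_that("menopausal status derives from age at the 50-year boundary", {
  co <- simulate_cohort(n = 2000, seed = 8, filter_compliance = FALSE)
  expect_identical(co$menopause, ifelse(co$age >= 50, "post", "pre"))
})
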