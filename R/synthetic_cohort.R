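## Synthetic patient cohort generator.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: diplotype strata drawn from the observed cohort composition,
## log-normal metabolite cascades TAM -> DMT -> endoxifen whose E/DMT
## geometric medians increase monotonically with CYP2D6 activity, covariate
## effects of CYP3A5*3 and CYP2C9*2/*3 on the precursor ratios, and a
## tamoxifen compliance filter at 150 nM.  The log-scale noise of E/DMT is
## calibrated analytically so that the fraction of variance of log(E/DMT)
## attributable to diplotype hits a configured target.

.disjoint_strata <- function() {
  tab <- diplotype_table()
  ## carve the nested *10 refinements out of their generic classes to get
  ## ten mutually exclusive strata
  n <- tab$count
  parent_deduction <- setNames(rep(0L, nrow(tab)), tab$label)
  for (i in which(tab$is_refinement)) {
    parent_deduction[[.REFINEMENT_PARENT[[tab$label[i]]]]] <-
      parent_deduction[[.REFINEMENT_PARENT[[tab$label[i]]]]] + tab$count[i]
  }
  n <- n - parent_deduction[tab$label]
  data.frame(label = tab$label, representative = tab$representative,
             prob = unname(n) / sum(n), stringsAsFactors = FALSE)
}

#' Default diplotype stratum frequencies (pooled study composition)
#'
#' Probabilities of the ten mutually exclusive diplotype strata (seven
#' generic categories with the three \*10 refinements carved out of their
#' parent classes) matching the pooled observed cohort composition of
#' [diplotype_table()].
#'
#' @return Named numeric vector summing to 1.
#' @export
pooled_frequencies <- function() {
  s <- .disjoint_strata()
  setNames(s$prob, s$label)
}

#' An Asian-like, *10-rich diplotype frequency preset
#'
#' East-Asian populations carry the reduced-function \*10 allele at high
#' frequency, so \*10-containing diplotypes dominate the reduced-activity
#' strata. This preset is used to study schemes whose generic binning
#' misclassifies abundant \*10/\*10 carriers.
#'
#' @return Named numeric vector over the ten strata, summing to 1.
#' @export
asian_like_frequencies <- function() {
  c("EM/UM" = 0.005, "EM/EM" = 0.24, "EM/IM" = 0.01, "EM/*10" = 0.445,
    "EM/PM" = 0.05, "IM/IM" = 0.005, "*10/*10" = 0.20, "IM/PM" = 0.005,
    "PM/*10" = 0.02, "PM/PM" = 0.02)
}

.default_ratio_medians <- function() {
  ## geometric medians of E/DMT per stratum, non-decreasing in activity
  ## class; *10-containing strata sit below their non-*10 class mates
  c("EM/UM" = 0.156, "EM/EM" = 0.101, "EM/IM" = 0.075, "EM/*10" = 0.062,
    "EM/PM" = 0.054, "IM/IM" = 0.0575, "*10/*10" = 0.051, "IM/PM" = 0.0265,
    "PM/*10" = 0.0226, "PM/PM" = 0.0198)
}

.default_ratio_sdlog_scale <- function() {
  ## the spread of attained activity narrows with functional impairment:
  ## reduced-activity strata get proportionally less E/DMT log-noise
  c("EM/UM" = 1, "EM/EM" = 1, "EM/IM" = 1, "EM/*10" = 1, "EM/PM" = 1,
    "IM/IM" = 0.8, "*10/*10" = 0.5, "IM/PM" = 0.6, "PM/*10" = 0.6,
    "PM/PM" = 0.5)
}

#' Configuration of the synthetic cohort generator
#'
#' All parameters of the generative model, with defaults calibrated to the
#' study structure the package emulates: the pooled diplotype composition
#' of [pooled_frequencies()]; log-normal metabolite cascade with E/DMT
#' geometric medians increasing in CYP2D6 activity; diplotype
#' variance-explained target of 0.75 for log(E/DMT); CYP3A5*3/*3 reducing
#' the DMT/TAM ratio by 12% and CYP2C9 variant homozygosity reducing
#' 4OH-TAM/TAM by 26% relative to *1/*1; and a tamoxifen compliance
#' threshold of 150 nM.
#'
#' @param diplotype_frequencies Named probabilities over the ten strata
#'   (default [pooled_frequencies()]); must sum to 1 within 1e-9.
#' @param ratio_medians Named geometric medians of E/DMT per stratum.
#' @param target_r2 Target fraction of variance of log(E/DMT) explained by
#'   diplotype; used to calibrate `ratio_sdlog` when that is `NULL`.
#' @param ratio_sdlog Base log-scale SD of E/DMT noise; `NULL` (default)
#'   means "calibrate from `target_r2`" via [calibrate_ratio_sdlog()].
#' @param ratio_sdlog_scale Named per-stratum multipliers on the base
#'   noise SD. The defaults encode the narrowing of phenotypic spread
#'   with functional impairment (reduced-activity strata scatter less).
#' @param tam_median_ngml,tam_sdlog Tamoxifen plasma concentration model
#'   (geometric median ng/mL, log-SD).
#' @param dmt_tam_median,dmt_tam_sdlog DMT/TAM ratio model; the median is
#'   anchored at the CYP3A5 \*1/\*1 wild type (carriers of \*3 sit below it
#'   via the covariate multiplier).
#' @param ohtam_tam_median,ohtam_tam_sdlog 4OH-TAM/TAM ratio model.
#' @param cyp3a5_freq Allele frequencies for CYP3A5 (`*1`, `*3`).
#' @param cyp3a5_dmt_multiplier Multiplier on DMT/TAM for CYP3A5 *3/*3
#'   (heterozygotes get its square root).
#' @param cyp2c9_freq Allele frequencies for CYP2C9 (`*1`, `*2`, `*3`).
#' @param cyp2c9_ohtam_multiplier Multiplier on 4OH-TAM/TAM for CYP2C9
#'   variant homozygotes.
#' @param age_mean,age_sd,age_range Age model (normal, truncated), years.
#' @param ethnicity_freq Named sampling frequencies for the ethnicity
#'   label.
#' @param compliance_threshold_nM Tamoxifen compliance threshold (nM).
#' @return A `cohort_config` object (validated list).
#' @export
#' @examples
#' cfg <- cohort_config()
#' round(calibrate_ratio_sdlog(cfg), 3)
cohort_config <- function(diplotype_frequencies = pooled_frequencies(),
                          ratio_medians = .default_ratio_medians(),
                          target_r2 = 0.75,
                          ratio_sdlog = NULL,
                          ratio_sdlog_scale = .default_ratio_sdlog_scale(),
                          tam_median_ngml = 120, tam_sdlog = 0.30,
                          dmt_tam_median = 1.66, dmt_tam_sdlog = 0.20,
                          ohtam_tam_median = 0.015, ohtam_tam_sdlog = 0.20,
                          cyp3a5_freq = c("*1" = 0.2, "*3" = 0.8),
                          cyp3a5_dmt_multiplier = 0.88,
                          cyp2c9_freq = c("*1" = 0.80, "*2" = 0.13, "*3" = 0.07),
                          cyp2c9_ohtam_multiplier = 0.74,
                          age_mean = 48, age_sd = 9, age_range = c(25, 85),
                          ethnicity_freq = c(Caucasian = 0.747,
                                             Asian = 0.168, Arab = 0.085),
                          compliance_threshold_nM = 150) {
  cfg <- list(
    diplotype_frequencies = diplotype_frequencies,
    ratio_medians = ratio_medians,
    ratio_sdlog_scale = ratio_sdlog_scale,
    target_r2 = target_r2, ratio_sdlog = ratio_sdlog,
    tam_median_ngml = tam_median_ngml, tam_sdlog = tam_sdlog,
    dmt_tam_median = dmt_tam_median, dmt_tam_sdlog = dmt_tam_sdlog,
    ohtam_tam_median = ohtam_tam_median, ohtam_tam_sdlog = ohtam_tam_sdlog,
    cyp3a5_freq = cyp3a5_freq,
    cyp3a5_dmt_multiplier = cyp3a5_dmt_multiplier,
    cyp2c9_freq = cyp2c9_freq,
    cyp2c9_ohtam_multiplier = cyp2c9_ohtam_multiplier,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    ethnicity_freq = ethnicity_freq,
    compliance_threshold_nM = compliance_threshold_nM
  )
  .validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

.validate_cohort_config <- function(cfg) {
  f <- cfg$diplotype_frequencies
  if (abs(sum(f) - 1) > 1e-9) {
    stop("diplotype_frequencies must sum to 1 (got ", format(sum(f)), ")",
         call. = FALSE)
  }
  if (any(f < 0)) stop("diplotype_frequencies must be non-negative",
                       call. = FALSE)
  known <- diplotype_table()$label
  bad <- setdiff(names(f), known)
  if (length(bad)) stop("unknown diplotype stratum in frequencies: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  pos <- c("tam_median_ngml", "dmt_tam_median", "ohtam_tam_median")
  for (p in pos) if (cfg[[p]] <= 0) stop(p, " must be > 0", call. = FALSE)
  sds <- c("tam_sdlog", "dmt_tam_sdlog", "ohtam_tam_sdlog")
  for (p in sds) if (cfg[[p]] < 0) stop(p, " must be >= 0", call. = FALSE)
  if (!is.null(cfg$ratio_sdlog) && cfg$ratio_sdlog < 0) {
    stop("ratio_sdlog must be >= 0", call. = FALSE)
  }
  if (any(cfg$ratio_medians <= 0)) {
    stop("ratio_medians must be strictly positive", call. = FALSE)
  }
  if (!is.null(cfg$target_r2) &&
      (cfg$target_r2 <= 0 || cfg$target_r2 > 1)) {
    stop("target_r2 must be in (0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  strata:", length(x$diplotype_frequencies),
      "| target R2(log E/DMT ~ diplotype):",
      if (is.null(x$ratio_sdlog)) format(x$target_r2)
      else sprintf("(fixed sdlog %.3f)", x$ratio_sdlog), "\n")
  cat("  TAM median", x$tam_median_ngml, "ng/mL, compliance >",
      x$compliance_threshold_nM, "nM\n")
  invisible(x)
}

#' Calibrate the E/DMT log-noise to a variance-explained target
#'
#' Under the log-normal model, log(E/DMT) = log median(stratum) + noise
#' with per-stratum noise SD `scale_i * sigma`. The moment calibration
#' solves the ordinary variance decomposition: the explained fraction is
#' `V / (V + sigma^2 * sum(f_i * scale_i^2))` with `V` the
#' frequency-weighted variance of the stratum log-medians, giving
#' `sigma = sqrt(V * (1 - R2) / (R2 * sum(f_i * scale_i^2)))`.
#'
#' The default (`method = "robust"`) instead targets the quantity the
#' analysis pipeline reports — the bisquare-weighted coefficient of
#' determination of [robust_adjusted_r2()] — whose population value under
#' a heteroscedastic noise mixture sits slightly above the ordinary
#' fraction (the redescending weights suppress the wide-noise strata).
#' That population value is computed by numerical integration of the
#' weight function over each stratum's Gaussian residual law (with the
#' residual scale taken as the population MAD, matching the fitting
#' scale), and the base SD solving `R2_robust(sigma) = target` is found
#' with [stats::uniroot()]; the moment solution serves as the bracket.
#'
#' @param config A [cohort_config()].
#' @param target_r2 Variance-explained target; defaults to the config's.
#' @param method `"robust"` (default; matches the robust estimator) or
#'   `"moment"` (ordinary variance decomposition, closed form).
#' @return The calibrated base log-scale noise SD.
#' @export
calibrate_ratio_sdlog <- function(config, target_r2 = config$target_r2,
                                  method = c("robust", "moment")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "cohort_config"),
            target_r2 > 0, target_r2 <= 1)
  f <- unname(config$diplotype_frequencies)
  mu <- log(config$ratio_medians[names(config$diplotype_frequencies)])
  if (anyNA(mu)) {
    stop("ratio_medians missing for stratum: ",
         paste(names(config$diplotype_frequencies)[is.na(mu)],
               collapse = ", "), call. = FALSE)
  }
  mu <- unname(mu)
  sc <- .ratio_scale(config, names(config$diplotype_frequencies))
  m <- sum(f * mu)
  v_between <- sum(f * (mu - m)^2)
  sigma_moment <- sqrt(v_between * (1 - target_r2) /
                         (target_r2 * sum(f * sc^2)))
  if (method == "moment" || target_r2 == 1) return(sigma_moment)
  obj <- function(sigma) {
    .population_robust_r2(mu, f, pmax(sigma * sc, 1e-12)) - target_r2
  }
  stats::uniroot(obj, lower = sigma_moment / 8, upper = sigma_moment * 8,
                 tol = 1e-8)$root
}

## Population value of the bisquare-weighted R2 when the response is a
## Gaussian scale mixture around stratum means mu with weights f and
## per-stratum residual SDs s.  The weight argument uses the population
## MAD-based scale, as in the IRLS fit.
.population_robust_r2 <- function(mu, f, s) {
  ## population MAD of the residual mixture
  med_abs <- stats::uniroot(function(m) {
    sum(f * (2 * stats::pnorm(m / s) - 1)) - 0.5
  }, lower = 1e-9, upper = 10 * max(s), tol = 1e-10)$root
  shat <- med_abs / 0.6745
  cc <- .BISQUARE_C * shat
  ## E[w] and E[w r^2] for r ~ N(0, s_i), w = (1 - (r/cc)^2)^2 on |r|<cc
  ew <- numeric(length(s)); ewr2 <- numeric(length(s))
  for (i in seq_along(s)) {
    dens <- function(r) stats::dnorm(r, sd = s[i])
    w <- function(r) (1 - (r / cc)^2)^2
    ew[i] <- stats::integrate(function(r) w(r) * dens(r), -cc, cc,
                              rel.tol = 1e-10)$value
    ewr2[i] <- stats::integrate(function(r) w(r) * r^2 * dens(r), -cc, cc,
                                rel.tol = 1e-10)$value
  }
  ybar <- sum(f * ew * mu) / sum(f * ew)
  num <- sum(f * ewr2)
  den <- sum(f * ((mu - ybar)^2 * ew + ewr2))
  1 - num / den
}

.ratio_scale <- function(config, labels) {
  sc <- config$ratio_sdlog_scale
  if (is.null(sc)) return(rep(1, length(labels)))
  out <- sc[labels]
  out[is.na(out)] <- 1
  unname(out)
}

.ratio_sdlog <- function(config) {
  if (!is.null(config$ratio_sdlog)) config$ratio_sdlog
  else calibrate_ratio_sdlog(config)
}

## deterministic per-stage seed streams derived from one root seed
.derive_seed <- function(root, stream) {
  s <- (as.numeric(root) %% 2147483647) * 48271 + stream * 7919
  as.integer(s %% 2147483647) + 1L
}

#' Sample diplotypes for a synthetic cohort
#'
#' Mode `"category"` draws the ten diplotype strata directly from the
#' configured frequencies and instantiates the fixed representative allele
#' pair of each stratum. Mode `"hardy_weinberg"` draws two alleles per
#' patient independently from supplied allele frequencies (random union of
#' gametes) and categorizes the resulting pair.
#'
#' @param config A [cohort_config()].
#' @param n Number of patients.
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @param mode `"category"` or `"hardy_weinberg"`.
#' @param allele_freq Named allele frequencies over
#'   [supported_alleles()] (mode `"hardy_weinberg"` only); must sum to 1.
#' @return A data frame as returned by [parse_diplotype()].
#' @export
#' @examples
#' head(sample_diplotypes(cohort_config(), 5, seed = 1))
sample_diplotypes <- function(config, n, seed = 1L,
                              mode = c("category", "hardy_weinberg"),
                              allele_freq = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "cohort_config"), n >= 0)
  set.seed(seed)
  if (mode == "category") {
    strata <- .disjoint_strata()
    f <- config$diplotype_frequencies
    strata <- strata[strata$label %in% names(f), ]
    prob <- unname(f[strata$label])
    idx <- sample.int(nrow(strata), n, replace = TRUE, prob = prob)
    dip <- strata$representative[idx]
  } else {
    if (is.null(allele_freq)) {
      stop("hardy_weinberg mode needs allele_freq", call. = FALSE)
    }
    bad <- setdiff(names(allele_freq), names(supported_alleles()))
    if (length(bad)) stop("unsupported allele in allele_freq: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (abs(sum(allele_freq) - 1) > 1e-9) {
      stop("allele_freq must sum to 1 (got ", format(sum(allele_freq)), ")",
           call. = FALSE)
    }
    a <- sample(names(allele_freq), n, replace = TRUE, prob = allele_freq)
    b <- sample(names(allele_freq), n, replace = TRUE, prob = allele_freq)
    dip <- paste0(a, "/", b)
  }
  out <- parse_diplotype(dip)
  rownames(out) <- NULL
  out
}

.sample_genotype <- function(n, freq) {
  a <- sample(names(freq), n, replace = TRUE, prob = freq)
  b <- sample(names(freq), n, replace = TRUE, prob = freq)
  ## canonical order so *1/*3 and *3/*1 read the same
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  paste0(a, "/", b)
}

#' Genotype class of a covariate gene
#'
#' Collapses a genotype string such as `"*1/*3"` into the three classes
#' used for covariate adjustment: `"wt"` (\*1/\*1), `"het"` (one variant
#' allele) and `"hom"` (two variant alleles).
#'
#' @param genotype Character vector of `"A/B"` genotype strings.
#' @param wild Wild-type allele name (default `"*1"`).
#' @return Character vector in `{"wt", "het", "hom"}`.
#' @export
genotype_class <- function(genotype, wild = "*1") {
  parts <- strsplit(genotype, "/", fixed = TRUE)
  nvar <- vapply(parts, function(p) sum(p != wild), integer(1))
  c("wt", "het", "hom")[nvar + 1L]
}

#' Attach covariates and metabolite concentrations to sampled diplotypes
#'
#' Draws the log-normal metabolite cascade: tamoxifen (TAM), then DMT and
#' 4OH-TAM via ratio models carrying the CYP3A5 and CYP2C9 covariate
#' multipliers (heterozygotes receive the square root of the homozygote
#' multiplier), then endoxifen via the diplotype-stratum E/DMT model whose
#' log-noise SD is [calibrate_ratio_sdlog()]-calibrated unless fixed in
#' the config. Demographics (age, ethnicity, menopausal status at the
#' 50-year boundary) are added.
#'
#' @param diplotypes Data frame from [sample_diplotypes()].
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A `cohort` data frame (one row per patient) with genotype,
#'   demographic and concentration columns (`tam_ngml`, `dmt_ngml`,
#'   `ohtam_ngml`, `e_ngml`); attributes `config`, `seed`, `ratio_sdlog`.
#' @export
sample_metabolites <- function(diplotypes, config, seed = 1L) {
  stopifnot(is.data.frame(diplotypes), inherits(config, "cohort_config"))
  n <- nrow(diplotypes)
  mu <- config$ratio_medians[diplotypes$label]
  if (anyNA(mu)) {
    stop("no E/DMT median configured for stratum: ",
         paste(unique(diplotypes$label[is.na(mu)]), collapse = ", "),
         call. = FALSE)
  }
  sdlog <- .ratio_sdlog(config)
  set.seed(seed)

  cyp3a5 <- .sample_genotype(n, config$cyp3a5_freq)
  cyp2c9 <- .sample_genotype(n, config$cyp2c9_freq)
  cl3a5 <- genotype_class(cyp3a5)
  cl2c9 <- genotype_class(cyp2c9)
  mult3a5 <- config$cyp3a5_dmt_multiplier ^
    (c(wt = 0, het = 0.5, hom = 1)[cl3a5])
  mult2c9 <- config$cyp2c9_ohtam_multiplier ^
    (c(wt = 0, het = 0.5, hom = 1)[cl2c9])

  age <- round(pmin(pmax(rnorm(n, config$age_mean, config$age_sd),
                         config$age_range[1]), config$age_range[2]), 1)
  ethnicity <- if (n > 0) {
    sample(names(config$ethnicity_freq), n, replace = TRUE,
           prob = config$ethnicity_freq)
  } else character(0)

  tam <- rlnorm(n, log(config$tam_median_ngml), config$tam_sdlog)
  r_dmt <- config$dmt_tam_median * unname(mult3a5) *
    rlnorm(n, 0, config$dmt_tam_sdlog)
  r_oh <- config$ohtam_tam_median * unname(mult2c9) *
    rlnorm(n, 0, config$ohtam_tam_sdlog)
  dmt <- tam * r_dmt
  ohtam <- tam * r_oh
  e <- dmt * unname(mu) *
    rlnorm(n, 0, sdlog * .ratio_scale(config, diplotypes$label))

  out <- data.frame(
    id = if (n > 0) sprintf("P%05d", seq_len(n)) else character(0),
    diplotypes,
    cyp2c9 = cyp2c9, cyp2c9_class = cl2c9,
    cyp3a5 = cyp3a5, cyp3a5_class = cl3a5,
    ethnicity = ethnicity, age = age,
    menopause = ifelse(age >= 50, "post", "pre"),
    tam_ngml = tam, dmt_ngml = dmt, ohtam_ngml = ohtam, e_ngml = e,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort", "data.frame")
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  attr(out, "ratio_sdlog") <- sdlog
  out
}

#' Remove presumptively non-adherent patients
#'
#' Retains records whose tamoxifen plasma concentration is strictly above
#' the compliance threshold (in nM; concentrations are converted from
#' ng/mL with the tamoxifen molar mass). A record at exactly the
#' threshold is removed.
#'
#' @param records A `cohort` data frame with a `tam_ngml` column.
#' @param threshold_nM Threshold in nmol/L (default 150).
#' @return The filtered data frame; attribute `compliance` records
#'   `n_in`, `n_kept`, `n_removed` and the threshold.
#' @export
apply_compliance_filter <- function(records, threshold_nM = 150) {
  stopifnot(is.data.frame(records), "tam_ngml" %in% names(records))
  tam_nM <- ngml_to_nmol(records$tam_ngml, "TAM")
  keep <- tam_nM > threshold_nM
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("config", "seed", "ratio_sdlog")) {
    attr(out, a) <- attr(records, a)
  }
  class(out) <- class(records)
  attr(out, "compliance") <- list(
    n_in = nrow(records), n_kept = sum(keep), n_removed = sum(!keep),
    threshold_nM = threshold_nM)
  out
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: [sample_diplotypes()] then [sample_metabolites()]
#' then (optionally) [apply_compliance_filter()], with per-stage seeds
#' derived deterministically from one root seed.
#'
#' @inheritParams sample_diplotypes
#' @param filter_compliance Apply the tamoxifen compliance filter?
#' @return A `cohort` data frame (see [sample_metabolites()]).
#' @export
#' @examples
#' co <- simulate_cohort(n = 50, seed = 42)
#' table(co$category)
simulate_cohort <- function(config = cohort_config(), n, seed = 1L,
                            filter_compliance = TRUE,
                            mode = c("category", "hardy_weinberg"),
                            allele_freq = NULL) {
  dip <- sample_diplotypes(config, n, seed = .derive_seed(seed, 1L),
                           mode = mode, allele_freq = allele_freq)
  co <- sample_metabolites(dip, config, seed = .derive_seed(seed, 2L))
  if (filter_compliance) {
    co <- apply_compliance_filter(co, config$compliance_threshold_nM)
  }
  attr(co, "root_seed") <- seed
  co
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients\n", nrow(x)))
  comp <- attr(x, "compliance")
  if (!is.null(comp)) {
    cat(sprintf("  compliance filter (> %g nM TAM): %d of %d removed\n",
                comp$threshold_nM, comp$n_removed, comp$n_in))
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
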