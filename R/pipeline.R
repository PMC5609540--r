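## End-to-end orchestration: generate or load a cohort, score diplotypes,
## assign phenotypes, fit robust association models per scheme, compare
## schemes, classify against the clinical threshold, and write artifacts.

#' Write a cohort to CSV
#'
#' Writes the patient table with a `# seed:` header comment recording the
#' generator seed (when present).
#'
#' @param cohort A `cohort` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(cohort, "root_seed")
  if (is.null(seed)) seed <- attr(cohort, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  write.csv(as.data.frame(cohort), con, row.names = FALSE)
  invisible(path)
}

.REQUIRED_COHORT_COLUMNS <- c("diplotype", "cyp2c9", "cyp3a5",
                              "tam_ngml", "dmt_ngml", "e_ngml")

#' Read and validate a cohort CSV
#'
#' Parses the diplotype strings through the star-allele model and
#' validates the genotype fields. Rows with unresolvable diplotypes or
#' malformed genotypes are excluded and counted, with the reason
#' retained, so that rows-in always equals records-used plus rejected.
#'
#' @param path CSV file with at least the columns `diplotype`, `cyp2c9`,
#'   `cyp3a5`, `tam_ngml`, `dmt_ngml`, `e_ngml` (plus optional `id`,
#'   `ohtam_ngml`, `ethnicity`, `age`). Lines starting with `#` are
#'   treated as comments.
#' @param no_variant Sentinel allele for "no variant detected".
#' @return A `cohort` data frame; attribute `validation` is a list with
#'   `rows_in`, `used`, `rejected` and a data frame of `rejections`
#'   (row number + reason).
#' @export
read_cohort_csv <- function(path, no_variant = "*1") {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(.REQUIRED_COHORT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows_in <- nrow(raw)
  rejections <- data.frame(row = integer(0), reason = character(0),
                           stringsAsFactors = FALSE)
  parsed <- vector("list", rows_in)
  for (i in seq_len(rows_in)) {
    parsed[[i]] <- tryCatch(
      parse_diplotype(raw$diplotype[i], no_variant = no_variant),
      error = function(e) conditionMessage(e))
    if (is.character(parsed[[i]])) {
      rejections <- rbind(rejections, data.frame(
        row = i, reason = parsed[[i]], stringsAsFactors = FALSE))
    }
  }
  ok <- !vapply(parsed, is.character, logical(1))
  ## numeric sanity on concentrations
  for (col in c("tam_ngml", "dmt_ngml", "e_ngml")) {
    bad <- ok & (!is.finite(raw[[col]]) | raw[[col]] < 0)
    if (any(bad)) {
      rejections <- rbind(rejections, data.frame(
        row = which(bad), reason = paste0("invalid ", col),
        stringsAsFactors = FALSE))
      ok[bad] <- FALSE
    }
  }
  dip <- do.call(rbind, parsed[ok])
  kept <- raw[ok, setdiff(names(raw), "diplotype"), drop = FALSE]
  out <- cbind(dip, kept)
  if (!"id" %in% names(out)) {
    out$id <- sprintf("P%05d", seq_len(nrow(out)))
  }
  if (!"ohtam_ngml" %in% names(out)) out$ohtam_ngml <- NA_real_
  out$cyp2c9_class <- genotype_class(out$cyp2c9)
  out$cyp3a5_class <- genotype_class(out$cyp3a5)
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  attr(out, "validation") <- list(rows_in = rows_in, used = sum(ok),
                                  rejected = rows_in - sum(ok),
                                  rejections = rejections)
  out
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.log_stage <- function(level, stage, ..., log_level = "info") {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[level]] <= levels[[log_level]]) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste(..., collapse = " ")))
  }
}

#' Run the full genotype-to-endoxifen pipeline
#'
#' Orchestrates: cohort acquisition (synthetic generation or CSV load),
#' compliance filtering, frequency tabulation, per-scheme robust
#' association with bootstrap R-squared intervals for the requested
#' endpoints, covariate screening, nested-model scheme comparisons, and
#' ROC/Youden threshold classification with bootstrap metric intervals.
#' All stochastic stages run on streams derived from one root seed, and
#' every artifact records the configuration hash.
#'
#' @param input `"synthetic"` or a path to a cohort CSV.
#' @param cohort_config A [cohort_config()] (synthetic mode).
#' @param n Cohort size before compliance filtering (synthetic mode).
#' @param schemes Scheme names to evaluate (default all registered).
#' @param endpoints Endpoints to model (default both).
#' @param replicates Bootstrap replicates for both bootstrap stages.
#' @param seed Root seed.
#' @param out_dir Output directory for artifacts, or `NULL` for none.
#' @param threshold_ngml Clinical endoxifen threshold (ng/mL).
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return A `pipeline_report` list: `cohort`, `frequency_table`,
#'   `associations` (per endpoint x predictor), `covariate_screen`,
#'   `scheme_comparisons`, `classifier`, `roc`, `config_hash`, `seed`.
#' @export
#' @examples
#' rep <- run_pipeline(n = 200, replicates = 50, seed = 11,
#'                     schemes = c("Codeine", "TAM4"), endpoints = "E_over_DMT")
#' rep$classifier
run_pipeline <- function(input = "synthetic",
                         cohort_config = endoxpred::cohort_config(),
                         n = 900,
                         schemes = scheme_names(),
                         endpoints = c("E_over_DMT", "E"),
                         replicates = 1000L,
                         seed = 1L,
                         out_dir = NULL,
                         threshold_ngml = CLINICAL_THRESHOLD_NGML,
                         log_level = "info") {
  stopifnot(replicates >= 1, length(schemes) >= 1, length(endpoints) >= 1)
  endpoints <- match.arg(endpoints, c("E_over_DMT", "E"), several.ok = TRUE)
  unknown <- setdiff(schemes, scheme_names())
  if (length(unknown)) {
    stop("unknown scheme(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  run_config <- list(input = input, n = n, schemes = schemes,
                     endpoints = endpoints, replicates = replicates,
                     seed = seed, threshold_ngml = threshold_ngml)
  hash <- .config_hash(run_config)
  t0 <- Sys.time()

  if (identical(input, "synthetic")) {
    cohort <- simulate_cohort(cohort_config, n = n,
                              seed = .derive_seed(seed, 101L))
    .log_stage("info", "cohort", sprintf(
      "synthetic n=%d (of %d generated) seed=%d", nrow(cohort), n, seed),
      log_level = log_level)
  } else {
    cohort <- read_cohort_csv(input)
    val <- attr(cohort, "validation")
    cohort <- apply_compliance_filter(
      cohort, cohort_config$compliance_threshold_nM)
    .log_stage("info", "cohort", sprintf(
      "file %s: %d rows, %d used, %d rejected, %d non-compliant removed",
      input, val$rows_in, val$used, val$rejected,
      attr(cohort, "compliance")$n_removed), log_level = log_level)
  }

  freq <- frequency_table(cohort)

  predictors <- c("diplotype", schemes)
  associations <- list()
  for (ep in endpoints) {
    for (pr in predictors) {
      key <- paste(ep, pr, sep = ".")
      associations[[key]] <- bootstrap_r2_ci(
        cohort, endpoint = ep, predictor = pr, replicates = replicates,
        seed = .derive_seed(seed, 211L + length(associations)))
      .log_stage("debug", "associate", key, log_level = log_level)
    }
  }
  .log_stage("info", "associate", sprintf(
    "%d models x %d bootstrap replicates", length(associations), replicates),
    log_level = log_level)

  screen <- covariate_effect_screen(cohort)

  comparisons <- list()
  if (length(schemes) >= 2) {
    for (i in seq_along(schemes)) {
      for (j in seq_along(schemes)) {
        if (i == j) next
        f1 <- fit_robust_linear(cohort, endpoints[1], schemes[i])
        d2 <- .build_design(cohort, endpoints[1], schemes[j],
                            covariates = FALSE)
        ## a second phenotype assignment typically shares levels with the
        ## first (e.g. the UM class), so drop aliased columns before fitting
        X2 <- .drop_aliased(cbind(f1$X, d2$X[, -1, drop = FALSE]))
        key <- paste(schemes[i], schemes[j], sep = "+")
        if (ncol(X2) == ncol(f1$X)) {
          comparisons[[key]] <- list(statistic = 0, df = 0L, p_value = NA_real_,
                                     note = "second assignment adds no information")
          next
        }
        f12 <- tryCatch({
          fit <- .robust_irls(X2, f1$y)
          structure(c(fit, list(y = f1$y, X = X2, n = nrow(X2),
                                p = ncol(X2))), class = "robust_fit")
        }, error = function(e) NULL)
        if (is.null(f12)) next
        comparisons[[key]] <- compare_models_deviance(f1, f12)
      }
    }
  }

  outcomes <- binarize_outcome(cohort, threshold_ngml)
  roc <- roc_diplotype_ranks(outcomes)
  best <- youden_optimal_cutoff(roc)
  classifier <- bootstrap_metric_ci(outcomes, best$cutoff,
                                    replicates = replicates,
                                    seed = .derive_seed(seed, 311L))
  .log_stage("info", "classify", sprintf(
    "cutoff %s, sens %.3f spec %.3f", best$label,
    classifier$point$sensitivity, classifier$point$specificity),
    log_level = log_level)

  report <- structure(
    list(cohort = cohort, frequency_table = freq,
         associations = associations, covariate_screen = screen,
         scheme_comparisons = comparisons,
         classifier = classifier, roc = roc,
         config = run_config, config_hash = hash, seed = seed,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    fr <- freq; fr$config_hash <- hash
    write.csv(fr, file.path(out_dir, "frequency_table.csv"),
              row.names = FALSE)
    write.csv(cbind(roc, config_hash = hash),
              file.path(out_dir, "roc_points.csv"), row.names = FALSE)
    summary <- list(
      config = run_config, config_hash = hash,
      n_patients = nrow(cohort),
      associations = lapply(associations, function(a) {
        list(endpoint = a$endpoint, predictor = a$predictor,
             r2 = a$estimate, boot_median = a$boot_median,
             ci = a$ci, n = a$n, replicates = a$replicates, seed = a$seed)
      }),
      covariate_screen = screen,
      scheme_comparisons = comparisons,
      classifier = list(
        cutoff = classifier$point$cutoff, label = classifier$point$label,
        sensitivity = classifier$point$sensitivity,
        specificity = classifier$point$specificity,
        fdr = classifier$point$fdr,
        positive_fraction = classifier$point$positive_fraction,
        ci = as.data.frame(classifier$ci),
        replicates = classifier$replicates, seed = classifier$seed)
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (config %s, seed %d)\n",
              substr(x$config_hash, 1, 8), x$seed))
  cat(sprintf("  %d patients; %d association models; cutoff %s\n",
              nrow(x$cohort), length(x$associations),
              x$classifier$point$label))
  for (key in names(x$associations)) {
    a <- x$associations[[key]]
    cat(sprintf("  R2[%s] = %.1f%% (%.1f-%.1f%%)\n", key, 100 * a$estimate,
                100 * a$ci[1], 100 * a$ci[2]))
  }
  invisible(x)
}
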