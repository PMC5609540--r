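# Frozen reference values for the canonical diplotype table: activity
# scores, cohort composition and the five phenotype assignment columns.
diplotype_reference <- function() {
  data.frame(
    label = c("EM/UM", "EM/EM", "EM/IM", "EM/*10", "EM/PM",
              "IM/IM", "*10/*10", "IM/PM", "PM/*10", "PM/PM"),
    as_standard = c(3, 2, 1.5, 1.5, 1, 1, 1, 0.5, 0.5, 0),
    as_star10 = c(3, 2, 1.5, 1.25, 1, 1, 0.5, 0.5, 0.25, 0),
    count = c(18L, 300L, 168L, 60L, 221L, 68L, 45L, 73L, 19L, 50L),
    percent = c(2.0, 33.4, 18.7, 6.7, 24.6, 7.6, 5.0, 8.1, 2.1, 5.6),
    Codeine = c("UM", "EM", "EM", "EM", "EM", "EM", "EM", "IM", "IM", "PM"),
    TAM1 = c("UM", "EM", "IM", "IM", "IM", "IM", "IM", "IM", "IM", "PM"),
    TAM2 = c("UM", "EM", "EM", "EM", "IM", "IM", "IM", "PM", "PM", "PM"),
    TAM3 = c("UM", "EM", "EM", "IM", "IM", "IM", "IM", "IM", "PM", "PM"),
    TAM4 = c("UM", "EM", "EM", "EM", "IM", "IM", "SM", "SM", "SM", "PM"),
    stringsAsFactors = FALSE
  )
}

# A vector of category labels reproducing the full study composition.
reference_cohort_labels <- function() {
  ref <- diplotype_reference()
  # generic rows contribute count minus their nested refinement
  nested_in <- c("EM/*10" = "EM/IM", "*10/*10" = "IM/IM", "PM/*10" = "IM/PM")
  n <- setNames(ref$count, ref$label)
  for (r in names(nested_in)) n[nested_in[[r]]] <- n[nested_in[[r]]] - n[r]
  rep(names(n), n)
}

# Random threshold outcomes over the seven activity levels.
random_outcomes <- function(n, seed) {
  set.seed(seed)
  lv <- c(3, 2, 1.5, 1, 0.75, 0.5, 0)
  act <- sample(lv, n, replace = TRUE)
  p <- runif(1, 0.2, 0.8)
  above <- runif(n) < plogis(act - 1) * p + 0.1
  # ROC needs both outcome classes
  if (all(above)) above[1] <- FALSE
  if (!any(above)) above[1] <- TRUE
  out <- data.frame(id = seq_len(n), above = above, activity = act)
  class(out) <- c("threshold_outcomes", "data.frame")
  out
}

# Small deterministic cohort for fast model tests.
tiny_cohort <- function(n = 300, seed = 1, ...) {
  simulate_cohort(cohort_config(...), n = n, seed = seed)
}
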