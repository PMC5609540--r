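#' Supported CYP2D6 star alleles and their functional classes
#'
#' @return Named character vector mapping star-allele name to functional
#'   class (`"PM"`, `"IM"` or `"EM"`).
#' @export
#' @examples
#' supported_alleles()
supported_alleles <- function() .ALLELE_CLASS

#' Classify a CYP2D6 star allele
#'
#' Assigns the functional class of a star allele: null function (PM: *3,
#' *4, *5, *6, *7), reduced function (IM: *9, *10, *41) or full function
#' (EM: *1, *2, *35, and the no-variant-detected sentinel, by default *1).
#' A gene duplication is ultra-rapid-driving only when it sits on a fully
#' functional allele; a duplicated null allele is scored as the
#' un-duplicated null, and a duplicated reduced-function allele is rejected
#' because its activity is not defined by the scoring system.
#'
#' @param name Star-allele name, e.g. `"*4"`.
#' @param duplicated Logical; does this allele carry a gene duplication?
#' @param no_variant Sentinel name used when genotyping detects no variant
#'   allele (treated as EM). Default `"*1"`.
#' @return An object of class `star_allele`: a list with `name`,
#'   `functional_class`, `duplicated` and `um_driving` (a duplicated EM
#'   allele, eligible to form an EM/UM diplotype).
#' @export
#' @examples
#' classify_allele("*4")
#' classify_allele("*1", duplicated = TRUE)
classify_allele <- function(name, duplicated = FALSE, no_variant = "*1") {
  stopifnot(length(name) == 1L, is.character(name), length(duplicated) == 1L)
  name <- trimws(name)
  if (identical(name, "") || is.na(name)) {
    stop("unsupported allele: empty allele name", call. = FALSE)
  }
  if (!name %in% names(.ALLELE_CLASS)) {
    stop(sprintf("unsupported allele: '%s' is not in the supported panel (%s)",
                 name, paste(names(.ALLELE_CLASS), collapse = ", ")),
         call. = FALSE)
  }
  cls <- unname(.ALLELE_CLASS[[name]])
  if (duplicated && cls == "IM") {
    stop(sprintf(
      "unsupported allele: duplicated reduced-function allele '%s' has no defined activity",
      name), call. = FALSE)
  }
  structure(
    list(name = name, functional_class = cls,
         duplicated = isTRUE(duplicated),
         um_driving = isTRUE(duplicated) && cls == "EM"),
    class = "star_allele"
  )
}

#' @export
print.star_allele <- function(x, ...) {
  cat(sprintf("CYP2D6 allele %s%s [%s%s]\n", x$name,
              if (x$duplicated) " (duplicated)" else "",
              x$functional_class,
              if (x$um_driving) ", UM-driving" else ""))
  invisible(x)
}

.as_star_allele <- function(x, no_variant = "*1") {
  if (inherits(x, "star_allele")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  dup <- grepl("x[0-9]+$", x)
  name <- sub("x[0-9]+$", "", x)
  classify_allele(name, duplicated = dup, no_variant = no_variant)
}

#' Determine the diplotype category of two star alleles
#'
#' Combines the functional classes of two alleles into the diplotype
#' category labels used throughout the package: the seven generic
#' categories EM/UM, EM/EM, EM/IM, EM/PM, IM/IM, IM/PM, PM/PM plus, where
#' applicable, the *10-specific refinements EM/\*10 (an EM paired with
#' \*10), \*10/\*10 (two \*10 alleles) and PM/\*10 (a null allele paired
#' with \*10). Refinements are subsets of their generic class; the generic
#' label is always defined. The category is symmetric in its arguments.
#'
#' An EM allele carrying a gene duplication yields EM/UM only when its
#' partner is also EM; paired with a variant allele the duplication does
#' not confer ultra-rapid status and the diplotype is categorized as the
#' un-duplicated pair.
#'
#' @param a,b `star_allele` objects (from [classify_allele()]) or allele
#'   strings such as `"*4"` or `"*1x2"` (an `xN` suffix marks duplication).
#' @return A list with `category` (generic label), `refined` (refinement
#'   label or `NA`), and `label` (`refined` when present, else `category`).
#' @export
#' @examples
#' diplotype_category("*1", "*4")    # EM/PM
#' diplotype_category("*10", "*10")  # IM/IM, refined *10/*10
diplotype_category <- function(a, b) {
  a <- .as_star_allele(a)
  b <- .as_star_allele(b)
  if (a$um_driving && b$um_driving) {
    stop("unsupported diplotype: two duplicated fully-functional alleles",
         call. = FALSE)
  }
  cls <- c(a$functional_class, b$functional_class)
  nm <- c(a$name, b$name)
  if ((a$um_driving || b$um_driving) && all(cls == "EM")) {
    return(list(category = "EM/UM", refined = NA_character_,
                label = "EM/UM"))
  }
  rank <- c(EM = 1, IM = 2, PM = 3)
  ord <- order(rank[cls])
  cls <- cls[ord]; nm <- nm[ord]
  category <- switch(
    paste(cls, collapse = "/"),
    "EM/EM" = "EM/EM", "EM/IM" = "EM/IM", "EM/PM" = "EM/PM",
    "IM/IM" = "IM/IM", "IM/PM" = "IM/PM", "PM/PM" = "PM/PM"
  )
  refined <- NA_character_
  if (category == "EM/IM" && nm[2] == "*10") refined <- "EM/*10"
  if (category == "IM/IM" && all(nm == "*10")) refined <- "*10/*10"
  if (category == "IM/PM" && nm[1] == "*10") refined <- "PM/*10"
  list(category = category, refined = refined,
       label = if (is.na(refined)) category else refined)
}

#' Parse diplotype strings into a categorized table
#'
#' Parses text diplotypes of the form `"A/B"` with an optional `xN`
#' duplication suffix (e.g. `"*1/*1x2"`, `"*4/*10"`) and returns the
#' category labels, activity scores under both scoring dialects, and the
#' numeric ROC activity.
#'
#' @param x Character vector of diplotype strings.
#' @param no_variant Sentinel allele name standing for "no variant
#'   detected" (default `"*1"`).
#' @return A data frame with one row per input: `diplotype`, `allele_a`,
#'   `allele_b`, `category`, `refined`, `label`, `as_standard`,
#'   `as_star10`, `roc_activity`.
#' @export
#' @examples
#' parse_diplotype(c("*1/*4", "*10/*10", "*1x2/*1"))
parse_diplotype <- function(x, no_variant = "*1") {
  stopifnot(is.character(x))
  ## parse each distinct string once, then expand to the input order
  ux <- unique(x)
  out <- lapply(ux, function(s) {
    parts <- strsplit(trimws(s), "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("malformed diplotype '%s': expected \"A/B\"", s),
           call. = FALSE)
    }
    a <- .as_star_allele(parts[1], no_variant = no_variant)
    b <- .as_star_allele(parts[2], no_variant = no_variant)
    cat <- diplotype_category(a, b)
    data.frame(
      diplotype = s,
      allele_a = a$name, allele_b = b$name,
      category = cat$category, refined = cat$refined, label = cat$label,
      as_standard = .score_pair(a, b, "standard"),
      as_star10 = .score_pair(a, b, "star10_downgrade"),
      roc_activity = unname(.ROC_ACTIVITY[[cat$category]]),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, out)
  res <- tab[match(x, ux), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.score_allele <- function(al, scheme) {
  if (al$um_driving) return(2)
  if (scheme == "star10_downgrade" && al$name == "*10") return(.AS_STAR10)
  unname(.AS_PER_CLASS[[al$functional_class]])
}

.score_pair <- function(a, b, scheme) {
  ## a duplicated EM paired with a variant allele is non-UM: its
  ## duplication is disregarded for scoring
  um_ok <- (a$um_driving || b$um_driving) &&
    a$functional_class == "EM" && b$functional_class == "EM"
  sa <- if (a$um_driving && !um_ok) 1 else .score_allele(a, scheme)
  sb <- if (b$um_driving && !um_ok) 1 else .score_allele(b, scheme)
  sa + sb
}

#' Diplotype activity score
#'
#' Sums the per-allele activity values of a diplotype. Under the
#' `standard` dialect alleles contribute 0 (PM), 0.5 (IM), 1 (EM) or 2
#' (duplicated EM); the `star10_downgrade` dialect additionally lowers the
#' \*10 allele to 0.25, separating it from the other reduced-function
#' alleles.
#'
#' @param x Diplotype string(s) such as `"*1/*41"`, or a data frame from
#'   [parse_diplotype()].
#' @param scheme `"standard"` or `"star10_downgrade"`.
#' @return Numeric vector of diplotype activity scores.
#' @export
#' @examples
#' diplotype_activity_score("*1/*41")                       # 1.5
#' diplotype_activity_score("*1/*10", "star10_downgrade")   # 1.25
diplotype_activity_score <- function(x, scheme = c("standard", "star10_downgrade")) {
  scheme <- match.arg(scheme)
  if (is.character(x)) x <- parse_diplotype(x)
  stopifnot(is.data.frame(x))
  if (scheme == "standard") x$as_standard else x$as_star10
}

#' Numeric ROC activity of a diplotype category
#'
#' Maps diplotype categories to the seven-level numeric activity ordering
#' used for ROC analysis: EM/UM 3 > EM/EM 2 > EM/IM 1.5 > EM/PM 1 >
#' IM/IM 0.75 > IM/PM 0.5 > PM/PM 0. The ordering coincides with the
#' standard activity score except that EM/PM and IM/IM, which both sum to
#' 1, are distinguished by assigning IM/IM the lower value 0.75. \*10
#' refinements inherit the activity of their generic class.
#'
#' @param category Character vector of category labels (generic or
#'   \*10-refined), or a data frame from [parse_diplotype()].
#' @return Numeric vector of ROC activities.
#' @export
#' @examples
#' roc_activity(c("EM/PM", "IM/IM", "*10/*10"))
roc_activity <- function(category) {
  if (is.data.frame(category)) return(category$roc_activity)
  stopifnot(is.character(category))
  gen <- ifelse(category %in% .REFINED_CATEGORIES,
                .REFINEMENT_PARENT[category], category)
  bad <- !gen %in% .GENERIC_CATEGORIES
  if (any(bad)) {
    stop("unknown diplotype category: ",
         paste(unique(category[bad]), collapse = ", "), call. = FALSE)
  }
  unname(.ROC_ACTIVITY[gen])
}

#' Canonical diplotype reference table
#'
#' The ten diplotype rows used throughout the package (seven generic
#' categories plus the three nested \*10 refinements), each with a
#' representative allele pair, activity scores under both dialects, the
#' ROC activity, and the observed cohort composition (counts out of 898)
#' that serves as the default frequency model for the synthetic cohort
#' generator. Refinement rows are subsets of their generic class, so the
#' seven generic counts sum to the total.
#'
#' @return A data frame with columns `label`, `category`, `is_refinement`,
#'   `representative`, `as_standard`, `as_star10`, `roc_activity`,
#'   `count`, `frequency`.
#' @export
#' @examples
#' diplotype_table()
diplotype_table <- function() {
  df <- data.frame(
    label = c("EM/UM", "EM/EM", "EM/IM", "EM/*10", "EM/PM",
              "IM/IM", "*10/*10", "IM/PM", "PM/*10", "PM/PM"),
    category = c("EM/UM", "EM/EM", "EM/IM", "EM/IM", "EM/PM",
                 "IM/IM", "IM/IM", "IM/PM", "IM/PM", "PM/PM"),
    is_refinement = c(FALSE, FALSE, FALSE, TRUE, FALSE,
                      FALSE, TRUE, FALSE, TRUE, FALSE),
    representative = c("*1x2/*1", "*1/*1", "*1/*41", "*1/*10", "*1/*4",
                       "*41/*41", "*10/*10", "*4/*41", "*4/*10", "*4/*4"),
    count = c(18L, 300L, 168L, 60L, 221L, 68L, 45L, 73L, 19L, 50L),
    stringsAsFactors = FALSE
  )
  parsed <- parse_diplotype(df$representative)
  df$as_standard <- parsed$as_standard
  df$as_star10 <- parsed$as_star10
  df$roc_activity <- parsed$roc_activity
  df$frequency <- df$count / sum(df$count[!df$is_refinement])
  df[, c("label", "category", "is_refinement", "representative",
         "as_standard", "as_star10", "roc_activity", "count", "frequency")]
}
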