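## The five diplotype -> metabolizer-phenotype assignment schemes.
## Schemes are data, not code: each is a named mapping from diplotype
## category (generic, plus *10 refinements where the scheme distinguishes
## them) to a phenotype label.  The binning choice is the experimental
## variable this package exists to study, so users can register their own.

.PHENOTYPE_ORDINAL <- c(PM = 0, SM = 1, IM = 2, EM = 3, UM = 4)

.builtin_schemes <- function() {
  list(
    Codeine = list(
      name = "Codeine", uses_star10_refinement = FALSE,
      mapping = c("EM/UM" = "UM", "EM/EM" = "EM", "EM/IM" = "EM",
                  "EM/PM" = "EM", "IM/IM" = "EM", "IM/PM" = "IM",
                  "PM/PM" = "PM")
    ),
    TAM1 = list(
      name = "TAM1", uses_star10_refinement = FALSE,
      mapping = c("EM/UM" = "UM", "EM/EM" = "EM", "EM/IM" = "IM",
                  "EM/PM" = "IM", "IM/IM" = "IM", "IM/PM" = "IM",
                  "PM/PM" = "PM")
    ),
    TAM2 = list(
      name = "TAM2", uses_star10_refinement = FALSE,
      mapping = c("EM/UM" = "UM", "EM/EM" = "EM", "EM/IM" = "EM",
                  "EM/PM" = "IM", "IM/IM" = "IM", "IM/PM" = "PM",
                  "PM/PM" = "PM")
    ),
    TAM3 = list(
      name = "TAM3", uses_star10_refinement = TRUE,
      mapping = c("EM/UM" = "UM", "EM/EM" = "EM", "EM/IM" = "EM",
                  "EM/*10" = "IM", "EM/PM" = "IM", "IM/IM" = "IM",
                  "*10/*10" = "IM", "IM/PM" = "IM", "PM/*10" = "PM",
                  "PM/PM" = "PM")
    ),
    TAM4 = list(
      name = "TAM4", uses_star10_refinement = TRUE,
      mapping = c("EM/UM" = "UM", "EM/EM" = "EM", "EM/IM" = "EM",
                  "EM/*10" = "EM", "EM/PM" = "IM", "IM/IM" = "IM",
                  "*10/*10" = "SM", "IM/PM" = "SM", "PM/*10" = "SM",
                  "PM/PM" = "PM")
    )
  )
}

.scheme_registry <- new.env(parent = emptyenv())

.get_schemes <- function() {
  if (is.null(.scheme_registry$schemes)) {
    .scheme_registry$schemes <- .builtin_schemes()
  }
  .scheme_registry$schemes
}

#' Names of the registered phenotype assignment schemes
#'
#' @return Character vector; the five built-in schemes are `Codeine`,
#'   `TAM1`, `TAM2`, `TAM3`, `TAM4`, plus any user-registered schemes.
#' @export
scheme_names <- function() names(.get_schemes())

#' Retrieve a phenotype assignment scheme
#'
#' The built-in schemes bin the diplotype categories into metabolizer
#' phenotypes UM/EM/IM/PM (plus the slow-metabolizer class SM, used only
#' by TAM4): `Codeine` is the codeine-metabolism-based consensus grouping;
#' `TAM1` the assignment used in earlier tamoxifen dose-escalation trials;
#' `TAM2` bins EM/IM into EM and IM/PM into PM; `TAM3` additionally
#' separates \*10-containing diplotypes using the downgraded \*10 activity;
#' `TAM4` extends the \*10 downgrade by placing \*10-containing
#' reduced-activity diplotypes into the new SM group.
#'
#' @param name Scheme name (see [scheme_names()]).
#' @return A `scheme_table` object: list with `name`, `mapping` (named
#'   character vector, category -> phenotype label) and
#'   `uses_star10_refinement`.
#' @export
#' @examples
#' scheme_table("TAM4")
scheme_table <- function(name) {
  schemes <- .get_schemes()
  if (!name %in% names(schemes)) {
    stop(sprintf("unknown scheme '%s'; registered schemes: %s", name,
                 paste(names(schemes), collapse = ", ")), call. = FALSE)
  }
  structure(schemes[[name]], class = "scheme_table")
}

#' @export
print.scheme_table <- function(x, ...) {
  cat(sprintf("Phenotype assignment scheme '%s'%s\n", x$name,
              if (x$uses_star10_refinement) " (uses *10 refinement)" else ""))
  print(data.frame(category = names(x$mapping), phenotype = unname(x$mapping)))
  invisible(x)
}

#' Register a phenotype assignment scheme
#'
#' @param scheme A list with `name`, `mapping` (named character vector
#'   category -> phenotype) and `uses_star10_refinement`; validated with
#'   [scheme_consistency_check()] before registration.
#' @param overwrite Replace an existing scheme of the same name?
#' @return The registered `scheme_table`, invisibly.
#' @export
register_scheme <- function(scheme, overwrite = FALSE) {
  stopifnot(is.list(scheme), is.character(scheme$name),
            !is.null(scheme$mapping))
  scheme <- structure(
    list(name = scheme$name, mapping = scheme$mapping,
         uses_star10_refinement = isTRUE(scheme$uses_star10_refinement)),
    class = "scheme_table")
  chk <- scheme_consistency_check(scheme)
  if (!chk$pass) {
    stop("scheme '", scheme$name, "' failed consistency check:\n  ",
         paste(chk$violations, collapse = "\n  "), call. = FALSE)
  }
  schemes <- .get_schemes()
  if (scheme$name %in% names(schemes) && !overwrite) {
    stop("scheme '", scheme$name, "' already registered", call. = FALSE)
  }
  schemes[[scheme$name]] <- scheme
  .scheme_registry$schemes <- schemes
  invisible(scheme)
}

#' Assign a metabolizer phenotype to a diplotype
#'
#' Deterministic lookup of the phenotype label for a diplotype under a
#' scheme. Schemes that use the \*10 refinement (TAM3, TAM4) consult the
#' refined label first; the others use only the generic category, so the
#' \*10 sub-categories inherit their generic class's phenotype.
#'
#' @param x Diplotype string(s), a data frame from [parse_diplotype()], or
#'   a character vector of category labels (generic or refined).
#' @param scheme Scheme name or `scheme_table` object.
#' @return Character vector of phenotype labels (UM/EM/IM/SM/PM).
#' @export
#' @examples
#' assign_phenotype("*10/*10", "TAM4")   # SM
#' assign_phenotype("*10/*10", "Codeine") # EM (generic IM/IM rule)
assign_phenotype <- function(x, scheme) {
  if (is.character(scheme)) scheme <- scheme_table(scheme)
  stopifnot(inherits(scheme, "scheme_table"))
  if (is.character(x) && all(grepl("/", x)) &&
      !all(x %in% c(.GENERIC_CATEGORIES, .REFINED_CATEGORIES))) {
    x <- parse_diplotype(x)
  }
  if (is.data.frame(x)) {
    generic <- x$category
    label <- x$label
  } else {
    label <- x
    generic <- ifelse(label %in% .REFINED_CATEGORIES,
                      .REFINEMENT_PARENT[label], label)
    bad <- !generic %in% .GENERIC_CATEGORIES
    if (any(bad)) {
      stop("unknown diplotype category: ",
           paste(unique(label[bad]), collapse = ", "), call. = FALSE)
    }
  }
  key <- if (scheme$uses_star10_refinement) label else generic
  ## refinement keys missing from a generic-only mapping fall back to the
  ## generic class
  key <- ifelse(key %in% names(scheme$mapping), key,
                ifelse(label %in% .REFINED_CATEGORIES,
                       .REFINEMENT_PARENT[label], key))
  unname(scheme$mapping[key])
}

#' Ordinal value of a metabolizer phenotype label
#'
#' Phenotypes carry an explicit ordering for use as an ordered regression
#' factor: UM = 4 > EM = 3 > IM = 2 > SM = 1 > PM = 0.
#'
#' @param phenotype Character vector of labels.
#' @return Integer vector of ordinal values.
#' @export
phenotype_ordinal <- function(phenotype) {
  bad <- !phenotype %in% names(.PHENOTYPE_ORDINAL)
  if (any(bad)) {
    stop("unknown phenotype label: ",
         paste(unique(phenotype[bad]), collapse = ", "), call. = FALSE)
  }
  unname(.PHENOTYPE_ORDINAL[phenotype])
}

#' Check a phenotype scheme for internal consistency
#'
#' Verifies that (i) every generic diplotype category has a phenotype
#' (totality, with refinement fallback), (ii) all assigned labels are
#' valid phenotypes, and (iii) the assignment is monotone: the phenotype
#' ordinal never increases as the standard activity score decreases
#' (refined categories are ordered by the \*10-downgraded score when the
#' scheme distinguishes them).
#'
#' @param scheme Scheme name or `scheme_table`.
#' @return A list with `pass` (logical) and `violations` (character
#'   vector describing each failure; empty when the scheme passes).
#' @export
#' @examples
#' scheme_consistency_check("Codeine")$pass
scheme_consistency_check <- function(scheme) {
  if (is.character(scheme)) scheme <- scheme_table(scheme)
  violations <- character()
  missing <- setdiff(.GENERIC_CATEGORIES, names(scheme$mapping))
  if (length(missing)) {
    violations <- c(violations, paste0(
      "mapping not total: no phenotype for ", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(scheme$mapping), names(.PHENOTYPE_ORDINAL))
  if (length(bad)) {
    violations <- c(violations, paste0(
      "invalid phenotype label(s): ", paste(bad, collapse = ", ")))
  }
  if (!length(violations)) {
    tab <- diplotype_table()
    keep <- if (scheme$uses_star10_refinement) {
      rep(TRUE, nrow(tab))
    } else {
      !tab$is_refinement
    }
    tab <- tab[keep, ]
    score <- if (scheme$uses_star10_refinement) tab$as_star10 else tab$as_standard
    ph <- assign_phenotype(tab$label, scheme)
    ord <- phenotype_ordinal(ph)
    o <- order(-score)
    score <- score[o]; ord <- ord[o]; lab <- tab$label[o]
    for (i in seq_along(score)[-1]) {
      ## strictly lower activity must not map to a strictly higher phenotype
      prior <- score > score[i]
      if (any(prior) && ord[i] > min(ord[prior])) {
        violations <- c(violations, sprintf(
          "monotonicity violation: %s (AS %.2f -> %s) above a higher-activity category",
          lab[i], score[i], ph[o][i]))
      }
    }
  }
  list(pass = length(violations) == 0L, violations = violations)
}

#' Write or read a scheme table as YAML or JSON
#'
#' Schemes serialize as `{name, mapping, uses_star10_refinement}`.
#'
#' @param scheme Scheme name or `scheme_table`.
#' @param path Output/input file; format chosen by extension (`.yaml`,
#'   `.yml` or `.json`).
#' @return `write_scheme()` returns `path` invisibly; `read_scheme()`
#'   returns a validated `scheme_table`.
#' @export
write_scheme <- function(scheme, path) {
  if (is.character(scheme)) scheme <- scheme_table(scheme)
  obj <- list(name = scheme$name,
              mapping = as.list(scheme$mapping),
              uses_star10_refinement = scheme$uses_star10_refinement)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  mapping <- unlist(obj$mapping)
  scheme <- structure(
    list(name = obj$name, mapping = mapping,
         uses_star10_refinement = isTRUE(obj$uses_star10_refinement)),
    class = "scheme_table")
  chk <- scheme_consistency_check(scheme)
  if (!chk$pass) {
    stop("scheme file '", path, "' failed consistency check:\n  ",
         paste(chk$violations, collapse = "\n  "), call. = FALSE)
  }
  scheme
}
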