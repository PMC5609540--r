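## Endpoints and unit handling.
## The two analysis endpoints are plasma (Z)-endoxifen (E, ng/mL) and the
## CYP2D6-specific metabolic ratio E/DMT (dimensionless).  Concentrations
## convert between ng/mL and nmol/L via fixed molar masses.

## Molar masses (g/mol), standard chemical reference values.
.MOLAR_MASS <- c(
  TAM = 371.51,      # tamoxifen
  DMT = 357.49,      # N-desmethyl-tamoxifen
  OHTAM = 387.51,    # 4-hydroxy-tamoxifen
  E = 373.53         # (Z)-endoxifen
)

#' Molar masses of tamoxifen and its metabolites
#'
#' @param analyte Optional analyte code(s): `"TAM"`, `"DMT"`, `"OHTAM"`
#'   (4-hydroxy-tamoxifen), `"E"` ((Z)-endoxifen). Default: all.
#' @return Named numeric vector of molar masses in g/mol.
#' @export
#' @examples
#' molar_mass("E")  # 373.53
molar_mass <- function(analyte = names(.MOLAR_MASS)) {
  bad <- !analyte %in% names(.MOLAR_MASS)
  if (any(bad)) stop("unknown analyte: ", paste(analyte[bad], collapse = ", "),
                     call. = FALSE)
  .MOLAR_MASS[analyte]
}

#' Convert between mass and molar plasma concentrations
#'
#' `ngml_to_nmol()` converts ng/mL to nmol/L (`conc * 1000 / molar_mass`);
#' `nmol_to_ngml()` is its inverse. The clinical endoxifen threshold of
#' 5.9 ng/mL corresponds to 15.8 nM at a molar mass of 373.53 g/mol.
#'
#' @param conc Numeric concentration vector (ng/mL or nM respectively).
#' @param mass Molar mass in g/mol, or an analyte code accepted by
#'   [molar_mass()].
#' @return Numeric vector in the target unit.
#' @export
#' @examples
#' ngml_to_nmol(5.9, "E")  # 15.8 nM
ngml_to_nmol <- function(conc, mass) {
  if (is.character(mass)) mass <- unname(molar_mass(mass))
  if (any(mass <= 0)) stop("molar mass must be positive", call. = FALSE)
  conc * 1000 / mass
}

#' @rdname ngml_to_nmol
#' @export
nmol_to_ngml <- function(conc, mass) {
  if (is.character(mass)) mass <- unname(molar_mass(mass))
  if (any(mass <= 0)) stop("molar mass must be positive", call. = FALSE)
  conc * mass / 1000
}

#' Metabolic ratio of two plasma concentrations
#'
#' Computes E/DMT (or any metabolite/precursor ratio) from concentrations
#' given in the same unit. The ratio is unit-invariant only when both
#' inputs use the same unit; mixing ng/mL and nM rescales it by the molar
#' mass ratio.
#'
#' @param num,denom Numeric vectors, same unit.
#' @return Numeric vector `num / denom`.
#' @export
#' @examples
#' metabolic_ratio(10, 100)  # 0.1
metabolic_ratio <- function(num, denom) {
  stopifnot(length(num) == length(denom) || length(num) == 1L ||
              length(denom) == 1L)
  if (any(!is.na(denom) & denom <= 0)) {
    stop("undefined ratio: denominator concentration must be > 0",
         call. = FALSE)
  }
  num / denom
}

#' Variance-stabilizing transformation of an endpoint
#'
#' Applies the configured transformation to an endpoint vector. The
#' default (and the package-wide default for analysis) is the natural
#' logarithm, the standard choice for right-skewed positive concentration
#' data; `"none"` passes values through for sensitivity analysis.
#'
#' @param values Numeric vector; strictly positive when `method = "log"`.
#' @param method `"log"` or `"none"`.
#' @param name Endpoint name recorded in the descriptor (e.g. `"E"`).
#' @return An `endpoint_vector` object: list with `name`, `raw`,
#'   `transformed` and `method`.
#' @export
#' @examples
#' transform_endpoint(c(1, exp(1), exp(2)))$transformed
transform_endpoint <- function(values, method = c("log", "none"),
                               name = "endpoint") {
  method <- match.arg(method)
  stopifnot(is.numeric(values))
  if (method == "log") {
    bad <- which(!is.na(values) & values <= 0)
    if (length(bad)) {
      stop(sprintf(
        "log transform undefined for non-positive values at record(s): %s",
        paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
    }
  }
  structure(
    list(name = name, raw = values,
         transformed = if (method == "log") log(values) else values,
         method = method),
    class = "endpoint_vector")
}

#' @export
print.endpoint_vector <- function(x, ...) {
  cat(sprintf("Endpoint '%s' (%s transform), n = %d\n",
              x$name, x$method, length(x$raw)))
  invisible(x)
}

## Round half away from zero at `digits` decimals (table formatting
## convention; base round() is half-even).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Diplotype category frequency table
#'
#' Tabulates a categorized cohort over the seven mutually exclusive
#' generic diplotype categories plus the three nested \*10 refinements.
#' Refinement rows are subsets of their generic class, so generic counts
#' sum to the total while refinement counts are also included in their
#' parent row. Percentages are relative to the total and rounded half-up
#' at one decimal.
#'
#' @param records A data frame with columns `category` and `label` (as
#'   produced by [parse_diplotype()] or [simulate_cohort()]), or a
#'   character vector of category labels.
#' @return A data frame with `label`, `is_refinement`, `n`, `percent`;
#'   attribute `total` holds the cohort size.
#' @export
#' @examples
#' frequency_table(c("EM/EM", "EM/EM", "PM/PM"))
frequency_table <- function(records) {
  if (is.character(records)) {
    generic <- ifelse(records %in% .REFINED_CATEGORIES,
                      .REFINEMENT_PARENT[records], records)
    records <- data.frame(category = generic, label = records,
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(records))
  if (!all(c("category", "label") %in% names(records))) {
    stop("records need 'category' and 'label' columns", call. = FALSE)
  }
  total <- nrow(records)
  rows <- diplotype_table()[, c("label", "category", "is_refinement")]
  n <- integer(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    n[i] <- if (rows$is_refinement[i]) {
      sum(records$label == rows$label[i])
    } else {
      sum(records$category == rows$category[i])
    }
  }
  out <- data.frame(label = rows$label, is_refinement = rows$is_refinement,
                    n = n,
                    percent = if (total > 0) round_half_up(100 * n / total, 1)
                              else rep(NA_real_, nrow(rows)),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}
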