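## CYP2D6 star-allele panel used throughout the package.
## Functional classes follow the closed panel of alleles predictive of
## metabolizer status: null-function (PM) *3-*7, reduced-function (IM)
## *9/*10/*41, fully functional (EM) *1/*2/*35.  Alleles outside this panel
## are rejected, never silently treated as functional.
.ALLELE_CLASS <- c(
  "*3" = "PM", "*4" = "PM", "*5" = "PM", "*6" = "PM", "*7" = "PM",
  "*9" = "IM", "*10" = "IM", "*41" = "IM",
  "*1" = "EM", "*2" = "EM", "*35" = "EM"
)

## Per-allele activity values.  The star10_downgrade dialect lowers *10 from
## 0.5 to 0.25; a duplication-carrying EM allele counts 2 (ultra-rapid).
.AS_PER_CLASS <- c(PM = 0, IM = 0.5, EM = 1)
.AS_STAR10 <- 0.25

## Numeric activity attached to the seven-level diplotype ordering used for
## ROC analysis: identical to the standard activity score except that the
## EM/PM vs IM/IM tie at AS = 1 is broken by assigning IM/IM a value of 0.75.
.ROC_ACTIVITY <- c(
  "EM/UM" = 3, "EM/EM" = 2, "EM/IM" = 1.5, "EM/PM" = 1,
  "IM/IM" = 0.75, "IM/PM" = 0.5, "PM/PM" = 0
)

.GENERIC_CATEGORIES <- names(.ROC_ACTIVITY)
.REFINED_CATEGORIES <- c("EM/*10", "*10/*10", "PM/*10")
.REFINEMENT_PARENT <- c(
  "EM/*10" = "EM/IM", "*10/*10" = "IM/IM", "PM/*10" = "IM/PM"
)

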