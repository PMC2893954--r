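#' @import methods
NULL

WELL_ROLES <- c("sample", "positive_control", "negative_control", "empty")

#' PlateLayout: roles and esiRNA assignment of a 384-well plate
#'
#' Maps every well of a 384-well plate to a role (sample, positive control,
#' negative control, empty) and, for sample wells, an esiRNA identifier.
#'
#' @slot plateId single plate identifier.
#' @slot roles named character vector over all 384 wells.
#' @slot esirna named character vector over all 384 wells (NA where no
#'   esiRNA is spotted).
#' @export
setClass("PlateLayout", representation(
  plateId = "character",
  roles = "character",
  esirna = "character"
))

setValidity("PlateLayout", function(object) {
  wells <- allWellAddresses()
  if (length(object@plateId) != 1L || is.na(object@plateId))
    return("plateId must be a single non-NA string")
  if (length(object@roles) != 384L || !identical(sort(names(object@roles)), sort(wells)))
    return("roles must be named over exactly the 384 well addresses")
  if (!all(object@roles %in% WELL_ROLES))
    return(paste("roles must be one of:", paste(WELL_ROLES, collapse = ", ")))
  if (length(object@esirna) != 384L || !identical(sort(names(object@esirna)), sort(wells)))
    return("esirna must be named over exactly the 384 well addresses")
  TRUE
})

#' PlateReadout: percent GFP-positive per well of one replicate plate
#'
#' Holds the per-well FACS summary (percent GFP-positive cells, 0-100)
#' for one replicate measurement of one plate, together with its layout.
#'
#' @slot layout a \linkS4class{PlateLayout}.
#' @slot values named numeric vector of percent GFP-positive cells.
#' @slot replicateId integer replicate index.
#' @export
setClass("PlateReadout", representation(
  layout = "PlateLayout",
  values = "numeric",
  replicateId = "integer"
))

setValidity("PlateReadout", function(object) {
  v <- object@values
  if (is.null(names(v)) || anyNA(names(v)))
    return("values must be a named numeric vector of well addresses")
  if (!all(names(v) %in% allWellAddresses()))
    return("values contain unknown well addresses")
  if (any(!is.finite(v)) || any(v < 0 | v > 100))
    return("all values must be finite percentages in [0, 100]")
  if (length(object@replicateId) != 1L || is.na(object@replicateId))
    return("replicateId must be a single integer")
  TRUE
})

#' HitThresholds: z-score cut-offs of the hit-calling funnel
#'
#' @slot primaryAbsZ absolute average-z cut-off for primary hits (strict).
#' @slot validationStrong strong-trigger cut-off for validated hits.
#' @slot validationWeak weak-trigger cut-off for validated hits.
#' @slot counterscreenAbsZ GFP-level counterscreen exclusion cut-off.
#' @slot singleTriggerAbsZ cut-off for genes with only one available trigger.
#' @export
setClass("HitThresholds", representation(
  primaryAbsZ = "numeric",
  validationStrong = "numeric",
  validationWeak = "numeric",
  counterscreenAbsZ = "numeric",
  singleTriggerAbsZ = "numeric"
))

setValidity("HitThresholds", function(object) {
  v <- c(object@primaryAbsZ, object@validationStrong, object@validationWeak,
         object@counterscreenAbsZ, object@singleTriggerAbsZ)
  if (length(v) != 5L || any(!is.finite(v)) || any(v <= 0))
    return("all thresholds must be single finite positive numbers")
  if (object@validationStrong < object@validationWeak)
    return("validationStrong must be >= validationWeak")
  TRUE
})

#' SyntheticScreenConfig: parameters of the synthetic screen generator
#'
#' The generator draws per-well positive-cell counts from a binomial
#' cell-sampling model with multiplicative log-normal plate effects and
#' per-gene multiplicative fold effects on the baseline GFP+ fraction.
#'
#' @slot nPlates number of sample plates.
#' @slot cellsPerWell cells assayed per well (binomial n).
#' @slot baselinePosFraction baseline GFP+ fraction in (0,1).
#' @slot plateEffectSd log-scale sd of the multiplicative plate effect.
#' @slot positiveControlFold fold depletion in positive-control wells.
#' @slot effectTable data.frame(gene, fold): fold > 1 depletes, < 1 enriches.
#' @slot replicateCount replicate measurements per plate.
#' @slot seed master seed; fully determines the output.
#' @export
setClass("SyntheticScreenConfig", representation(
  nPlates = "integer",
  cellsPerWell = "integer",
  baselinePosFraction = "numeric",
  plateEffectSd = "numeric",
  positiveControlFold = "numeric",
  effectTable = "data.frame",
  replicateCount = "integer",
  seed = "integer"
))

setValidity("SyntheticScreenConfig", function(object) {
  if (object@nPlates < 1L) return("nPlates must be >= 1")
  if (object@cellsPerWell < 1L) return("cellsPerWell must be >= 1")
  if (!(object@baselinePosFraction > 0 && object@baselinePosFraction < 1))
    return("baselinePosFraction must be in (0, 1)")
  if (object@plateEffectSd < 0) return("plateEffectSd must be >= 0")
  if (object@positiveControlFold <= 0) return("positiveControlFold must be > 0")
  et <- object@effectTable
  if (nrow(et) > 0) {
    if (!all(c("gene", "fold") %in% names(et)))
      return("effectTable needs columns gene, fold")
    if (any(!is.finite(et$fold)) || any(et$fold <= 0))
      return("all effect folds must be finite and > 0")
    if (anyDuplicated(et$gene)) return("duplicate gene in effectTable")
  }
  if (object@replicateCount < 1L) return("replicateCount must be >= 1")
  if (is.na(object@seed)) return("seed must be a single integer")
  TRUE
})

#' CodingVariant: an HGVS-style coding indel
#'
#' A single replacement: the inclusive 1-based c. coordinate range
#' [delStart, delEnd] is deleted and insSeq inserted in its place. A pure
#' insertion has an empty range (delEnd = delStart - 1: insertion between
#' delStart - 1 and delStart); a pure deletion has insSeq = "". Not both
#' may be empty. Insertions of known length but unreported sequence are
#' stored as runs of N (they can be described but not applied).
#'
#' @slot delStart,delEnd 1-based inclusive deletion range.
#' @slot insSeq inserted nucleotide sequence ("" when none).
#' @slot label the descriptor the variant was parsed from.
#' @export
setClass("CodingVariant", representation(
  delStart = "integer",
  delEnd = "integer",
  insSeq = "character",
  label = "character"
))

setValidity("CodingVariant", function(object) {
  if (object@delStart < 1L)
    return("delStart must be >= 1 (1-based c. coordinates)")
  if (object@delEnd < object@delStart - 1L)
    return("delEnd must be >= delStart - 1 (empty range allowed)")
  emptyDel <- object@delEnd < object@delStart
  if (emptyDel && nchar(object@insSeq) == 0L)
    return("variant must delete and/or insert something")
  if (nchar(object@insSeq) > 0L &&
      !grepl("^[ACGTN]+$", object@insSeq))
    return("insSeq must be over A,C,G,T (or N for unreported bases)")
  TRUE
})
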