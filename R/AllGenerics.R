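#' @rdname PlateLayout-class
#' @param object,x a PlateLayout or PlateReadout.
#' @export
setGeneric("plateId", function(x) standardGeneric("plateId"))

#' @rdname PlateLayout-class
#' @export
setGeneric("wellRoles", function(x) standardGeneric("wellRoles"))

#' @rdname PlateLayout-class
#' @export
setGeneric("wellEsiRNA", function(x) standardGeneric("wellEsiRNA"))

#' @rdname PlateReadout-class
#' @export
setGeneric("wellValues", function(x) standardGeneric("wellValues"))

#' @rdname PlateReadout-class
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))

setMethod("plateId", "PlateLayout", function(x) x@plateId)
setMethod("wellRoles", "PlateLayout", function(x) x@roles)
setMethod("wellEsiRNA", "PlateLayout", function(x) x@esirna)
setMethod("plateId", "PlateReadout", function(x) x@layout@plateId)
setMethod("wellRoles", "PlateReadout", function(x) x@layout@roles)
setMethod("wellEsiRNA", "PlateReadout", function(x) x@layout@esirna)
setMethod("wellValues", "PlateReadout", function(x) x@values)
setMethod("replicateId", "PlateReadout", function(x) x@replicateId)

#' Wells of a layout with a given role
#'
#' @param x a \linkS4class{PlateLayout} or \linkS4class{PlateReadout}.
#' @param role one of "sample", "positive_control", "negative_control",
#'   "empty".
#' @return character vector of well addresses.
#' @export
wellsWithRole <- function(x, role = "sample") {
  role <- match.arg(role, WELL_ROLES)
  roles <- wellRoles(x)
  names(roles)[roles == role]
}

setMethod("show", "PlateLayout", function(object) {
  tab <- table(factor(object@roles, levels = WELL_ROLES))
  cat("PlateLayout '", object@plateId, "': ",
      paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "PlateReadout", function(object) {
  cat("PlateReadout '", plateId(object), "' replicate ", object@replicateId,
      ": ", length(object@values), " measured wells, median ",
      format(stats::median(object@values), digits = 3), "% GFP+\n", sep = "")
})

setMethod("show", "HitThresholds", function(object) {
  cat("HitThresholds: primary |z| > ", object@primaryAbsZ,
      "; validation ", object@validationStrong, "/", object@validationWeak,
      "; counterscreen |z| > ", object@counterscreenAbsZ,
      "; single-trigger |z| > ", object@singleTriggerAbsZ, "\n", sep = "")
})

setMethod("show", "SyntheticScreenConfig", function(object) {
  cat("SyntheticScreenConfig: ", object@nPlates, " plate(s) x ",
      object@replicateCount, " replicate(s), ", object@cellsPerWell,
      " cells/well, baseline ", 100 * object@baselinePosFraction,
      "% GFP+, plate-effect sd ", object@plateEffectSd, ", ",
      nrow(object@effectTable), " gene effect(s), seed ", object@seed,
      "\n", sep = "")
})

setMethod("show", "CodingVariant", function(object) {
  cat("CodingVariant ", object@label, "\n", sep = "")
})
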