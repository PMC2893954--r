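POSITIVE_CONTROL_WELLS <- c("C3", "C21", "M5", "M18")
NEGATIVE_CONTROL_WELLS <- c("C4", "D3", "D4", "C22", "D21", "D22",
                            "M6", "N5", "N6", "M19", "N18", "N19")

#' Construct a PlateLayout
#'
#' @param plateId plate identifier.
#' @param roles named character vector (well -> role); wells not mentioned
#'   default to "sample".
#' @param esirna named character vector (well -> esiRNA id); unmentioned
#'   wells get NA.
#' @return a \linkS4class{PlateLayout}.
#' @export
PlateLayout <- function(plateId, roles = character(), esirna = character()) {
  wells <- allWellAddresses()
  allRoles <- stats::setNames(rep("sample", 384L), wells)
  if (length(roles)) {
    unknown <- setdiff(names(roles), wells)
    if (length(unknown))
      stop("unknown wells in roles: ", paste(unknown, collapse = ", "))
    allRoles[names(roles)] <- roles
  }
  allEsi <- stats::setNames(rep(NA_character_, 384L), wells)
  if (length(esirna)) {
    unknown <- setdiff(names(esirna), wells)
    if (length(unknown))
      stop("unknown wells in esirna: ", paste(unknown, collapse = ", "))
    allEsi[names(esirna)] <- esirna
  }
  new("PlateLayout", plateId = as.character(plateId), roles = allRoles,
      esirna = allEsi)
}

#' Default screening control layout
#'
#' The fixed control map of the screen design: four positive-control wells
#' (esiRNA against Rad51, positions C3, C21, M5, M18), twelve
#' negative-control wells (esiRNA against renilla luciferase, positions
#' C4, D3, D4, C22, D21, D22, M6, N5, N6, M19, N18, N19), all remaining
#' 368 wells are samples.
#'
#' @param plateId plate identifier.
#' @param esirna optional named character vector assigning esiRNA ids to
#'   sample wells.
#' @return a \linkS4class{PlateLayout}.
#' @examples
#' layout <- defaultControlLayout("p1")
#' table(wellRoles(layout))
#' @export
defaultControlLayout <- function(plateId = "plate1", esirna = character()) {
  roles <- c(stats::setNames(rep("positive_control", 4L), POSITIVE_CONTROL_WELLS),
             stats::setNames(rep("negative_control", 12L), NEGATIVE_CONTROL_WELLS))
  esi <- c(stats::setNames(rep("esiRad51", 4L), POSITIVE_CONTROL_WELLS),
           stats::setNames(rep("esiRluc", 12L), NEGATIVE_CONTROL_WELLS),
           esirna)
  PlateLayout(plateId, roles = roles, esirna = esi)
}

#' Construct a PlateReadout
#'
#' @param layout a \linkS4class{PlateLayout}.
#' @param values named numeric vector of percent GFP-positive cells
#'   (0-100) keyed by well address.
#' @param replicateId integer replicate index.
#' @return a \linkS4class{PlateReadout}.
#' @export
PlateReadout <- function(layout, values, replicateId = 1L) {
  new("PlateReadout", layout = layout, values = values,
      replicateId = as.integer(replicateId))
}
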