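#' Construct hit-calling thresholds
#'
#' Defaults are the screen's published cut-offs: primary hits at average
#' |z| > 2; validated hits need one trigger beyond 2 and a second beyond
#' 1.5 in the same direction; the GFP-level counterscreen excludes at
#' |z| > 4 (decreasing); single-trigger genes validate only at |z| > 4.
#' All inequalities are strict: a boundary value never calls.
#'
#' @param primaryAbsZ,validationStrong,validationWeak,counterscreenAbsZ,singleTriggerAbsZ
#'   positive cut-offs; see slots of \linkS4class{HitThresholds}.
#' @return a \linkS4class{HitThresholds}.
#' @export
hitThresholds <- function(primaryAbsZ = 2, validationStrong = 2,
                          validationWeak = 1.5, counterscreenAbsZ = 4,
                          singleTriggerAbsZ = 4) {
  new("HitThresholds", primaryAbsZ = primaryAbsZ,
      validationStrong = validationStrong, validationWeak = validationWeak,
      counterscreenAbsZ = counterscreenAbsZ,
      singleTriggerAbsZ = singleTriggerAbsZ)
}

#' Call primary hits from an average z table
#'
#' An esiRNA is a primary hit when its replicate-averaged z lies strictly
#' below -primaryAbsZ (decreased) or strictly above +primaryAbsZ
#' (increased).
#'
#' @param zTable data.frame with columns \code{esirna_id} and \code{avg_z}
#'   (a \code{gene_id} column is carried through when present).
#' @param thresholds a \linkS4class{HitThresholds}.
#' @return data.frame of hits with a \code{direction} column
#'   ("decreased"/"increased") and \code{stage} = "primary".
#' @export
callPrimaryHits <- function(zTable, thresholds = hitThresholds()) {
  stopifnot(all(c("esirna_id", "avg_z") %in% names(zTable)))
  cut <- thresholds@primaryAbsZ
  hit <- is.finite(zTable$avg_z) & abs(zTable$avg_z) > cut
  out <- zTable[hit, , drop = FALSE]
  out$direction <- ifelse(out$avg_z < 0, "decreased", "increased")
  out$stage <- rep("primary", nrow(out))
  rownames(out) <- NULL
  out
}

#' Call validated hits from per-trigger average z values
#'
#' A gene with two available triggers is validated when one trigger's
#' average z exceeds the strong cut-off and the other exceeds the weak
#' cut-off, both strictly and in the same direction (either trigger may
#' play the strong role). A gene with a single available trigger is
#' validated only when that trigger exceeds the single-trigger cut-off,
#' and is flagged.
#'
#' @param geneZ data.frame with columns \code{gene_id},
#'   \code{trigger_index}, \code{avg_z} (one row per trigger; a missing
#'   trigger is either an absent row or an NA avg_z).
#' @param thresholds a \linkS4class{HitThresholds}.
#' @return data.frame: gene_id, z1, z2, direction, single_trigger,
#'   validated; one row per gene.
#' @export
callValidatedHits <- function(geneZ, thresholds = hitThresholds()) {
  stopifnot(all(c("gene_id", "trigger_index", "avg_z") %in% names(geneZ)))
  strong <- thresholds@validationStrong
  weak <- thresholds@validationWeak
  single <- thresholds@singleTriggerAbsZ
  genes <- unique(geneZ$gene_id)
  rows <- lapply(genes, function(g) {
    sub <- geneZ[geneZ$gene_id == g, ]
    z1 <- sub$avg_z[match(1L, sub$trigger_index)]
    z2 <- sub$avg_z[match(2L, sub$trigger_index)]
    z <- c(z1, z2)[is.finite(c(z1, z2))]
    if (length(z) == 0L)
      stop("gene '", g, "': no finite trigger z-scores")
    if (length(z) == 2L) {
      sameDir <- prod(sign(z)) > 0
      ok <- sameDir &&
        ((abs(z[1]) > strong && abs(z[2]) > weak) ||
         (abs(z[2]) > strong && abs(z[1]) > weak))
      singleFlag <- FALSE
    } else {
      ok <- abs(z) > single
      singleFlag <- TRUE
    }
    data.frame(gene_id = g,
               z1 = if (is.null(z1)) NA_real_ else z1,
               z2 = if (is.null(z2)) NA_real_ else z2,
               direction = if (mean(z) < 0) "decreased" else "increased",
               single_trigger = singleFlag, validated = ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$validated, , drop = FALSE]
}

#' Apply the GFP-level counterscreen
#'
#' Excludes validated genes whose knockdown reduces GFP levels in
#' constitutively GFP-expressing cells (counterscreen z strictly below
#' -counterscreenAbsZ): such esiRNAs lower the reporter signal itself
#' rather than recombination. Increased GFP levels never exclude. Genes
#' without a counterscreen value are flagged untested and retained.
#'
#' @param validated data.frame of validated hits (needs \code{gene_id}).
#' @param gfpLevelZ named numeric vector, gene -> counterscreen z.
#' @param thresholds a \linkS4class{HitThresholds}.
#' @return list with \code{retained} (data.frame, gains
#'   \code{counterscreen_untested}), \code{excluded} (data.frame with the
#'   failing z) .
#' @export
applyCounterscreen <- function(validated, gfpLevelZ,
                               thresholds = hitThresholds()) {
  stopifnot("gene_id" %in% names(validated))
  z <- gfpLevelZ[validated$gene_id]
  untested <- !is.finite(z)
  fails <- !untested & z < -thresholds@counterscreenAbsZ
  retained <- validated[!fails, , drop = FALSE]
  retained$counterscreen_untested <- untested[!fails]
  excluded <- validated[fails, , drop = FALSE]
  excluded$counterscreen_z <- as.numeric(z[fails])
  rownames(retained) <- rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}

#' Select the secondary-assay cohort
#'
#' Validated decreasers that survived the counterscreen enter the
#' secondary assays (drug/IR sensitivity, gamma-H2AX kinetics) unless
#' their knockdown severely reduces viability (grade "++", i.e. more than
#' a 50\% drop in cell numbers).
#'
#' @param decreasers data.frame of retained validated decreasers (needs
#'   \code{gene_id}).
#' @param viabilityGrades named character vector, gene -> viability grade
#'   ("-", "+", "++"). An empty table retains every gene with a warning.
#' @return list with \code{cohort} (character vector of gene ids) and
#'   \code{excluded} (genes dropped by the viability grade).
#' @export
selectSecondaryCohort <- function(decreasers, viabilityGrades = character()) {
  genes <- decreasers$gene_id
  if (length(viabilityGrades) == 0L) {
    warning("no viability grades supplied; retaining all decreasers")
    return(list(cohort = genes, excluded = character()))
  }
  grade <- viabilityGrades[genes]
  drop <- !is.na(grade) & grade == "++"
  list(cohort = genes[!drop], excluded = genes[drop])
}
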