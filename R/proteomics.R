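#' Confident AP-MS identifications
#'
#' A protein is a confident hit in an experiment when it was identified
#' there with at least three peptides whose ions score is strictly above
#' the score cut-off (default 20). The rule is applied per experiment,
#' not pooled across immunoprecipitations of one bait.
#'
#' @param records data.frame with columns \code{protein_id},
#'   \code{experiment_id}, \code{peptide_score} (one row per peptide).
#' @param minPeptides minimum qualifying peptides.
#' @param minScore score that peptides must strictly exceed.
#' @return data.frame of confident (protein_id, experiment_id) pairs with
#'   the qualifying peptide count.
#' @export
confidentHits <- function(records, minPeptides = 3L, minScore = 20) {
  stopifnot(all(c("protein_id", "experiment_id", "peptide_score") %in%
                names(records)))
  if (any(!is.finite(records$peptide_score)))
    stop("peptide scores must be finite")
  qual <- records[records$peptide_score > minScore, , drop = FALSE]
  if (nrow(qual) == 0L)
    return(data.frame(protein_id = character(), experiment_id = character(),
                      n_peptides = integer(), stringsAsFactors = FALSE))
  counts <- stats::aggregate(peptide_score ~ protein_id + experiment_id,
                             data = qual, FUN = length)
  names(counts)[3] <- "n_peptides"
  out <- counts[counts$n_peptides >= minPeptides, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter common-background proteins
#'
#' Excludes proteins observed in strictly more than \code{fraction}
#' (default 15\%) of the independent control immunoprecipitations from
#' unrelated baits. Bait proteins are exempt (they are trivially present
#' in their own IPs). Proteins absent from the registry count as 0 and
#' are flagged.
#'
#' @param proteins character vector of candidate protein ids.
#' @param registry data.frame with columns \code{protein_id},
#'   \code{ctrl_count} (number of control IPs containing the protein).
#' @param nCtrl total number of control immunoprecipitations.
#' @param fraction exclusion frequency cut-off (strict).
#' @param baits character vector of bait protein ids, never excluded.
#' @return list: \code{retained}, \code{excluded} (character vectors) and
#'   \code{unregistered} (retained proteins missing from the registry).
#' @export
filterCommonBackground <- function(proteins, registry, nCtrl = 193L,
                                   fraction = 0.15, baits = character()) {
  stopifnot(all(c("protein_id", "ctrl_count") %in% names(registry)))
  if (nCtrl <= 0) stop("nCtrl must be positive")
  if (any(registry$ctrl_count < 0 | registry$ctrl_count > nCtrl))
    stop("ctrl_count must lie in [0, nCtrl]")
  counts <- registry$ctrl_count[match(proteins, registry$protein_id)]
  unregistered <- proteins[is.na(counts)]
  counts[is.na(counts)] <- 0L
  isBackground <- counts / nCtrl > fraction
  isBait <- proteins %in% baits
  excluded <- proteins[isBackground & !isBait]
  list(retained = proteins[!(isBackground & !isBait)],
       excluded = excluded,
       unregistered = unregistered)
}
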