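DOWN <- "\u2193"
UP <- "\u2191"

#' Grade an HR z-score into the arrow scale
#'
#' The replicate-averaged, negative-control-based z of a knockdown is
#' graded by the strongest satisfied cut-off: strictly below -4, -2, -1.5
#' gives three, two, one down arrows; strictly above 1.5, 2, 4 gives one,
#' two, three up arrows; otherwise "-".
#'
#' @param z numeric vector of average z-scores.
#' @return character vector of grade symbols.
#' @examples
#' gradeHr(c(-4.5, 0, 1.7))
#' @export
gradeHr <- function(z) {
  stopifnot(all(is.finite(z)))
  vapply(z, function(zi) {
    if (zi < -4) strrep(DOWN, 3)
    else if (zi < -2) strrep(DOWN, 2)
    else if (zi < -1.5) DOWN
    else if (zi > 4) strrep(UP, 3)
    else if (zi > 2) strrep(UP, 2)
    else if (zi > 1.5) UP
    else "-"
  }, character(1))
}

#' Representative z-score for an HR grade symbol
#'
#' Inverse of \code{\link{gradeHr}} for reconstructing grade-consistent z
#' values from a printed summary table: interior grades map to the
#' midpoint of their z interval, the unbounded extreme grades to |z| = 5,
#' "n.a." to NA.
#'
#' @param grade character vector of grade symbols.
#' @return numeric vector of representative z values.
#' @export
hrGradeToZ <- function(grade) {
  map <- c(5, 3, 1.75, 0, -1.75, -3, -5)
  names(map) <- c(strrep(UP, 3), strrep(UP, 2), UP, "-",
                  DOWN, strrep(DOWN, 2), strrep(DOWN, 3))
  z <- map[grade]
  z[grade %in% c("n.a.", "n.a", NA)] <- NA_real_
  unknown <- !(grade %in% c(names(map), "n.a.", "n.a")) & !is.na(grade)
  if (any(unknown))
    stop("unknown grade symbol: ", paste(unique(grade[unknown]), collapse = ", "))
  unname(z)
}

#' Grade the GFP-level counterscreen
#'
#' "+" when the constitutive-GFP counterscreen z is strictly below -4
#' (the knockdown reduces GFP signal itself), "-" otherwise.
#'
#' @param z numeric vector of counterscreen z values.
#' @return character vector of "+"/"-".
#' @export
gradeGfpLevel <- function(z) ifelse(is.finite(z) & z < -4, "+", "-")

#' Grade knockdown viability
#'
#' Relative decrease in untreated cell numbers versus the Rluc control,
#' r = 1 - mean(gene)/mean(Rluc): r strictly above 0.50 grades "++"
#' (excluded from secondary assays), above 0.25 grades "+", else "-".
#'
#' @param geneUntreated,rlucUntreated replicate untreated cell counts.
#' @return list with \code{grade} and \code{decrease} (r).
#' @export
gradeViability <- function(geneUntreated, rlucUntreated) {
  mR <- mean(rlucUntreated)
  if (!is.finite(mR) || mR == 0)
    stop("zero or undefined Rluc untreated mean")
  r <- 1 - mean(geneUntreated) / mR
  grade <- if (r > 0.50) "++" else if (r > 0.25) "+" else "-"
  list(grade = grade, decrease = r)
}

#' Grade drug/IR sensitivity
#'
#' Drug-specific sensitivity is double-normalized so baseline viability
#' effects do not masquerade as drug sensitivity:
#' d = 1 - (treated/untreated of the gene) / (treated/untreated of Rluc),
#' means over replicates. d >= 0.40 grades "+++", >= 0.30 "++",
#' >= 0.10 "+", else "-" (inclusive boundaries).
#'
#' @param geneTreated,geneUntreated,rlucTreated,rlucUntreated replicate
#'   cell counts for one treatment condition.
#' @return list with \code{grade} and \code{decrease} (d).
#' @export
gradeSensitivity <- function(geneTreated, geneUntreated,
                             rlucTreated, rlucUntreated) {
  mGU <- mean(geneUntreated); mRU <- mean(rlucUntreated)
  if (!is.finite(mGU) || mGU == 0 || !is.finite(mRU) || mRU == 0)
    stop("zero untreated mean: sensitivity ratio undefined")
  mRT <- mean(rlucTreated)
  if (!is.finite(mRT) || mRT == 0)
    stop("zero Rluc treated mean: sensitivity ratio undefined")
  d <- 1 - (mean(geneTreated) / mGU) / (mRT / mRU)
  # inclusive boundaries; absorb floating-point noise from the double ratio
  eps <- 1e-9
  grade <- if (d >= 0.40 - eps) "+++" else if (d >= 0.30 - eps) "++"
           else if (d >= 0.10 - eps) "+" else "-"
  list(grade = grade, decrease = d)
}

#' Classify gamma-H2AX removal kinetics
#'
#' At each post-irradiation timepoint (1 h, 6 h) the percent
#' gamma-H2AX-positive cells of the knockdown is compared to the Rluc
#' control by a two-sided two-sample Student's t test (equal variances by
#' default; Welch available). p < 0.05 annotates an arrow with the sign
#' of the mean difference, rendered e.g. "(down) 1h, (down) 6h".
#'
#' @param gene,rluc data.frames with columns \code{timepoint} (one of
#'   "no_IR", "1h", "6h") and \code{value} (percent positive, 3
#'   replicates per timepoint).
#' @param welch use Welch's unequal-variance t test instead of Student's.
#' @return list with \code{annotation} (single string, "-" when nothing
#'   is significant) and \code{details} (data.frame timepoint, mean_diff,
#'   p, arrow).
#' @export
classifyH2ax <- function(gene, rluc, welch = FALSE) {
  det <- do.call(rbind, lapply(c("1h", "6h"), function(tp) {
    g <- gene$value[gene$timepoint == tp]
    r <- rluc$value[rluc$timepoint == tp]
    if (length(g) < 2L || length(r) < 2L)
      stop("fewer than 2 replicates at timepoint ", tp)
    if (stats::sd(g) == 0 && stats::sd(r) == 0) {
      p <- if (mean(g) == mean(r)) 1 else 0
    } else {
      p <- stats::t.test(g, r, var.equal = !welch)$p.value
    }
    d <- mean(g) - mean(r)
    data.frame(timepoint = tp, mean_diff = d, p = p,
               arrow = if (p < 0.05) ifelse(d > 0, UP, DOWN) else "",
               stringsAsFactors = FALSE)
  }))
  hitTp <- det$arrow != ""
  ann <- if (any(hitTp))
    paste(paste(det$arrow[hitTp], det$timepoint[hitTp]), collapse = ", ")
  else "-"
  list(annotation = ann, details = det)
}

#' Assemble the per-gene phenotype summary table
#'
#' One row per validated gene with its per-trigger HR grades, GFP-level
#' counterscreen grade, viability grade, per-treatment sensitivity grades
#' and gamma-H2AX annotation. Genes not assayed at a stage (excluded by
#' the counterscreen or the viability filter) carry "n.d." in the
#' downstream columns; a missing trigger carries "n.a.".
#'
#' @param validated data.frame from \code{\link{callValidatedHits}}.
#' @param gfpGrades,viabilityGrades named character vectors, gene -> grade.
#' @param sensitivityGrades data.frame with columns gene_id, cisplatin,
#'   mmc, ir (one row per assayed gene).
#' @param h2axAnnotations named character vector, gene -> annotation.
#' @return data.frame, one row per gene.
#' @export
buildSummaryTable <- function(validated, gfpGrades = character(),
                              viabilityGrades = character(),
                              sensitivityGrades = NULL,
                              h2axAnnotations = character()) {
  if (nrow(validated) == 0L)
    return(data.frame(gene_id = character(), hr_grade_1 = character(),
                      hr_grade_2 = character(), gfp_grade = character(),
                      viability_grade = character(), cisplatin = character(),
                      mmc = character(), ir = character(), h2ax = character(),
                      stringsAsFactors = FALSE))
  if (anyDuplicated(validated$gene_id))
    stop("conflicting duplicate rows for gene(s): ",
         paste(unique(validated$gene_id[duplicated(validated$gene_id)]),
               collapse = ", "))
  lookup <- function(tab, g, default = "n.d.") {
    v <- tab[g]
    ifelse(is.na(v), default, v)
  }
  g <- validated$gene_id
  sens <- function(cond) {
    if (is.null(sensitivityGrades)) return(rep("n.d.", length(g)))
    v <- sensitivityGrades[[cond]][match(g, sensitivityGrades$gene_id)]
    ifelse(is.na(v), "n.d.", v)
  }
  data.frame(
    gene_id = g,
    hr_grade_1 = ifelse(is.finite(validated$z1), gradeHr(ifelse(is.finite(validated$z1), validated$z1, 0)), "n.a."),
    hr_grade_2 = ifelse(is.finite(validated$z2), gradeHr(ifelse(is.finite(validated$z2), validated$z2, 0)), "n.a."),
    gfp_grade = lookup(gfpGrades, g, default = "-"),
    viability_grade = lookup(viabilityGrades, g, default = "n.d."),
    cisplatin = sens("cisplatin"), mmc = sens("mmc"), ir = sens("ir"),
    h2ax = lookup(h2axAnnotations, g),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Bundled candidate-gene phenotype table
#'
#' The worked-example dataset: the published summary of the 62
#' dual-trigger candidate genes of a genome-scale DR-GFP screen, with
#' per-trigger HR grades, GFP-level counterscreen grade, viability grade,
#' drug/IR sensitivity grades and gamma-H2AX annotations. One weak-trigger
#' grade (AIP) was reconciled from one to two arrows so that every row is
#' consistent with the screen's own dual-trigger selection rule and
#' stated candidate counts.
#'
#' @return data.frame with columns gene_id, ensembl_id, hr_grade_1,
#'   hr_grade_2, gfp_grade, viability_grade, cisplatin, mmc, ir, h2ax.
#' @examples
#' tab <- candidatePhenotypes()
#' nrow(tab) # 62 candidate genes
#' @export
candidatePhenotypes <- function() {
  path <- system.file("extdata", "candidate_phenotypes.tsv",
                      package = "drgfpScreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
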