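#' The candidate-table worked example: full hit-calling funnel
#'
#' Runs the complete validation funnel on the bundled candidate phenotype
#' table: per-trigger grades are transcribed into grade-consistent
#' representative z values (\code{\link{hrGradeToZ}}), the dual-trigger
#' validation rule is applied, then the GFP-level counterscreen and the
#' viability exclusion. This reproduces the published funnel: 45
#' decreasers + 17 increasers validated, 61 genes after the
#' counterscreen, 44 decreasers characterized, 13 excluded by the
#' viability grade, 31 entering secondary assays.
#'
#' @param tab a candidate table as returned by
#'   \code{\link{candidatePhenotypes}}.
#' @param thresholds a \linkS4class{HitThresholds}.
#' @return list: \code{validated} (data.frame), \code{retained},
#'   \code{excludedByCounterscreen}, \code{secondaryCohort},
#'   \code{viabilityExcluded}, \code{summary} (rebuilt phenotype table)
#'   and \code{counts} (named integer funnel).
#' @export
candidateFunnel <- function(tab = candidatePhenotypes(),
                            thresholds = hitThresholds()) {
  geneZ <- rbind(
    data.frame(gene_id = tab$gene_id, trigger_index = 1L,
               avg_z = hrGradeToZ(tab$hr_grade_1), stringsAsFactors = FALSE),
    data.frame(gene_id = tab$gene_id, trigger_index = 2L,
               avg_z = hrGradeToZ(tab$hr_grade_2), stringsAsFactors = FALSE))
  validated <- callValidatedHits(geneZ, thresholds)
  # counterscreen grade "+" marks |z| > 4 in the decreasing direction
  gfpZ <- stats::setNames(ifelse(tab$gfp_grade == "+", -5, 0), tab$gene_id)
  cs <- applyCounterscreen(validated, gfpZ, thresholds)
  decreasers <- cs$retained[cs$retained$direction == "decreased", ]
  viability <- stats::setNames(tab$viability_grade, tab$gene_id)
  cohort <- selectSecondaryCohort(decreasers, viability)
  sens <- tab[, c("gene_id", "cisplatin", "mmc", "ir")]
  sens <- sens[!(sens$cisplatin == "n.d."), , drop = FALSE]
  h2ax <- stats::setNames(tab$h2ax, tab$gene_id)
  h2ax <- h2ax[h2ax != "n.d."]
  summary <- buildSummaryTable(
    validated,
    gfpGrades = stats::setNames(tab$gfp_grade, tab$gene_id),
    viabilityGrades = viability, sensitivityGrades = sens,
    h2axAnnotations = h2ax)
  counts <- c(validated = nrow(validated),
              decreased = sum(validated$direction == "decreased"),
              increased = sum(validated$direction == "increased"),
              after_counterscreen = nrow(cs$retained),
              decreasers_characterized = nrow(decreasers),
              viability_excluded = length(cohort$excluded),
              secondary_cohort = length(cohort$cohort))
  list(validated = validated, retained = cs$retained,
       excludedByCounterscreen = cs$excluded,
       secondaryCohort = cohort$cohort,
       viabilityExcluded = cohort$excluded,
       summary = summary, counts = counts)
}

#' Run the screen pipeline from a configuration
#'
#' Config-driven orchestration: simulate (or read) plate readouts, score
#' them, call primary and validated hits, optionally apply the
#' counterscreen and a category enrichment, write stage outputs and a
#' run manifest. Deterministic given the config and inputs.
#'
#' @param config a list, or path to a YAML file, with (all optional
#'   except one of \code{synthetic}/\code{inputs}):
#'   \describe{
#'     \item{mode}{"plate" or "control" normalization (default "plate").}
#'     \item{seed}{integer seed for synthetic generation.}
#'     \item{thresholds}{named overrides: primary, strong, weak,
#'       counterscreen, single_trigger.}
#'     \item{synthetic}{generator settings: n_plates, cells_per_well,
#'       baseline_pos_fraction, plate_effect_sd, positive_control_fold,
#'       replicate_count, validation (logical), effects (list of
#'       \{gene, fold\} or \{gene, fold1, fold2\}).}
#'     \item{inputs}{readouts (CSV path) and library (TSV path) instead
#'       of synthetic generation.}
#'     \item{counterscreen}{CSV path with columns gene_id, z.}
#'     \item{annotation}{TSV path (gene_id, category) for enrichment of
#'       the validated hits against the screened-gene universe.}
#'     \item{out_dir}{directory for stage CSV outputs and the manifest.}
#'   }
#' @return list: zTable, primaryHits, validatedHits, counterscreen
#'   result, enrichment table (or NULL), funnel counts, manifest.
#' @export
runScreenPipeline <- function(config) {
  t0 <- Sys.time()
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- if (is.null(config$mode)) "plate" else config$mode
  th <- config$thresholds
  thresholds <- hitThresholds(
    primaryAbsZ = th$primary %||% 2, validationStrong = th$strong %||% 2,
    validationWeak = th$weak %||% 1.5,
    counterscreenAbsZ = th$counterscreen %||% 4,
    singleTriggerAbsZ = th$single_trigger %||% 4)
  checksums <- character()
  if (!is.null(config$synthetic)) {
    s <- config$synthetic
    effects <- if (is.null(s$effects))
      data.frame(gene = character(), fold = numeric())
    else do.call(rbind, lapply(s$effects, as.data.frame))
    cfg <- syntheticScreenConfig(
      nPlates = s$n_plates %||% 1L, cellsPerWell = s$cells_per_well %||% 2000L,
      baselinePosFraction = s$baseline_pos_fraction %||% 0.05,
      plateEffectSd = s$plate_effect_sd %||% 0.1,
      positiveControlFold = s$positive_control_fold %||% 5,
      effectTable = effects,
      replicateCount = s$replicate_count %||% 2L,
      seed = config$seed %||% 1L)
    screen <- if (isTRUE(s$validation)) generateValidationScreen(cfg)
              else generatePrimaryScreen(cfg)
  } else if (!is.null(config$inputs)) {
    screen <- list(readouts = readReadoutTable(config$inputs$readouts),
                   libraryMap = readLibraryMap(config$inputs$library),
                   truth = NULL)
    checksums <- tools::md5sum(c(config$inputs$readouts,
                                 config$inputs$library))
  } else stop("config needs either 'synthetic' or 'inputs'")

  zTab <- zScoreTable(screen$readouts, screen$libraryMap, mode = mode)
  primary <- callPrimaryHits(zTab, thresholds)
  twoTrig <- any(zTab$trigger_index == 2L)
  validated <- if (twoTrig) callValidatedHits(zTab, thresholds) else NULL

  cs <- NULL
  if (!is.null(validated) && !is.null(config$counterscreen)) {
    gz <- utils::read.csv(config$counterscreen, stringsAsFactors = FALSE)
    cs <- applyCounterscreen(validated, stats::setNames(gz$z, gz$gene_id),
                             thresholds)
    checksums <- c(checksums, tools::md5sum(config$counterscreen))
  }
  enr <- NULL
  if (!is.null(config$annotation)) {
    hitGenes <- if (!is.null(cs)) cs$retained$gene_id
                else if (!is.null(validated)) validated$gene_id
                else unique(primary$gene_id)
    enr <- enrichmentTable(hitGenes, readAnnotationTable(config$annotation),
                           universe = unique(screen$libraryMap$gene_id))
    checksums <- c(checksums, tools::md5sum(config$annotation))
  }
  counts <- c(esirnas_scored = nrow(zTab), primary_hits = nrow(primary),
              validated = if (is.null(validated)) NA_integer_
                          else nrow(validated),
              after_counterscreen = if (is.null(cs)) NA_integer_
                                    else nrow(cs$retained))
  cfgFile <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfgFile)
  manifest <- list(
    package_version = as.character(utils::packageVersion("drgfpScreen")),
    config_md5 = unname(tools::md5sum(cfgFile)),
    input_md5 = as.list(checksums),
    normalization_mode = mode, sd_mode = "sample (n-1)",
    t_test = "Student (equal variance), two-sided",
    counts = as.list(counts),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  unlink(cfgFile)
  out <- list(zTable = zTab, primaryHits = primary,
              validatedHits = validated, counterscreen = cs,
              enrichment = enr, counts = counts, manifest = manifest)
  if (!is.null(config$out_dir)) writePipelineOutputs(out, config$out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writePipelineOutputs <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(dir, f), row.names = FALSE,
                     fileEncoding = "UTF-8")
  wr(bundle$zTable, "z_table.csv")
  wr(bundle$primaryHits, "primary_hits.csv")
  wr(bundle$validatedHits, "validated_hits.csv")
  if (!is.null(bundle$counterscreen)) {
    wr(bundle$counterscreen$retained, "hits_after_counterscreen.csv")
    wr(bundle$counterscreen$excluded, "counterscreen_excluded.csv")
  }
  wr(bundle$enrichment, "enrichment.csv")
  yaml::write_yaml(bundle$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
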