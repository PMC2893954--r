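#' Construct a synthetic screen configuration
#'
#' Defaults describe the emulated assay: a ~5\% baseline GFP+ fraction in
#' negative-control wells, ~2000 cells sampled per well (binomial
#' counting noise), a strong (5-fold) depletion in positive-control
#' wells, log-normal multiplicative plate effects, and per-gene
#' multiplicative fold effects (fold > 1 = depletion of the GFP+
#' fraction, fold < 1 = enrichment). The master seed fully determines the
#' output; each plate/replicate gets its own derived generator stream so
#' partial regeneration is reproducible.
#'
#' @param nPlates number of plates.
#' @param cellsPerWell cells per well.
#' @param baselinePosFraction baseline GFP+ fraction in (0,1).
#' @param plateEffectSd log-scale sd of the plate effect.
#' @param positiveControlFold fold depletion of the positive control.
#' @param effectTable data.frame(gene, fold); optionally per-trigger
#'   columns fold1, fold2 for validation screens (NA marks an
#'   unavailable trigger).
#' @param replicateCount replicates per plate (2 is typical for a primary
#'   screen, 4 for validation).
#' @param seed integer master seed.
#' @return a \linkS4class{SyntheticScreenConfig}.
#' @export
syntheticScreenConfig <- function(nPlates = 1L, cellsPerWell = 2000L,
                                  baselinePosFraction = 0.05,
                                  plateEffectSd = 0.1,
                                  positiveControlFold = 5,
                                  effectTable = data.frame(gene = character(),
                                                           fold = numeric()),
                                  replicateCount = 2L, seed = 1L) {
  new("SyntheticScreenConfig", nPlates = as.integer(nPlates),
      cellsPerWell = as.integer(cellsPerWell),
      baselinePosFraction = baselinePosFraction,
      plateEffectSd = plateEffectSd,
      positiveControlFold = positiveControlFold,
      effectTable = effectTable, replicateCount = as.integer(replicateCount),
      seed = as.integer(seed))
}

## Seed streams derived once from the master seed: one per plate x replicate.
derivedSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

simulateWells <- function(folds, config, plateEffect) {
  p <- pmin(pmax(config@baselinePosFraction * plateEffect / folds, 0), 1)
  counts <- stats::rbinom(length(p), config@cellsPerWell, p)
  100 * counts / config@cellsPerWell
}

## One measured plate: sample wells get the fold of their esiRNA's gene,
## positive controls the positive-control fold, negatives fold 1.
simulatePlate <- function(layout, geneFold, config, streamSeed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(streamSeed)
  plateEffect <- exp(stats::rnorm(1, 0, config@plateEffectSd))
  roles <- wellRoles(layout)
  esi <- wellEsiRNA(layout)
  measured <- names(roles)[roles %in% c("positive_control", "negative_control") |
                           (roles == "sample" & !is.na(esi))]
  folds <- vapply(measured, function(w) {
    if (roles[w] == "positive_control") config@positiveControlFold
    else if (roles[w] == "negative_control") 1
    else geneFold[[esi[w]]]
  }, numeric(1))
  stats::setNames(simulateWells(folds, config, plateEffect), measured)
}

#' Generate a synthetic primary screen
#'
#' One esiRNA (trigger 1) per gene, spread over the sample wells of
#' \code{nPlates} plates with the default control layout, measured in
#' \code{replicateCount} replicates. Genes listed in the effect table get
#' their configured fold; remaining sample wells are filled with null
#' genes (fold 1).
#'
#' @param config a \linkS4class{SyntheticScreenConfig}.
#' @return list with \code{readouts} (list of \linkS4class{PlateReadout}),
#'   \code{libraryMap}, and \code{truth} (data.frame gene, fold,
#'   direction, is_null).
#' @export
generatePrimaryScreen <- function(config) {
  et <- config@effectTable
  nSample <- 368L * config@nPlates
  if (nrow(et) > nSample)
    stop("effect table has more genes (", nrow(et),
         ") than available sample wells (", nSample, ")")
  genes <- c(et$gene, sprintf("null%04d", seq_len(nSample - nrow(et))))
  folds <- stats::setNames(c(et$fold, rep(1, nSample - nrow(et))), genes)
  seeds <- derivedSeeds(config@seed, config@nPlates * config@replicateCount + 1L)
  # scatter genes over plates/wells (seeded), as arrayed libraries do,
  # so effect genes do not cluster on one plate
  perm <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seeds[length(seeds)])
    sample.int(length(genes))
  })
  genes <- genes[perm]
  folds <- folds[perm]
  lib <- libraryMap(paste0("esi_", genes), genes, rep(1L, length(genes)))
  esiFold <- stats::setNames(unname(folds), lib$esirna_id)
  sampleWells <- wellsWithRole(defaultControlLayout("x"), "sample")
  readouts <- list(); k <- 0L
  for (p in seq_len(config@nPlates)) {
    idx <- ((p - 1L) * 368L + 1L):(p * 368L)
    layout <- defaultControlLayout(
      sprintf("plate%02d", p),
      esirna = stats::setNames(lib$esirna_id[idx], sampleWells))
    for (r in seq_len(config@replicateCount)) {
      k <- k + 1L
      readouts[[paste0(sprintf("plate%02d", p), ":", r)]] <-
        PlateReadout(layout, simulatePlate(layout, esiFold, config, seeds[k]),
                     replicateId = r)
    }
  }
  truth <- data.frame(gene = genes, fold = unname(folds),
                      direction = ifelse(folds > 1, "decreased",
                                  ifelse(folds < 1, "increased", "none")),
                      is_null = folds == 1, stringsAsFactors = FALSE)
  list(readouts = readouts, libraryMap = lib, truth = truth)
}

#' Generate a synthetic validation screen
#'
#' Two independent silencing triggers per gene (or one, when a
#' per-trigger fold is NA, to exercise the missing-trigger path), each in
#' one well per plate, measured in \code{replicateCount} replicates
#' (4 is the validation design). Per-trigger folds come from effect-table
#' columns \code{fold1}/\code{fold2} when present, else both triggers
#' share \code{fold}.
#'
#' @param config a \linkS4class{SyntheticScreenConfig} whose effect table
#'   lists the genes to re-screen.
#' @return list with \code{readouts}, \code{libraryMap}, \code{truth}.
#' @export
generateValidationScreen <- function(config) {
  et <- config@effectTable
  if (nrow(et) == 0L) stop("validation screen needs a non-empty effect table")
  if (!all(c("fold1", "fold2") %in% names(et))) {
    et$fold1 <- et$fold
    et$fold2 <- et$fold
  }
  lib <- do.call(rbind, lapply(seq_len(nrow(et)), function(i) {
    keep <- !is.na(c(et$fold1[i], et$fold2[i]))
    data.frame(esirna_id = paste0("esi_", et$gene[i], "_t", (1:2)[keep]),
               gene_id = et$gene[i], trigger_index = (1:2)[keep],
               stringsAsFactors = FALSE)
  }))
  lib <- libraryMap(lib)
  esiFold <- stats::setNames(
    unlist(lapply(seq_len(nrow(et)), function(i)
      c(et$fold1[i], et$fold2[i])[!is.na(c(et$fold1[i], et$fold2[i]))])),
    lib$esirna_id)
  nPlates <- ceiling(nrow(lib) / 368)
  seeds <- derivedSeeds(config@seed, nPlates * config@replicateCount)
  sampleWells <- wellsWithRole(defaultControlLayout("x"), "sample")
  readouts <- list(); k <- 0L
  for (p in seq_len(nPlates)) {
    idx <- ((p - 1L) * 368L + 1L):min(p * 368L, nrow(lib))
    layout <- defaultControlLayout(
      sprintf("vplate%02d", p),
      esirna = stats::setNames(lib$esirna_id[idx],
                               sampleWells[seq_along(idx)]))
    for (r in seq_len(config@replicateCount)) {
      k <- k + 1L
      readouts[[paste0(sprintf("vplate%02d", p), ":", r)]] <-
        PlateReadout(layout, simulatePlate(layout, esiFold, config, seeds[k]),
                     replicateId = r)
    }
  }
  truth <- data.frame(gene = et$gene, fold1 = et$fold1, fold2 = et$fold2,
                      stringsAsFactors = FALSE)
  list(readouts = readouts, libraryMap = lib, truth = truth)
}

#' Generate synthetic secondary-assay replicate tables
#'
#' Emulates the two secondary assays with 3 replicates per condition.
#' Cell counts are Poisson around condition means: the Rluc control
#' plates 1000 cells untreated and keeps a 0.7 treated/untreated survival
#' ratio; a gene's untreated mean is scaled by its configured viability
#' decrease and its treated mean additionally by the drug-specific
#' depletion. Percent gamma-H2AX-positive values are Gaussian (sd 3
#' percentage points, clamped to [0, 100]) around baseline means of
#' 5\%/60\%/20\% at no-IR/1 h/6 h, shifted per gene. Rluc rows are always
#' included.
#'
#' @param config a \linkS4class{SyntheticScreenConfig} (seed source).
#' @param sensitivityEffects data.frame(gene, viability_decrease,
#'   cisplatin, mmc, ir): fractional decreases (0 = no effect).
#' @param h2axEffects data.frame(gene, shift_1h, shift_6h): additive
#'   shifts in percentage points of gamma-H2AX-positive cells.
#' @return list with \code{sensitivity} (data.frame gene_id, condition,
#'   replicate, count) and \code{h2ax} (data.frame gene_id, timepoint,
#'   replicate, value).
#' @export
generateSecondaryAssays <- function(config, sensitivityEffects = NULL,
                                    h2axEffects = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)
  baseCount <- 1000; survival <- 0.7; nRep <- 3L
  if (is.null(sensitivityEffects))
    sensitivityEffects <- data.frame(gene = character(),
                                     viability_decrease = numeric(),
                                     cisplatin = numeric(), mmc = numeric(),
                                     ir = numeric())
  se <- rbind(data.frame(gene = "Rluc", viability_decrease = 0,
                         cisplatin = 0, mmc = 0, ir = 0),
              sensitivityEffects)
  sens <- do.call(rbind, lapply(seq_len(nrow(se)), function(i) {
    untreatedMean <- baseCount * (1 - se$viability_decrease[i])
    means <- c(untreated = untreatedMean,
               cisplatin = untreatedMean * survival * (1 - se$cisplatin[i]),
               mmc = untreatedMean * survival * (1 - se$mmc[i]),
               ir = untreatedMean * survival * (1 - se$ir[i]))
    do.call(rbind, lapply(names(means), function(cond)
      data.frame(gene_id = se$gene[i], condition = cond,
                 replicate = seq_len(nRep),
                 count = stats::rpois(nRep, means[[cond]]),
                 stringsAsFactors = FALSE)))
  }))
  if (is.null(h2axEffects))
    h2axEffects <- data.frame(gene = character(), shift_1h = numeric(),
                              shift_6h = numeric())
  he <- rbind(data.frame(gene = "Rluc", shift_1h = 0, shift_6h = 0),
              h2axEffects)
  baseline <- c(no_IR = 5, `1h` = 60, `6h` = 20)
  h2ax <- do.call(rbind, lapply(seq_len(nrow(he)), function(i) {
    shift <- c(no_IR = 0, `1h` = he$shift_1h[i], `6h` = he$shift_6h[i])
    do.call(rbind, lapply(names(baseline), function(tp)
      data.frame(gene_id = he$gene[i], timepoint = tp,
                 replicate = seq_len(nRep),
                 value = pmin(pmax(stats::rnorm(nRep, baseline[[tp]] +
                                                shift[[tp]], 3), 0), 100),
                 stringsAsFactors = FALSE)))
  }))
  list(sensitivity = sens, h2ax = h2ax)
}

#' Estimate a knockdown's fold change from readouts
#'
#' The pipeline's fold estimate for a gene is the ratio of the pooled
#' negative-control mean percent GFP-positive to the pooled mean over all
#' wells (all triggers, all replicates) whose esiRNA targets the gene.
#' Fold > 1 means the knockdown depleted GFP+ cells.
#'
#' @param readouts list of \linkS4class{PlateReadout}.
#' @param libraryMap library map data.frame.
#' @param gene gene identifier.
#' @return single numeric fold estimate.
#' @export
estimateFoldChange <- function(readouts, libraryMap, gene) {
  esis <- libraryMap$esirna_id[libraryMap$gene_id == gene]
  if (length(esis) == 0L) stop("gene '", gene, "' not in library map")
  geneVals <- negVals <- numeric()
  for (r in readouts) {
    v <- wellValues(r)
    roles <- wellRoles(r)[names(v)]
    esi <- wellEsiRNA(r)[names(v)]
    geneVals <- c(geneVals, v[!is.na(esi) & esi %in% esis])
    negVals <- c(negVals, v[roles == "negative_control"])
  }
  if (length(geneVals) == 0L) stop("no measured wells for gene '", gene, "'")
  if (mean(geneVals) == 0) stop("gene mean is zero; fold undefined")
  mean(negVals) / mean(geneVals)
}
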