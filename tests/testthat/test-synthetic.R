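test_that("generation is byte-identical under the same seed", {
  cfg <- syntheticScreenConfig(nPlates = 1L, seed = 101L,
                               effectTable = data.frame(gene = "gA",
                                                        fold = 4))
  a <- generatePrimaryScreen(cfg)
  b <- generatePrimaryScreen(cfg)
  expect_identical(lapply(a$readouts, wellValues),
                   lapply(b$readouts, wellValues))
  c2 <- generatePrimaryScreen(syntheticScreenConfig(
    nPlates = 1L, seed = 102L,
    effectTable = data.frame(gene = "gA", fold = 4)))
  expect_false(identical(lapply(a$readouts, wellValues),
                         lapply(c2$readouts, wellValues)))
})

test_that("null wells fluctuate around the baseline, effects scale it", {
  cfg <- syntheticScreenConfig(nPlates = 2L, plateEffectSd = 0,
                               replicateCount = 2L, seed = 7L,
                               effectTable = data.frame(gene = "gA",
                                                        fold = 5))
  scr <- generatePrimaryScreen(cfg)
  vals <- unlist(lapply(scr$readouts, function(r) {
    v <- wellValues(r)
    v[wellRoles(r)[names(v)] == "sample"]
  }))
  # 1471 null wells x 4 measurements around 5%
  expect_equal(mean(vals), 5, tolerance = 0.05)
  geneWells <- unlist(lapply(scr$readouts, function(r) {
    v <- wellValues(r)
    v[!is.na(wellEsiRNA(r)[names(v)]) & wellEsiRNA(r)[names(v)] == "esi_gA"]
  }))
  expect_equal(mean(geneWells), 1, tolerance = 0.35)  # 5% / fold 5
  # positive-control wells share the configured depletion
  pos <- unlist(lapply(scr$readouts, function(r)
    wellValues(r)[wellsWithRole(r, "positive_control")]))
  expect_equal(mean(pos), 1, tolerance = 0.35)
})

test_that("per-plate z of generated plates is calibrated to mean 0, sd 1", {
  cfg <- syntheticScreenConfig(nPlates = 3L, replicateCount = 2L, seed = 9L)
  scr <- generatePrimaryScreen(cfg)
  for (r in scr$readouts) {
    z <- plateZScores(r)$z[wellsWithRole(r, "sample")]
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sd(z) - 1), 1e-9)
  }
})

test_that("null-screen false-call rate matches the normal tail", {
  # per-plate z on a null plate is approximately standard normal, so the
  # duplicate-averaged z exceeds +/-2 at about the two-sided tail of
  # N(0, 1/sqrt(2)); check the single-replicate rate against N(0,1).
  calls <- 0L; total <- 0L
  for (seed in 1:40) {
    cfg <- syntheticScreenConfig(nPlates = 1L, replicateCount = 1L,
                                 seed = seed)
    scr <- generatePrimaryScreen(cfg)
    tab <- zScoreTable(scr$readouts, scr$libraryMap, mode = "plate")
    calls <- calls + sum(abs(tab$avg_z) > 2)
    total <- total + nrow(tab)
  }
  expected <- 2 * pnorm(-2)
  se <- sqrt(expected * (1 - expected) / total)
  expect_lt(abs(calls / total - expected), 4 * se + 0.002)
})

test_that("validation screens recover planted dual-trigger effects", {
  validated <- 0L
  nullCalls <- 0L
  for (seed in 1:60) {
    cfg <- syntheticScreenConfig(
      replicateCount = 4L, seed = seed,
      effectTable = data.frame(gene = c("hit", "null"),
                               fold = c(4, 1)))
    scr <- generateValidationScreen(cfg)
    tab <- zScoreTable(scr$readouts, scr$libraryMap, mode = "control")
    called <- callValidatedHits(tab)
    if ("hit" %in% called$gene_id &&
        called$direction[called$gene_id == "hit"] == "decreased")
      validated <- validated + 1L
    if ("null" %in% called$gene_id) nullCalls <- nullCalls + 1L
  }
  expect_gte(validated / 60, 0.95)
  expect_lte(nullCalls / 60, 0.10)
})

test_that("a single-trigger gene flows through as n.a.", {
  cfg <- syntheticScreenConfig(
    replicateCount = 4L, seed = 3L,
    effectTable = data.frame(gene = "solo", fold1 = 6, fold2 = NA,
                             fold = 6))
  scr <- generateValidationScreen(cfg)
  expect_identical(nrow(scr$libraryMap), 1L)
  tab <- zScoreTable(scr$readouts, scr$libraryMap, mode = "control")
  called <- callValidatedHits(tab)
  expect_identical(called$gene_id, "solo")
  expect_true(called$single_trigger)
})

test_that("the gene-level fold estimate recovers the truth", {
  ok <- 0L
  for (seed in 1:60) {
    cfg <- syntheticScreenConfig(
      plateEffectSd = 0, replicateCount = 4L, seed = seed,
      effectTable = data.frame(gene = "gA", fold = 3.4))
    scr <- generateValidationScreen(cfg)
    fold <- estimateFoldChange(scr$readouts, scr$libraryMap, "gA")
    if (abs(fold / 3.4 - 1) <= 0.15) ok <- ok + 1L
  }
  expect_gte(ok / 60, 0.90)
})

test_that("secondary-assay generator drives the graders as configured", {
  strong <- 0L; null <- 0L
  for (seed in 1:60) {
    cfg <- syntheticScreenConfig(seed = seed)
    sec <- generateSecondaryAssays(
      cfg,
      sensitivityEffects = data.frame(gene = c("sens", "flat"),
                                      viability_decrease = 0,
                                      cisplatin = c(0.45, 0), mmc = 0,
                                      ir = 0))
    s <- sec$sensitivity
    pull <- function(g, cond) s$count[s$gene_id == g & s$condition == cond]
    gSens <- gradeSensitivity(pull("sens", "cisplatin"),
                              pull("sens", "untreated"),
                              pull("Rluc", "cisplatin"),
                              pull("Rluc", "untreated"))
    gFlat <- gradeSensitivity(pull("flat", "cisplatin"),
                              pull("flat", "untreated"),
                              pull("Rluc", "cisplatin"),
                              pull("Rluc", "untreated"))
    if (gSens$grade == "+++") strong <- strong + 1L
    if (gFlat$grade == "-") null <- null + 1L
  }
  expect_gte(strong / 60, 0.90)
  expect_gte(null / 60, 0.90)
})

test_that("Rluc-vs-Rluc gamma-H2AX p-values are uniform under the null", {
  ps <- numeric(500)
  tp <- rep(c("1h", "6h"), each = 3)
  for (seed in seq_len(500)) {
    set.seed(seed + 4e5)
    a <- data.frame(timepoint = tp, value = rnorm(6, 20, 3))
    b <- data.frame(timepoint = tp, value = rnorm(6, 20, 3))
    det <- classifyH2ax(a, b)$details
    ps[seed] <- det$p[det$timepoint == "6h"]
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticScreenConfig(baselinePosFraction = 1.2), "0, 1")
  expect_error(syntheticScreenConfig(
    effectTable = data.frame(gene = "g", fold = -1)), "> 0")
  expect_error(generateValidationScreen(syntheticScreenConfig()),
               "non-empty effect table")
})
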