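test_that("c. descriptors parse to the expected replacement spans", {
  v <- parseCodingVariant("c.1413_1426del14")
  expect_identical(c(v@delStart, v@delEnd), c(1413L, 1426L))
  expect_identical(v@insSeq, "")
  expect_error(parseCodingVariant("c.1413_1426del13"), "does not match")
  ins <- parseCodingVariant("c.79_80insACGT")
  expect_identical(c(ins@delStart, ins@delEnd), c(80L, 79L))  # empty range
  expect_identical(ins@insSeq, "ACGT")
  cplx <- parseCodingVariant("c.[80_83del4;79_84ins22]")
  expect_identical(c(cplx@delStart, cplx@delEnd), c(80L, 83L))
  expect_identical(nchar(cplx@insSeq), 22L)
  expect_match(cplx@label, "normalized")
  expect_error(parseCodingVariant("c.del"), "cannot parse")
})

test_that("applying an indel edits the right span and keeps length books", {
  cds <- "ATGAAACTCTTAGGGTAA"
  expect_identical(applyIndel(cds, "c.7del"), "ATGAAATCTTAGGGTAA")
  expect_identical(nchar(applyIndel(cds, "c.4_9del")), nchar(cds) - 6L)
  expect_identical(applyIndel(cds, "c.3_4insTT"),
                   "ATGTTAAACTCTTAGGGTAA")
  # a 14-base deletion shortens any CDS by 14
  long <- randomCds(600)
  expect_identical(nchar(applyIndel(long, "c.1413_1426del14")),
                   nchar(long) - 14L)
  expect_error(applyIndel(cds, "c.100del"), "outside")
  expect_error(applyIndel(cds, "c.[1_2del2;1_2ins22]"), "unreported")
})

test_that("empty variants are rejected by the class invariant", {
  expect_error(new("CodingVariant", delStart = 5L, delEnd = 4L,
                   insSeq = "", label = "x"), "delete and/or insert")
})

test_that("translation stops at the first stop codon and matches an oracle", {
  expect_identical(translateToStop("ATGTAA")$protein, "M")
  expect_identical(translateToStop("ATGAAACTCTTAGGGTAA")$protein, "MKLLG")
  expect_identical(translateToStop("ATGAAATCTTAGGGTAA")$protein, "MKS")
  expect_false(translateToStop("ATGAAA")$stopped)
  expect_error(translateToStop("ATGXAA"), "non-ACGT")
  set.seed(14)
  for (i in 1:25) {
    cds <- randomCds(sample(5:40, 1))
    mine <- translateToStop(cds)
    oracle <- translateOracle(cds)
    expect_identical(mine$protein, oracle$protein)
    expect_identical(mine$stopped, oracle$stopped)
  }
})

test_that("frameshift description anchors the first divergence", {
  res <- describeFrameshift(list(protein = "MKLLG", stopped = TRUE),
                            list(protein = "MKS", stopped = TRUE),
                            netIndel = -1L)
  expect_identical(res$kind, "frameshift")
  expect_identical(res$nomenclature, "p.L3SfsX2")
  expect_identical(res$stopPosition, 4L)
  expect_error(describeFrameshift("MKLLG", "MKLLG"), "identical")
  inframe <- describeFrameshift("MKLLG", "MKLG", netIndel = -3L)
  expect_false(inframe$kind == "frameshift")
})

test_that("stop positions parse from fsX nomenclature by anchor convention", {
  expect_identical(stopPositionFromFs("p.L471LfsX56"), 527L)  # retained
  expect_identical(stopPositionFromFs("p.A10AfsX1"), 11L)
  expect_identical(suppressWarnings(stopPositionFromFs("p.L3SfsX2")), 4L)
  expect_warning(stopPositionFromFs("p.R27LfsX3"), "substituted")
  expect_identical(suppressWarnings(stopPositionFromFs("p.R27LfsX3")), 29L)
  expect_identical(stopPositionFromFs("p.R97X"), 97L)
  expect_error(stopPositionFromFs("p.L471fs"), "malformed")
})

test_that("frameshift round trip holds on random CDS/indel pairs", {
  set.seed(15)
  bases <- c("A", "C", "G", "T")
  checked <- 0L
  while (checked < 1000L) {
    cds <- randomCds(sample(10:50, 1))
    n <- nchar(cds)
    # random 1-2 nt net indel strictly inside the CDS
    pos <- sample(4:(n - 4), 1)
    if (runif(1) < 0.5) {
      len <- sample(1:2, 1)
      desc <- if (pos + len - 1 <= n - 3)
        sprintf("c.%d_%ddel", pos, pos + len - 1) else next
    } else {
      desc <- sprintf("c.%d_%dins%s", pos, pos + 1,
                      paste(sample(bases, sample(1:2, 1), TRUE),
                            collapse = ""))
    }
    vc <- tryCatch(variantConsequence(cds, desc), error = function(e) NULL)
    if (is.null(vc)) next  # indel in the last codon can leave the protein unchanged
    cons <- vc$consequence
    if (cons$kind != "frameshift") next  # stop-loss: no fsX round trip
    observedStop <- nchar(vc$alt$protein) + 1L
    expect_identical(suppressWarnings(stopPositionFromFs(cons$nomenclature)),
                     observedStop)
    expect_identical(cons$stopPosition, observedStop)
    checked <- checked + 1L
  }
})

test_that("net indel length mod 3 controls the consequence kind", {
  set.seed(16)
  for (i in 1:50) {
    cds <- randomCds(sample(10:30, 1))
    n <- nchar(cds)
    pos <- sample(4:(n - 12), 1)
    inframe <- variantConsequence(cds, sprintf("c.%d_%ddel", pos, pos + 2))
    expect_false(inframe$consequence$kind == "frameshift")
    shifted <- variantConsequence(cds, sprintf("c.%d_%ddel", pos, pos + 1))
    expect_true(shifted$consequence$kind %in% c("frameshift", "stop-loss"))
  }
})

test_that("CDS validation and FASTA reading work together", {
  expect_error(validateCodingSequence("ATGAAATT"), "multiple of 3")
  expect_error(validateCodingSequence("TTGAAATAA"), "start with ATG")
  expect_error(validateCodingSequence("ATGAAAAAA"), "stop codon")
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">cds1", "ATGAAACTCTTAGGGTAA"), path)
  seqs <- readCdsFasta(path)
  expect_identical(unname(seqs["cds1"]), "ATGAAACTCTTAGGGTAA")
})
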