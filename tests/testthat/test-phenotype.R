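DOWN <- "↓"; UP <- "↑"

test_that("HR grading follows the arrow cut-offs with strict boundaries", {
  expect_identical(gradeHr(-4.5), strrep(DOWN, 3))
  expect_identical(gradeHr(-4), strrep(DOWN, 2))   # -4 exactly is not below -4
  expect_identical(gradeHr(-1.7), DOWN)
  expect_identical(gradeHr(0), "-")
  expect_identical(gradeHr(1.5), "-")
  expect_identical(gradeHr(1.7), UP)
  expect_identical(gradeHr(2.6), strrep(UP, 2))
  expect_identical(gradeHr(4.2), strrep(UP, 3))
})

test_that("grade transcription inverts grading on representative values", {
  grades <- c(strrep(DOWN, 3), strrep(DOWN, 2), DOWN, "-",
              UP, strrep(UP, 2), strrep(UP, 3))
  z <- hrGradeToZ(grades)
  expect_identical(gradeHr(z), grades)
  expect_true(is.na(hrGradeToZ("n.a.")))
  expect_error(hrGradeToZ("?"), "unknown grade")
})

test_that("grading is monotone: a more extreme z never weakens the grade", {
  rank <- setNames(1:7, c(strrep(DOWN, 3), strrep(DOWN, 2), DOWN, "-",
                          UP, strrep(UP, 2), strrep(UP, 3)))
  z <- seq(-6, 6, by = 0.1)
  expect_true(all(diff(rank[gradeHr(z)]) >= 0))
})

test_that("viability grading uses relative decrease with strict boundaries", {
  expect_identical(gradeViability(rep(400, 3), rep(1000, 3))$grade, "++")
  expect_identical(gradeViability(rep(600, 3), rep(1000, 3))$grade, "+")
  expect_identical(gradeViability(rep(1000, 3), rep(1000, 3))$grade, "-")
  expect_identical(gradeViability(rep(500, 3), rep(1000, 3))$grade, "+")  # r = 0.5 is not above 0.5
  expect_identical(gradeViability(rep(750, 3), rep(1000, 3))$grade, "-")
  expect_error(gradeViability(rep(5, 3), rep(0, 3)), "Rluc")
})

test_that("sensitivity grading double-normalizes and has inclusive boundaries", {
  g <- function(d) gradeSensitivity(rep(700 * (1 - d), 3), rep(1000, 3),
                                    rep(700, 3), rep(1000, 3))
  expect_identical(g(0.45)$grade, "+++")
  expect_identical(g(0.40)$grade, "+++")  # inclusive
  expect_identical(g(0.30)$grade, "++")
  expect_identical(g(0.10)$grade, "+")
  expect_identical(g(0)$grade, "-")
  expect_equal(g(0.45)$decrease, 0.45, tolerance = 1e-12)
  # a pure viability effect (same ratio under treatment) is not sensitivity
  pure <- gradeSensitivity(rep(350, 3), rep(500, 3), rep(700, 3), rep(1000, 3))
  expect_identical(pure$grade, "-")
  expect_error(gradeSensitivity(1:3, rep(0, 3), 1:3, 1:3), "untreated")
})

test_that("sensitivity grading is invariant to scaling a condition pair", {
  set.seed(5)
  for (i in 1:10) {
    gt <- runif(3, 100, 900); gu <- runif(3, 500, 1500)
    rt <- runif(3, 400, 800); ru <- runif(3, 800, 1200)
    base <- gradeSensitivity(gt, gu, rt, ru)
    scaled <- gradeSensitivity(3.7 * gt, 3.7 * gu, rt, ru)
    expect_identical(scaled$grade, base$grade)
    expect_equal(scaled$decrease, base$decrease, tolerance = 1e-12)
  }
})

test_that("gamma-H2AX classification matches an independent t-test oracle", {
  gene <- data.frame(timepoint = rep(c("no_IR", "1h", "6h"), each = 3),
                     value = c(5, 6, 5, 60, 62, 61, 10, 12, 11))
  rluc <- data.frame(timepoint = rep(c("no_IR", "1h", "6h"), each = 3),
                     value = c(5, 5, 6, 60, 61, 62, 20, 21, 22))
  res <- classifyH2ax(gene, rluc)
  det6 <- res$details[res$details$timepoint == "6h", ]
  expect_equal(det6$p, tTestOracle(c(10, 12, 11), c(20, 21, 22)),
               tolerance = 1e-10)
  expect_identical(res$annotation, paste(DOWN, "6h"))
  # equal means at both timepoints: nothing annotated
  none <- classifyH2ax(rluc, rluc)
  expect_identical(none$annotation, "-")
  expect_equal(none$details$p, c(1, 1))
})

test_that("gamma-H2AX arrows flip and p is preserved when groups swap", {
  set.seed(8)
  gene <- data.frame(timepoint = rep(c("1h", "6h"), each = 3),
                     value = c(rnorm(3, 70, 2), rnorm(3, 10, 2)))
  rluc <- data.frame(timepoint = rep(c("1h", "6h"), each = 3),
                     value = c(rnorm(3, 60, 2), rnorm(3, 20, 2)))
  a <- classifyH2ax(gene, rluc)
  b <- classifyH2ax(rluc, gene)
  expect_equal(a$details$p, b$details$p, tolerance = 1e-12)
  swap <- c(setNames(DOWN, UP), setNames(UP, DOWN), setNames("", ""))
  expect_identical(unname(swap[a$details$arrow]), b$details$arrow)
  expect_error(classifyH2ax(gene[1, ], rluc), "fewer than 2")
})

test_that("summary table renders n.d., n.a. and rejects duplicates", {
  validated <- data.frame(gene_id = c("gA", "gB"), z1 = c(-5, -3),
                          z2 = c(-3, NA), direction = "decreased",
                          single_trigger = c(FALSE, TRUE), validated = TRUE)
  tab <- buildSummaryTable(validated,
                           gfpGrades = c(gA = "-", gB = "-"),
                           viabilityGrades = c(gA = "-"),
                           sensitivityGrades = data.frame(
                             gene_id = "gA", cisplatin = "+++",
                             mmc = "+", ir = "-"),
                           h2axAnnotations = c(gA = paste(UP, "6h")))
  expect_identical(tab$hr_grade_1, c(strrep(DOWN, 3), strrep(DOWN, 2)))
  expect_identical(tab$hr_grade_2[2], "n.a.")
  expect_identical(tab$cisplatin, c("+++", "n.d."))
  expect_identical(tab$viability_grade[2], "n.d.")
  expect_identical(tab$h2ax[2], "n.d.")
  expect_identical(nrow(buildSummaryTable(validated[0, ])), 0L)
  expect_error(buildSummaryTable(rbind(validated, validated[1, ])),
               "duplicate")
})

test_that("the bundled candidate table reproduces the published row structure", {
  tab <- candidatePhenotypes()
  expect_identical(nrow(tab), 62L)
  down <- grepl(DOWN, tab$hr_grade_1)
  expect_identical(sum(down), 45L)
  expect_identical(sum(grepl(UP, tab$hr_grade_1)), 17L)
  # the counterscreen-positive gene carries n.d. in the assay columns
  mk <- tab[tab$gfp_grade == "+", ]
  expect_identical(nrow(mk), 1L)
  expect_identical(mk$cisplatin, "n.d.")
  expect_identical(sum(tab$viability_grade == "++"), 13L)
})
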