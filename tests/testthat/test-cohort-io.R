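test_that("a synthetic cohort round-trips through write/read unchanged", {
  sp <- mqtlSpec("rs401681")
  tr <- simTruthFromMqtl(sp, nCases = 40L, nControls = 50L, seed = 21L)
  co <- simulateCaseControl(tr)$cohort
  dir <- tempfile("roundtrip")
  paths <- writeCohort(co, dir)
  back <- readCohort(paths["genotype"], paths["methylation"],
                     paths["covariates"], paths["outcome"], sp)
  expect_identical(colnames(back), colnames(co))
  expect_identical(genotypes(back), genotypes(co))
  expect_identical(caseStatus(back), caseStatus(co))
  expect_equal(mvalues(back), mvalues(co), tolerance = 1e-12)
  cv0 <- covariateTable(co); cv1 <- covariateTable(back)
  expect_identical(names(cv1), names(cv0))
  for (nm in names(cv0)) {
    if (is.numeric(cv0[[nm]]))
      expect_equal(cv1[[nm]], cv0[[nm]], tolerance = 1e-12)
    else expect_identical(as.character(cv1[[nm]]), as.character(cv0[[nm]]))
  }
})

test_that("readCohort validates tables and joins by the genotype order", {
  sp <- mqtlSpec("rs798766")
  dir <- tempfile("io")
  dir.create(dir)
  g <- data.frame(subject_id = c("b", "a"), rs798766 = c(1L, 2L))
  m <- data.frame(subject_id = c("a", "b"), cg00006948 = c(0.5, -0.3))
  cv <- data.frame(subject_id = c("a", "b"), age = c(60, 70))
  y <- data.frame(subject_id = c("a", "b"), case = c(1L, 0L))
  w <- function(df, f) {
    p <- file.path(dir, f)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(w(g, "g.tsv"), w(m, "m.tsv"), w(cv, "c.tsv"), w(y, "y.tsv"))
  co <- readCohort(paths[1], paths[2], paths[3], paths[4], sp)
  # genotype-table order wins
  expect_identical(colnames(co), c("b", "a"))
  expect_equal(unname(mvalues(co)["cg00006948", ]), c(-0.3, 0.5))

  # comma-delimited tables are accepted too
  pg <- file.path(dir, "g.csv")
  write.csv(g, pg, row.names = FALSE, quote = FALSE)
  co2 <- readCohort(pg, paths[2], paths[3], paths[4], sp)
  expect_identical(genotypes(co2), genotypes(co))

  # missing CpG column -> format error
  m2 <- w(data.frame(subject_id = c("a", "b"), cgWRONG = c(1, 2)),
          "m2.tsv")
  expect_error(readCohort(paths[1], m2, paths[3], paths[4], sp),
               "lacks CpG")
  # disjoint subject ids -> validation error
  y2 <- w(data.frame(subject_id = c("x", "z"), case = c(1L, 0L)),
          "y2.tsv")
  expect_error(readCohort(paths[1], paths[2], paths[3], y2, sp),
               "share no subject ids")
  # duplicate subject id -> format error
  g2 <- w(data.frame(subject_id = c("a", "a"), rs798766 = c(1L, 1L)),
          "g2.tsv")
  expect_error(readCohort(g2, paths[2], paths[3], paths[4], sp),
               "duplicate subject id")
  # genotype outside {0,1,2,NA} -> validation error
  g3 <- w(data.frame(subject_id = c("a", "b"), rs798766 = c(3L, 1L)),
          "g3.tsv")
  expect_error(readCohort(g3, paths[2], paths[3], paths[4], sp),
               "genotype outside")
})

test_that("beta-scale methylation input is converted to M-values", {
  sp <- mqtlSpec("rs798766")
  dir <- tempfile("beta")
  dir.create(dir)
  w <- function(df, f) {
    p <- file.path(dir, f)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  pg <- w(data.frame(subject_id = c("a", "b"), rs798766 = c(0L, 2L)),
          "g.tsv")
  pm <- w(data.frame(subject_id = c("a", "b"),
                     cg00006948 = c(0.8, 0.2)), "m.tsv")
  pc <- w(data.frame(subject_id = c("a", "b"), age = c(55, 65)), "c.tsv")
  py <- w(data.frame(subject_id = c("a", "b"), case = c(1L, 0L)),
          "y.tsv")
  co <- readCohort(pg, pm, pc, py, sp, methylationScale = "beta")
  expect_equal(unname(mvalues(co)["cg00006948", ]), c(2, -2))
})

test_that("exclusions are order-attributed and reconcile", {
  co <- makeExclusionFixture()
  out <- applyExclusions(co)
  rep <- out$report
  expect_equal(rep@nInput, 880L)
  expect_equal(unname(rep@excluded), c(1L, 35L, 8L))
  expect_equal(rep@nRetained, 836L)
  expect_equal(rep@nInput, rep@nRetained + sum(rep@excluded))
  expect_equal(ncol(out$cohort), 836L)
  # brute-force recount: union of rule hits equals total excluded
  cv <- covariateTable(co)
  anyHit <- is.na(cv$race) | is.na(cv$pack_years) |
    cv$extraction %in% c("Salt", "Bioserve")
  expect_equal(sum(anyHit), sum(rep@excluded))
  tab <- exclusionReportTable(rep)
  expect_equal(tab$n, c(880L, 1L, 35L, 8L, 836L))
})

test_that("empty rule list is the identity and full exclusion errors", {
  co <- makeSimpleCohort(n = 50, seed = 4)
  out <- applyExclusions(co, list())
  expect_equal(out$report@nRetained, 50L)
  expect_equal(sum(out$report@excluded), 0L)
  expect_identical(colnames(out$cohort), colnames(co))
  expect_error(
    applyExclusions(co, list(all = function(x) rep(TRUE, ncol(x)))),
    "all subjects excluded")
})
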