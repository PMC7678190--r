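test_that("genotype simulation honours the allele frequency and HWE", {
  expect_identical(simulateGenotypes(50, 0, seed = 1), rep(0L, 50))
  g <- simulateGenotypes(10000, 0.5, seed = 2)
  expect_gt(mean(g), 0.97)   # binomial SE bound around 1.0
  expect_lt(mean(g), 1.03)
  g2 <- simulateGenotypes(10000, 0.49, seed = 3)
  counts <- c(sum(g2 == 2), sum(g2 == 1), sum(g2 == 0))
  expect_gt(hweChisq(counts)$p.value, 0.001)
  expect_identical(simulateGenotypes(100, 0.3, seed = 4),
                   simulateGenotypes(100, 0.3, seed = 4))
})

test_that("null mQTL effects centre every genotype group at baseline", {
  sp <- new("MqtlSpec", snpId = "s", snpLocation = NA_character_,
            region = NA_character_, gene = NA_character_,
            riskAllele = "T", raf = 0.5,
            cpgs = data.frame(cpg_id = "cgX",
                              cpg_location = NA_character_,
                              cpg_gene = NA_character_, direction = 1,
                              effect_size = 0))
  g <- rep(0:2, each = 3000)
  M <- simulateMethylation(g, sp, baselineBeta = 0.3, seed = 5)
  centre <- betaToMvalue(0.3)
  for (gg in 0:2)
    expect_equal(mean(M[g == gg, 1]), centre, tolerance = 0.05)
})

test_that("the homozygote beta difference is recovered from simulated data", {
  sp <- mqtlSpec("rs401681")  # cg27028750: +0.059
  g <- rep(c(0L, 2L), each = 5000)
  M <- simulateMethylation(g, sp, seed = 6)
  medBeta <- function(x) mvalueToBeta(median(x))
  diff <- medBeta(M[g == 2, "cg27028750"]) -
    medBeta(M[g == 0, "cg27028750"])
  expect_lt(abs(diff - 0.059), 0.01)
  diff2 <- medBeta(M[g == 2, "cg26209169"]) -
    medBeta(M[g == 0, "cg26209169"])
  expect_lt(abs(diff2 - (-0.038)), 0.01)
})

test_that("flipping the direction column flips the fitted beta1 sign", {
  sp <- mqtlSpec("rs401681")
  spFlip <- sp
  spFlip@cpgs$direction <- -spFlip@cpgs$direction
  set.seed(7)
  g <- rbinom(4000, 2, sp@raf)
  y <- rep_len(c(1L, 0L), 4000)
  fitB1 <- function(spec) {
    M <- simulateMethylation(g, spec, seed = 8)
    co <- MethCohort(genotype = g, mvalues = M,
                     covariates = data.frame(row.names = seq_len(4000)),
                     case = y)
    fits <- fitMediatorModels(co, analysisSpec("s", colnames(M)))
    vapply(fits, function(f) f@beta1, numeric(1))
  }
  b <- fitB1(sp)
  bf <- fitB1(spFlip)
  expect_equal(sign(b), c(cg27028750 = 1, cg26209169 = -1))
  expect_equal(sign(bf), -sign(b))
})

test_that("out-of-range shifted beta-values name the offending CpG", {
  sp <- mqtlSpec("rs401681")
  expect_error(simulateMethylation(0:2, sp, baselineBeta = 0.99),
               "cg27028750")
})

test_that("covariate marginals match their targets and structure", {
  cv <- simulateCovariates(1e5, seed = 9)
  nev <- mean(cv$smoking == "Never")
  expect_gt(nev, 0.54); expect_lt(nev, 0.56)
  expect_true(all(cv$pack_years[cv$smoking == "Never"] == 0))
  expect_true(all(cv$pack_years[cv$smoking != "Never"] > 0))
  expect_true(all(cv$enrollment_year %in% 1994:1998))
  expect_true(all(cv$age >= 50 & cv$age <= 80))
  expect_identical(simulateCovariates(50, seed = 10),
                   simulateCovariates(50, seed = 10))
})

test_that("case-control sampling hits the design counts and prevalence", {
  tr <- simTruth(nCases = 412L, nControls = 424L, seed = 12L)
  sim <- simulateCaseControl(tr)
  expect_equal(nCases(sim$cohort), 412L)
  expect_equal(nControls(sim$cohort), 424L)
  expect_lt(abs(sim$truth@achievedPrevalence - 0.01) / 0.01, 0.1)
  expect_true(is.finite(sim$truth@theta0))
  # determinism: the same truth reproduces the cohort exactly
  sim2 <- simulateCaseControl(tr)
  expect_identical(genotypes(sim2$cohort), genotypes(sim$cohort))
  expect_identical(mvalues(sim2$cohort), mvalues(sim$cohort))
  expect_identical(caseStatus(sim2$cohort), caseStatus(sim$cohort))
  # infeasible design is a generation error
  small <- simTruth(nCases = 500L, nControls = 100L,
                    nPopulation = 1000L, seed = 13L)
  expect_error(simulateCaseControl(small), "too few cases")
})

test_that("closed-form truth matches hand arithmetic", {
  tr <- simTruth(cpgIds = c("a", "b"), beta1 = c(0.5, -0.2),
                 theta2 = c(0.1, 0.2), theta1 = log(1.2),
                 includeCovariates = FALSE)
  cf <- closedFormTruth(tr)
  # sum beta1 theta2 = 0.05 - 0.04 = 0.01
  expect_equal(cf$or_nie, exp(0.01))
  expect_equal(cf$or_nde, 1.2)
  expect_equal(cf$or_te, 1.2 * exp(0.01))
  tr0 <- simTruth(beta1 = 0, theta2 = 0.7, includeCovariates = FALSE)
  expect_equal(closedFormTruth(tr0)$or_nie, 1)
})

test_that("|log true NIE| grows with a mediator's |beta1 theta2|", {
  last <- 0
  for (s in c(0.05, 0.1, 0.2, 0.4)) {
    tr <- simTruth(beta1 = 0.2, theta2 = s, includeCovariates = FALSE)
    cur <- abs(log(closedFormTruth(tr)$or_nie))
    expect_gt(cur, last)
    last <- cur
  }
})

test_that("interaction closed forms agree with the Monte-Carlo oracle", {
  tr <- simTruth(theta3 = 0.3, theta2 = 0.4, beta1 = 0.25,
                 prevalence = 0.005, includeCovariates = FALSE,
                 seed = 14L)
  cf <- closedFormTruth(tr)
  mc <- mcCounterfactualTruth(tr, nPopulation = 3e5)
  for (k in c("or_nde", "or_nie", "or_te"))
    expect_lt(abs(mc[[k]] - cf[[k]]) / cf[[k]], 0.02)
})

test_that("simulateStudy emits the four joined tables", {
  dir <- tempfile("study")
  out <- simulateStudy(nCases = 60L, nControls = 80L, seed = 15L,
                       dir = dir)
  tabs <- out$tables
  expect_identical(names(tabs),
                   c("genotype", "methylation", "covariates", "outcome"))
  expect_equal(nrow(tabs$genotype), 140L)
  expect_identical(sort(setdiff(names(tabs$genotype), "subject_id")),
                   sort(unique(mqtlTable()$snp_id)))
  expect_identical(setdiff(names(tabs$methylation), "subject_id"),
                   mqtlTable()$cpg_id)
  expect_equal(sum(tabs$outcome$case), 60L)
  expect_true(all(file.exists(out$paths)))
})
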