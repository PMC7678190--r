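# Constructed coefficient fixtures for the pure effect formulas.
mkOfit <- function(theta1, theta2, theta3 = numeric(0)) {
  new("OutcomeFit", theta0 = -2, theta1 = theta1, theta2 = theta2,
      theta3 = theta3, theta4 = stats::setNames(numeric(0), character(0)),
      converged = TRUE, nUsed = 100L)
}
mkMfit <- function(cpg, beta1, beta0 = 0, sigma2 = 0.25) {
  new("MediatorFit", cpgId = cpg, beta0 = beta0, beta1 = beta1,
      beta2 = stats::setNames(numeric(0), character(0)), sigma2 = sigma2,
      nUsed = 50L)
}

test_that("logistic outcome fit agrees with an independent IRLS fit", {
  co <- makeSimpleCohort(n = 300, K = 2, seed = 7)
  spec <- simpleSpec(K = 2)
  of <- fitOutcomeModel(co, spec)
  X <- cbind(1, genotypes(co), t(mvalues(co)),
             covariateTable(co)$age)
  oracle <- irlsLogistic(X, caseStatus(co))
  got <- c(of@theta0, of@theta1, unname(of@theta2), unname(of@theta4))
  expect_equal(got, unname(oracle), tolerance = 1e-6)
})

test_that("null outcome coefficients are recovered within 3 SE", {
  set.seed(17)
  n <- 2000
  A <- rbinom(n, 2, 0.4)
  M <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "cg1"))
  y <- rbinom(n, 1, 0.3)  # independent of A and M: theta1 = theta2 = 0
  co <- MethCohort(genotype = A, mvalues = M,
                   covariates = data.frame(row.names = seq_len(n)),
                   case = y, snpId = "rs_null")
  of <- fitOutcomeModel(co, analysisSpec("rs_null", "cg1"))
  se <- sqrt(diag(vcov(glm(y ~ A + M, family = binomial()))))
  expect_lt(abs(of@theta1), 3 * se[["A"]])
  expect_lt(abs(of@theta2[["cg1"]]), 3 * se[["M"]])
})

test_that("degenerate outcome designs error explicitly", {
  co <- makeSimpleCohort(n = 100, seed = 9)
  co0 <- MethCohort(genotype = rep(1L, 100),
                    mvalues = t(mvalues(co)),
                    covariates = covariateTable(co),
                    case = caseStatus(co))
  expect_error(fitOutcomeModel(co0, simpleSpec()), "no contrast")
  # duplicated mediator column -> rank deficiency
  M <- t(mvalues(co))
  M2 <- cbind(M, cg3 = M[, 1])
  co2 <- MethCohort(genotype = genotypes(co), mvalues = M2,
                    covariates = covariateTable(co),
                    case = caseStatus(co))
  expect_error(
    fitOutcomeModel(co2, analysisSpec("rs_test", c("cg1", "cg2", "cg3"),
                                      covariates = "age")),
    "rank deficient")
})

test_that("mediator models recover the exposure effect among controls", {
  set.seed(23)
  n <- 2100
  A <- rbinom(n, 2, 0.4)
  M <- matrix(0.3 * A + rnorm(n, sd = 0.5), ncol = 1,
              dimnames = list(NULL, "cg1"))
  y <- c(rep(1L, 100), rep(0L, n - 100))  # ~2000 controls
  co <- MethCohort(genotype = A, mvalues = M,
                   covariates = data.frame(row.names = seq_len(n)),
                   case = y)
  mf <- fitMediatorModels(co, analysisSpec("s", "cg1"))[[1]]
  ctl <- y == 0
  se <- sqrt(mf@sigma2 / sum((A[ctl] - mean(A[ctl]))^2))
  expect_lt(abs(mf@beta1 - 0.3), 3 * se)
  expect_equal(mf@nUsed, sum(ctl))
})

test_that("zero-noise mediators give exact coefficients and sigma2 = 0", {
  set.seed(24)
  n <- 60
  A <- rbinom(n, 2, 0.5)
  M <- matrix(1.5 - 0.3 * A, ncol = 1, dimnames = list(NULL, "cg1"))
  y <- rep_len(c(1L, 0L), n)
  co <- MethCohort(genotype = A, mvalues = M,
                   covariates = data.frame(row.names = seq_len(n)),
                   case = y)
  mf <- fitMediatorModels(co, analysisSpec("s", "cg1"))[[1]]
  expect_equal(mf@beta0, 1.5, tolerance = 1e-10)
  expect_equal(mf@beta1, -0.3, tolerance = 1e-10)
  expect_equal(mf@sigma2, 0, tolerance = 1e-16)
})

test_that("mediator fits are driven by controls only", {
  co <- makeSimpleCohort(n = 400, K = 2, seed = 25)
  spec <- simpleSpec(K = 2)
  base <- fitMediatorModels(co, spec)
  # corrupt every case subject's mediator values; fits must not move
  M <- t(mvalues(co))
  M[caseStatus(co) == 1L, ] <- 99
  co2 <- MethCohort(genotype = genotypes(co), mvalues = M,
                    covariates = covariateTable(co),
                    case = caseStatus(co))
  scrambled <- fitMediatorModels(co2, spec)
  for (k in seq_along(base)) {
    expect_equal(scrambled[[k]]@beta1, base[[k]]@beta1, tolerance = 1e-12)
    expect_equal(scrambled[[k]]@sigma2, base[[k]]@sigma2,
                 tolerance = 1e-12)
  }
})

test_that("NDE follows exp(theta1 (a - astar))", {
  spec1 <- analysisSpec("s", "cg1")
  expect_equal(naturalDirectEffect(mkOfit(0, c(cg1 = 0.5)), spec1), 1.0)
  expect_equal(naturalDirectEffect(mkOfit(log(1.36), c(cg1 = 0.2)),
                                   spec1), 1.36)
  spec20 <- analysisSpec("s", "cg1", a = 2, astar = 0)
  expect_equal(naturalDirectEffect(mkOfit(0.1, c(cg1 = 0)), spec20),
               exp(0.2))
  ispec <- analysisSpec("s", "cg1", interaction = TRUE)
  expect_error(naturalDirectEffect(mkOfit(0.1, c(cg1 = 0), theta3 = 0.2),
                                   ispec), "effectsWithInteraction")
})

test_that("NIE sums per-mediator products and allows cancellation", {
  spec <- analysisSpec("s", c("cg1", "cg2"))
  of <- mkOfit(0.1, c(cg1 = 0.4, cg2 = 0.5))
  mf <- list(mkMfit("cg1", 0.5), mkMfit("cg2", -0.2))
  out <- naturalIndirectEffect(mf, of, spec)
  expect_equal(out$or, exp(0.5 * 0.4 - 0.2 * 0.5))  # exp(0.1)
  expect_equal(unname(out$contributions), c(0.2, -0.1))

  # no exposure -> mediator path
  mf0 <- list(mkMfit("cg1", 0), mkMfit("cg2", 0))
  expect_equal(naturalIndirectEffect(mf0, of, spec)$or, 1.0)

  # exact cancellation: beta1_1 theta2_1 = -beta1_2 theta2_2
  ofc <- mkOfit(0.1, c(cg1 = 0.4, cg2 = 0.4))
  mfc <- list(mkMfit("cg1", 0.5), mkMfit("cg2", -0.5))
  expect_identical(naturalIndirectEffect(mfc, ofc, spec)$or, 1.0)

  # misaligned ordering is a contract error
  expect_error(naturalIndirectEffect(rev(mf), of, spec), "misaligned")
})

test_that("NIE is invariant to mediator listing order", {
  co <- makeSimpleCohort(n = 600, K = 2, seed = 26)
  r12 <- runMediation(co, analysisSpec("rs_test", c("cg1", "cg2"),
                                       covariates = "age"))
  r21 <- runMediation(co, analysisSpec("rs_test", c("cg2", "cg1"),
                                       covariates = "age"))
  expect_equal(r12@estimates[["or_nie"]], r21@estimates[["or_nie"]],
               tolerance = 1e-12)
})

test_that("total effect is the product, exactly, on the log scale", {
  expect_equal(totalEffect(1.0, 1.0), 1.0)
  nde <- 1.2345; nie <- 0.8765
  expect_equal(totalEffect(nde, nie), exp(log(nde) + log(nie)),
               tolerance = 1e-12)
  expect_error(totalEffect(-1, 1), "> 0")
  # plug-in identity through the full estimator
  co <- makeSimpleCohort(n = 500, seed = 27)
  r <- runMediation(co, simpleSpec())
  expect_equal(r@estimates[["or_te"]],
               r@estimates[["or_nde"]] * r@estimates[["or_nie"]],
               tolerance = 1e-12)
})

test_that("both NIE-percent conventions match hand arithmetic", {
  expect_equal(niePercent(1, 1.2, "or_ratio"), 100)
  # printed-value worked examples
  expect_equal(niePercent(1.04, 1.10, "proportion_mediated"),
               100 * 1.04 * 0.10 / (1.04 * 1.10 - 1))
  expect_equal(niePercent(1.04, 1.10, "proportion_mediated"), 72.22,
               tolerance = 1e-3)
  expect_equal(niePercent(1.01, 1.05, "or_ratio"), 100 / 1.01)
  expect_equal(niePercent(1.01, 1.05, "or_ratio"), 99.01,
               tolerance = 1e-3)
  # TE = 1 leaves the proportion mediated undefined
  expect_true(is.na(niePercent(2, 0.5, "proportion_mediated")))
})

test_that("interaction closed forms reduce exactly when theta3 = 0", {
  spec <- analysisSpec("s", "cg1")
  ispec <- analysisSpec("s", "cg1", interaction = TRUE)
  of0 <- mkOfit(0.25, c(cg1 = 0.4))
  ofi <- mkOfit(0.25, c(cg1 = 0.4), theta3 = 0)
  mf <- mkMfit("cg1", beta1 = 0.3, beta0 = 1.1, sigma2 = 0.36)
  eff <- effectsWithInteraction(ofi, mf, ispec)
  expect_equal(eff$or_nde, naturalDirectEffect(of0, spec),
               tolerance = 1e-12)
  expect_equal(eff$or_nie,
               naturalIndirectEffect(list(mf), of0, spec)$or,
               tolerance = 1e-12)
  expect_equal(eff$or_cde, exp(0.25), tolerance = 1e-12)  # any m
  eff2 <- effectsWithInteraction(ofi, mf, ispec, m = 5)
  expect_equal(eff2$or_cde, exp(0.25), tolerance = 1e-12)
})

test_that("runMediation and the public interaction ops agree", {
  tr <- simTruth(theta3 = 0.3, theta2 = 0.4, beta1 = 0.25,
                 includeCovariates = FALSE, nCases = 300L,
                 nControls = 400L, seed = 41L)
  co <- simulateCaseControl(tr)$cohort
  ispec <- analysisSpec(tr@snpId, tr@cpgIds, interaction = TRUE)
  of <- fitOutcomeModel(co, ispec)
  mf <- fitMediatorModels(co, ispec)[[1]]
  eff <- effectsWithInteraction(of, mf, ispec)
  r <- runMediation(co, ispec)
  expect_equal(r@estimates[["or_nde"]], eff$or_nde, tolerance = 1e-12)
  expect_equal(r@estimates[["or_nie"]], eff$or_nie, tolerance = 1e-12)
  expect_equal(r@orCde, eff$or_cde, tolerance = 1e-12)
  expect_error(analysisSpec("s", c("cg1", "cg2"), interaction = TRUE),
               "K = 1")
})

test_that("independent mediators make the multi-mediator log NIE additive", {
  tr <- simTruth(cpgIds = c("cg1", "cg2"), beta1 = c(0.2, -0.15),
                 theta2 = c(0.4, 0.3), includeCovariates = FALSE,
                 nCases = 4000L, nControls = 4000L, seed = 51L)
  co <- simulateCaseControl(tr)$cohort
  multi <- runMediation(co, analysisSpec(tr@snpId, c("cg1", "cg2")))
  s1 <- runMediation(co, analysisSpec(tr@snpId, "cg1"))
  s2 <- runMediation(co, analysisSpec(tr@snpId, "cg2"))
  expect_equal(log(multi@estimates[["or_nie"]]),
               log(s1@estimates[["or_nie"]]) +
                 log(s2@estimates[["or_nie"]]),
               tolerance = 0.02)
})
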