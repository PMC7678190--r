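# Shared fixtures and independent oracles, all built in code.

# Hand-written Newton-Raphson (IRLS) logistic fit, independent of the
# package's fitting path; used as the two-implementation oracle.
irlsLogistic <- function(X, y, tol = 1e-12, maxit = 60L) {
  b <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    bn <- drop(solve(crossprod(X, X * W), crossprod(X, W * z)))
    if (max(abs(bn - b)) < tol) return(bn)
    b <- bn
  }
  b
}

# Small cohort built directly (no file IO): K mediators linked to the
# genotype, optional simple continuous covariate, outcome from a logistic
# model.
makeSimpleCohort <- function(n = 400, K = 2, beta1 = 0.3, theta1 = 0.2,
                             theta2 = 0.4, withAge = TRUE, seed = 1) {
  set.seed(seed)
  A <- rbinom(n, 2, 0.4)
  age <- if (withAge) runif(n, 50, 80) else NULL
  M <- sapply(seq_len(K), function(k)
    beta1 * A + (if (withAge) 0.01 * age else 0) + rnorm(n, sd = 0.5))
  colnames(M) <- paste0("cg", seq_len(K))
  lp <- -1 + theta1 * A + drop(M %*% rep(theta2, K)) +
    (if (withAge) 0.005 * age else 0)
  y <- rbinom(n, 1, plogis(lp))
  covs <- if (withAge) data.frame(age = age) else
    data.frame(row.names = seq_len(n))
  MethCohort(genotype = A, mvalues = M, covariates = covs, case = y,
             snpId = "rs_test")
}

simpleSpec <- function(K = 2, withAge = TRUE, ...) {
  analysisSpec("rs_test", paste0("cg", seq_len(K)),
               covariates = if (withAge) "age" else character(0), ...)
}

# 880-subject fixture reproducing the study's exclusion arithmetic:
# one subject missing race (also missing pack-years, to exercise
# first-rule attribution), 35 further subjects missing pack-years only,
# 8 with a disallowed DNA extraction method.
makeExclusionFixture <- function(seed = 99) {
  set.seed(seed)
  n <- 880
  race <- rep("White", n)
  pack <- runif(n, 0, 40)
  extraction <- rep("5-prime", n)
  race[1] <- NA
  pack[1:36] <- NA                      # subject 1 hit by two rules
  extraction[37:44] <- rep(c("Salt", "Bioserve"), 4)
  M <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "cg1"))
  MethCohort(genotype = rbinom(n, 2, 0.3), mvalues = M,
             covariates = data.frame(race = race, pack_years = pack,
                                     extraction = extraction,
                                     stringsAsFactors = FALSE),
             case = rep_len(c(1L, 0L), n), snpId = "rs_test")
}

# Table-2-like five-mediator truth used by the calibration studies.
recoveryTruth <- function(logNie = 0.1, nCases = 2000L,
                          nControls = 2000L, seed = 1L, ...) {
  simTruthFromMqtl(mqtlSpec("rs2294008"), theta1 = log(1.04),
                   logNie = logNie, nCases = nCases,
                   nControls = nControls, seed = seed, ...)
}

recoverySpec <- function() {
  analysisSpec("rs2294008", mqtlSpec("rs2294008")@cpgs$cpg_id,
               covariates = studyCovariates())
}
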