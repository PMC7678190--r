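# Synthetic case-control cohorts with the statistical structure the
# analysis assumes: Hardy-Weinberg genotypes, mQTL-driven methylation on
# the M-value scale, study-like covariates, and a rare logistic disease
# model sampled case-control. A closed-form oracle of the true effects
# doubles as the recovery-test reference.

#' Simulate risk-allele counts under Hardy-Weinberg equilibrium
#'
#' Independent draws from Binomial(2, raf).
#'
#' @param n number of subjects.
#' @param raf risk-allele frequency in [0, 1].
#' @param seed optional seed (caller's RNG state is preserved).
#' @return integer vector of counts in \{0, 1, 2\}.
#' @export
simulateGenotypes <- function(n, raf, seed = NULL) {
  if (raf < 0 || raf > 1) stop("raf must be in [0, 1]")
  .withSeed(seed, function() stats::rbinom(n, 2L, raf))
}

#' Simulate mQTL-driven methylation M-values
#'
#' Each CpG's mean beta-value is the baseline shifted by
#' \code{direction * effect_size / 2} per risk allele (the homozygote
#' difference split additively between the two allele steps), converted to
#' the M-value scale, plus Gaussian residual noise on the M scale.
#'
#' @param genotypes risk-allele counts.
#' @param spec an [MqtlSpec-class] providing directions and effect sizes.
#' @param baselineBeta baseline proportion methylated per CpG (recycled;
#'   default 0.5).
#' @param residualSd residual standard deviation on the M scale per CpG
#'   (recycled; default 0.5).
#' @param seed optional seed.
#' @return numeric matrix (subjects x CpGs) of M-values.
#' @export
simulateMethylation <- function(genotypes, spec, baselineBeta = 0.5,
                                residualSd = 0.5, seed = NULL) {
  K <- nrow(spec@cpgs)
  n <- length(genotypes)
  baselineBeta <- rep_len(baselineBeta, K)
  residualSd <- rep_len(residualSd, K)
  shift <- spec@cpgs$direction * spec@cpgs$effect_size / 2
  meanBeta <- outer(rep(1, n), baselineBeta) + outer(genotypes, shift)
  bad <- meanBeta <= 0 | meanBeta >= 1
  if (any(bad)) {
    j <- which(colSums(bad) > 0)[1L]
    stop("shifted beta-value outside (0, 1) for CpG ",
         spec@cpgs$cpg_id[j])
  }
  meanM <- betaToMvalue(meanBeta)
  M <- .withSeed(seed, function() {
    meanM + sweep(matrix(stats::rnorm(n * K), n, K), 2L, residualSd, `*`)
  })
  colnames(M) <- spec@cpgs$cpg_id
  M
}

#' Default covariate marginals for the synthetic cohort
#'
#' Marginal distributions emulating the control arm of a postmenopausal
#' case-control study: trial arm, age bands (uniform within band),
#' enrollment year, follow-up time, DNA extraction method, race/ethnicity,
#' smoking status (never 0.55, former 0.41, current 0.04) and pack-years
#' (structurally 0 for never-smokers, log-normal otherwise). All entries
#' can be overridden.
#'
#' @return list of marginal specifications consumed by
#'   [simulateCovariates()].
#' @export
covariateMarginals <- function() {
  list(
    arm = c(OS = 0.52, HT_DM = 0.06, HT = 0.13, DM = 0.29),
    ageBands = data.frame(lo = c(50, 60, 70), hi = c(60, 70, 80),
                          prob = c(0.24, 0.48, 0.28)),
    year = c(`1994` = 0.13, `1995` = 0.13, `1996` = 0.30, `1997` = 0.27,
             `1998` = 0.17),
    followup = c(1, 15),
    extraction = c(`5-prime` = 0.96, Phenol = 0.04),
    race = c(White = 0.823, Asian_PI = 0.028, Black = 0.094,
             Hispanic = 0.038, Other = 0.017),
    smoking = c(Never = 0.55, Former = 0.41, Current = 0.04),
    packYearsLog = c(meanlog = 2.85, sdlog = 1.0)
  )
}

#' Simulate a raw covariate table
#'
#' Draws one row per subject from the marginals of [covariateMarginals()],
#' in a fixed documented order (arm, age band, age, enrollment year,
#' follow-up, extraction, race, smoking, pack-years), so a fixed seed
#' reproduces the table exactly. Never-smokers always have pack-years 0.
#'
#' @param n number of subjects.
#' @param marginals marginal specification, see [covariateMarginals()].
#' @param seed optional seed.
#' @return data.frame of raw covariates (calendar enrollment years).
#' @export
simulateCovariates <- function(n, marginals = covariateMarginals(),
                               seed = NULL) {
  stopifnot(n >= 1)
  m <- marginals
  .withSeed(seed, function() {
    arm <- sample(names(m$arm), n, replace = TRUE, prob = m$arm)
    band <- sample.int(nrow(m$ageBands), n, replace = TRUE,
                       prob = m$ageBands$prob)
    age <- stats::runif(n, m$ageBands$lo[band], m$ageBands$hi[band])
    year <- as.integer(sample(names(m$year), n, replace = TRUE,
                              prob = m$year))
    followup <- stats::runif(n, m$followup[1L], m$followup[2L])
    extraction <- sample(names(m$extraction), n, replace = TRUE,
                         prob = m$extraction)
    race <- sample(names(m$race), n, replace = TRUE, prob = m$race)
    smoking <- sample(names(m$smoking), n, replace = TRUE,
                      prob = m$smoking)
    py <- stats::rlnorm(n, m$packYearsLog[["meanlog"]],
                        m$packYearsLog[["sdlog"]])
    py[smoking == "Never"] <- 0
    data.frame(arm = arm, age = age, enrollment_year = year,
               followup_years = followup, extraction = extraction,
               race = race, smoking = smoking, pack_years = py,
               stringsAsFactors = FALSE)
  })
}

#' Construct a SimTruth
#'
#' Defines the generating model of a synthetic cohort: per-CpG mediator
#' models M_i = beta0_i + beta1_i A + beta2_i' c + N(0, residualSd_i^2) on
#' the M-value scale, and the population disease model
#' logit P(Y = 1) = theta0 + theta1 A + sum_i theta2_i M_i
#' (+ theta3 A M_1) + theta4' c, with theta0 tuned to the target
#' prevalence by [simulateCaseControl()].
#'
#' @param snpId,cpgIds labels; defaults are a single synthetic CpG.
#' @param raf risk-allele frequency.
#' @param beta0,beta1,residualSd per-CpG mediator-model intercept,
#'   per-allele effect and residual sd (M-value scale).
#' @param beta2 list of named numeric vectors (one per CpG) of covariate
#'   effects on the mediator over encoded design columns; empty = none.
#' @param theta1 log odds ratio per risk allele (direct).
#' @param theta2 per-CpG mediator log odds ratios.
#' @param theta3 optional exposure-mediator interaction (K = 1 only);
#'   numeric(0) = none.
#' @param theta4 named covariate log odds ratios over encoded design
#'   columns; default a smoking-driven gradient (current vs never log-OR
#'   log 4, former log 1.5, 0.01 per pack-year).
#' @param prevalence target population disease prevalence, in (0, 0.05]
#'   to honour the rare-disease regime.
#' @param nCases,nControls case-control sample sizes (default 412 / 424).
#' @param nPopulation population size; NA = derived from the prevalence
#'   and required counts with a 30 percent margin.
#' @param includeCovariates draw the covariate table and apply theta4 /
#'   beta2 (default TRUE); FALSE gives a covariate-free cohort.
#' @param seed integer seed making the whole cohort reproducible.
#' @return a [SimTruth-class].
#' @export
simTruth <- function(snpId = "rs_sim", cpgIds = "cg_sim1", raf = 0.49,
                     beta0 = 0, beta1 = 0.2, residualSd = 0.5,
                     beta2 = list(), theta1 = log(1.1), theta2 = 0.5,
                     theta3 = numeric(0),
                     theta4 = c(smokingFormer = log(1.5),
                                smokingCurrent = log(4),
                                pack_years = 0.01),
                     prevalence = 0.01, nCases = 412L, nControls = 424L,
                     nPopulation = NA_integer_, includeCovariates = TRUE,
                     seed = 1L) {
  K <- length(cpgIds)
  if (!includeCovariates) theta4 <- stats::setNames(numeric(0), character(0))
  new("SimTruth", snpId = snpId, cpgIds = cpgIds, raf = raf,
      beta0 = rep_len(beta0, K), beta1 = rep_len(beta1, K),
      beta2 = beta2, residualSd = rep_len(residualSd, K),
      theta0 = NA_real_, theta1 = theta1, theta2 = rep_len(theta2, K),
      theta3 = theta3, theta4 = theta4, prevalence = prevalence,
      nCases = as.integer(nCases), nControls = as.integer(nControls),
      nPopulation = as.integer(nPopulation),
      includeCovariates = isTRUE(includeCovariates),
      achievedPrevalence = NA_real_, seed = as.integer(seed))
}

#' SimTruth with mediator effects taken from an MqtlSpec
#'
#' Converts the per-CpG homozygote beta-scale differences of an mQTL
#' specification into per-allele M-value effects (beta1) at the given
#' baseline, and chooses theta2 proportional to beta1 so that the true
#' log NIE, sum_i beta1_i theta2_i, equals \code{logNie} exactly.
#'
#' @param spec an [MqtlSpec-class].
#' @param theta1 direct-effect log OR per risk allele.
#' @param logNie target true log NIE across the SNP's CpGs.
#' @param baselineBeta baseline proportion methylated.
#' @param ... further arguments passed to [simTruth()]
#'   (\code{residualSd}, sample sizes, \code{prevalence}, \code{seed}, ...).
#' @return a [SimTruth-class].
#' @export
simTruthFromMqtl <- function(spec, theta1 = log(1.1), logNie = 0.1,
                             baselineBeta = 0.5, ...) {
  shift <- spec@cpgs$direction * spec@cpgs$effect_size / 2
  beta1 <- betaToMvalue(baselineBeta + shift) - betaToMvalue(baselineBeta)
  theta2 <- if (logNie == 0) rep(0, length(beta1)) else
    logNie * beta1 / sum(beta1^2)
  simTruth(snpId = spec@snpId, cpgIds = spec@cpgs$cpg_id, raf = spec@raf,
           beta0 = betaToMvalue(baselineBeta), beta1 = beta1,
           theta1 = theta1, theta2 = theta2, ...)
}

# Expand truth@theta4 (named over a subset of encoded columns) to the full
# design; unknown names are an error.
.expandTheta <- function(theta, colNames, what) {
  full <- stats::setNames(numeric(length(colNames)), colNames)
  if (length(theta)) {
    bad <- setdiff(names(theta), colNames)
    if (length(bad))
      stop(what, " names not among encoded covariate columns: ",
           paste(bad, collapse = ", "))
    full[names(theta)] <- theta
  }
  full
}

# Population pieces shared by the sampler and the Monte-Carlo oracle.
# Draw order: genotypes, covariates, mediator residuals.
.drawPopulation <- function(truth, n) {
  g <- as.numeric(stats::rbinom(n, 2L, truth@raf))
  if (truth@includeCovariates) {
    covdf <- simulateCovariates(n)
    C <- encodeCovariates(covdf)
  } else {
    covdf <- data.frame(row.names = seq_len(n))
    C <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  K <- length(truth@cpgIds)
  eps <- sweep(matrix(stats::rnorm(n * K), n, K), 2L, truth@residualSd, `*`)
  CB2 <- matrix(0, n, K)
  if (length(truth@beta2)) {
    if (length(truth@beta2) != K)
      stop("beta2 must have one entry per CpG")
    for (k in seq_len(K)) {
      bk <- .expandTheta(truth@beta2[[k]], colnames(C), "beta2")
      if (length(bk)) CB2[, k] <- C %*% bk
    }
  }
  list(g = g, covdf = covdf, C = C, eps = eps, CB2 = CB2)
}

.mediatorValues <- function(truth, pop, a) {
  sweep(pop$CB2 + pop$eps, 2L, truth@beta0, `+`) +
    outer(a, truth@beta1)
}

.linearPredictor <- function(truth, pop, g, M) {
  lp <- truth@theta1 * g + drop(M %*% truth@theta2)
  if (ncol(pop$C)) {
    th4 <- .expandTheta(truth@theta4, colnames(pop$C), "theta4")
    lp <- lp + drop(pop$C %*% th4)
  }
  if (length(truth@theta3)) lp <- lp + truth@theta3 * g * M[, 1L]
  lp
}

# Bisection on the intercept so the mean simulated disease probability hits
# the target prevalence (relative tolerance tolRel, cap maxit).
.tuneTheta0 <- function(lp, target, tolRel = 0.1, maxit = 60L) {
  lo <- -40; hi <- 10
  mid <- NA_real_
  for (it in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    p <- mean(stats::plogis(mid + lp))
    if (abs(p - target) <= tolRel * target) return(mid)
    if (p > target) hi <- mid else lo <- mid
  }
  stop("failed to tune the disease-model intercept to prevalence ",
       target)
}

#' Simulate a nested case-control cohort from a SimTruth
#'
#' Generates a population (genotypes, covariates, mediators, disease status
#' from the logistic model with the intercept tuned by bisection to the
#' target prevalence), then samples the requested numbers of cases and
#' controls without replacement. Identical truth (including seed) gives an
#' identical cohort.
#'
#' @param truth a [SimTruth-class].
#' @return list with \code{cohort} (a [MethCohort-class]) and \code{truth}
#'   (the input with \code{theta0}, \code{nPopulation} and
#'   \code{achievedPrevalence} filled in).
#' @export
simulateCaseControl <- function(truth) {
  stopifnot(is(truth, "SimTruth"))
  n <- truth@nPopulation
  if (is.na(n))
    n <- as.integer(ceiling(1.3 * max(truth@nCases / truth@prevalence,
                                      truth@nControls /
                                        (1 - truth@prevalence))))
  .withSeed(truth@seed, function() {
    pop <- .drawPopulation(truth, n)
    M <- .mediatorValues(truth, pop, pop$g)
    lp <- .linearPredictor(truth, pop, pop$g, M)
    theta0 <- .tuneTheta0(lp, truth@prevalence)
    p <- stats::plogis(theta0 + lp)
    y <- stats::rbinom(n, 1L, p)
    caseIdx <- which(y == 1L)
    ctlIdx <- which(y == 0L)
    if (length(caseIdx) < truth@nCases || length(ctlIdx) < truth@nControls)
      stop("population generated too few cases or controls; ",
           "increase nPopulation")
    sel <- c(sample(caseIdx, truth@nCases),
             sample(ctlIdx, truth@nControls))
    Msel <- M[sel, , drop = FALSE]
    colnames(Msel) <- truth@cpgIds
    cohort <- MethCohort(
      genotype = pop$g[sel], mvalues = Msel,
      covariates = pop$covdf[sel, , drop = FALSE],
      case = y[sel],
      subjectIds = sprintf("S%06d", seq_along(sel)),
      snpId = truth@snpId)
    out <- truth
    out@theta0 <- theta0
    out@nPopulation <- n
    out@achievedPrevalence <- mean(p)
    list(cohort = cohort, truth = out)
  })
}

#' Closed-form true effects of a SimTruth
#'
#' Plugs the generating coefficients into the rare-outcome effect formulas:
#' without interaction, NDE = exp(theta1 (a - astar)) and
#' NIE = exp((a - astar) sum_i beta1_i theta2_i); with a theta3 interaction
#' (K = 1) the single-mediator closed forms of
#' [effectsWithInteraction()] evaluated at the generating parameters and a
#' zero covariate profile (generating beta2 effects on the mediator require
#' an explicit \code{profile}).
#'
#' @param truth a [SimTruth-class].
#' @param a,astar exposure contrast (default per risk allele, 1 vs 0).
#' @param profile covariate profile for the interaction forms when beta2
#'   effects are present.
#' @return list with \code{or_nde}, \code{or_nie}, \code{or_te} and the
#'   per-mediator \code{contributions}.
#' @export
closedFormTruth <- function(truth, a = 1, astar = 0, profile = NULL) {
  if (truth@prevalence > 0.05)
    warning("prevalence above 0.05: rare-outcome effect formulas degrade")
  d <- a - astar
  contributions <- stats::setNames(truth@beta1 * truth@theta2,
                                   truth@cpgIds)
  if (!length(truth@theta3)) {
    nde <- exp(truth@theta1 * d)
    nie <- exp(d * sum(contributions))
  } else {
    if (length(truth@beta2) && is.null(profile))
      stop("generating beta2 effects present: supply a covariate profile")
    beta2c <- if (length(truth@beta2))
      sum(.expandTheta(truth@beta2[[1L]], names(profile), "beta2") *
            profile) else 0
    s2 <- truth@residualSd[1L]^2
    th3 <- truth@theta3
    nde <- exp((truth@theta1 + th3 * (truth@beta0[1L] +
                  truth@beta1[1L] * astar + beta2c +
                  truth@theta2[1L] * s2)) * d +
               0.5 * th3^2 * s2 * (a^2 - astar^2))
    nie <- exp((truth@theta2[1L] * truth@beta1[1L] +
                  th3 * truth@beta1[1L] * a) * d)
  }
  list(or_nde = nde, or_nie = nie, or_te = nde * nie,
       contributions = contributions)
}

#' Monte-Carlo counterfactual evaluation of the true effects
#'
#' Independent check of [closedFormTruth()]: simulates a large population,
#' constructs the counterfactual mediator values M(a) and M(astar) with
#' common residuals, and compares the population odds of disease under
#' (a, M(a)), (a, M(astar)) and (astar, M(astar)). Expectations of the
#' disease probability are averaged directly (no Bernoulli draws), so the
#' evaluator is deterministic given the seed and variance-reduced by common
#' random numbers. The disease-model intercept is taken from the truth
#' when already tuned, otherwise tuned here on the natural population.
#'
#' @param truth a [SimTruth-class].
#' @param nPopulation Monte-Carlo population size (default 500000).
#' @param a,astar exposure contrast.
#' @param seed seed for the Monte-Carlo population (default truth seed + 1).
#' @return list with \code{or_nde}, \code{or_nie}, \code{or_te} and the
#'   \code{theta0} used.
#' @export
mcCounterfactualTruth <- function(truth, nPopulation = 5e5, a = 1,
                                  astar = 0, seed = truth@seed + 1L) {
  n <- as.integer(nPopulation)
  .withSeed(seed, function() {
    pop <- .drawPopulation(truth, n)
    theta0 <- truth@theta0
    if (is.na(theta0)) {
      Mnat <- .mediatorValues(truth, pop, pop$g)
      theta0 <- .tuneTheta0(
        .linearPredictor(truth, pop, pop$g, Mnat), truth@prevalence)
    }
    Ma <- .mediatorValues(truth, pop, rep(a, n))
    Ms <- .mediatorValues(truth, pop, rep(astar, n))
    pOf <- function(x, M)
      mean(stats::plogis(theta0 +
        .linearPredictor(truth, pop, rep(x, n), M)))
    odds <- function(p) p / (1 - p)
    paa <- pOf(a, Ma); pas <- pOf(a, Ms); pss <- pOf(astar, Ms)
    list(or_nde = odds(pas) / odds(pss),
         or_nie = odds(paa) / odds(pas),
         or_te = odds(paa) / odds(pss),
         theta0 = theta0)
  })
}

#' Simulate a complete multi-SNP study and its four input tables
#'
#' Generates one population in which every SNP of the mQTL table acts on
#' disease both directly and through its own CpG sites (SNPs independent,
#' as for variants on different chromosomes), samples cases and controls,
#' and returns -- optionally writing -- the four tables [readCohort()]
#' consumes. Per-allele mediator effects come from the table's directions
#' and effect sizes at the baseline beta-value; mediator disease effects
#' default to \code{theta2Scale} in each CpG's direction of association,
#' and per-SNP direct effects default to modest log odds ratios.
#'
#' @param table mQTL-CpG table (default the packaged fixture).
#' @param nCases,nControls sample sizes (default 412 / 424).
#' @param prevalence target population prevalence (default 0.01).
#' @param theta1 named per-SNP direct-effect log ORs; defaults emulate the
#'   per-risk-allele effect sizes typical of the four packaged SNPs.
#' @param theta2Scale magnitude of each CpG's disease log OR, signed by
#'   its direction column (default 0.4).
#' @param baselineBeta,residualSd methylation baseline and M-scale noise.
#' @param theta4 covariate disease effects as in [simTruth()].
#' @param seed integer seed.
#' @param dir optional directory; when given, the four tables are written
#'   there as TSV (genotype.tsv with one column per SNP, methylation.tsv,
#'   covariates.tsv, outcome.tsv).
#' @return invisible list with \code{tables} (the four data.frames),
#'   \code{paths} (when written), and \code{truth} (generating parameters
#'   incl. the tuned theta0 and achieved prevalence).
#' @export
simulateStudy <- function(table = mqtlTable(), nCases = 412L,
                          nControls = 424L, prevalence = 0.01,
                          theta1 = NULL, theta2Scale = 0.4,
                          baselineBeta = 0.5, residualSd = 0.5,
                          theta4 = c(smokingFormer = log(1.5),
                                     smokingCurrent = log(4),
                                     pack_years = 0.01),
                          seed = 1L, dir = NULL) {
  snps <- unique(table$snp_id)
  if (is.null(theta1)) {
    defaults <- c(rs798766 = log(1.16), rs401681 = log(1.01),
                  rs2294008 = log(1.04), rs8102137 = log(1.36))
    theta1 <- stats::setNames(
      ifelse(snps %in% names(defaults), defaults[snps], log(1.1)), snps)
  }
  if (!all(snps %in% names(theta1)))
    stop("theta1 must be named and cover every SNP in the table")
  n <- as.integer(ceiling(1.3 * max(nCases / prevalence,
                                    nControls / (1 - prevalence))))
  .withSeed(seed, function() {
    G <- vapply(snps, function(s)
      as.numeric(stats::rbinom(n, 2L,
                               table$raf[table$snp_id == s][1L])),
      numeric(n))
    covdf <- simulateCovariates(n)
    C <- encodeCovariates(covdf)
    th4 <- .expandTheta(theta4, colnames(C), "theta4")
    sign <- ifelse(table$direction == "+", 1, -1)
    shift <- sign * table$effect_size / 2
    beta1 <- betaToMvalue(baselineBeta + shift) -
      betaToMvalue(baselineBeta)
    theta2 <- theta2Scale * sign
    nCpg <- nrow(table)
    M <- matrix(betaToMvalue(baselineBeta), n, nCpg) +
      G[, table$snp_id, drop = FALSE] %*% diag(beta1, nCpg) +
      matrix(stats::rnorm(n * nCpg, sd = residualSd), n, nCpg)
    colnames(M) <- table$cpg_id
    lp <- drop(G %*% theta1[snps]) + drop(M %*% theta2) +
      drop(C %*% th4)
    theta0 <- .tuneTheta0(lp, prevalence)
    p <- stats::plogis(theta0 + lp)
    y <- stats::rbinom(n, 1L, p)
    caseIdx <- which(y == 1L); ctlIdx <- which(y == 0L)
    if (length(caseIdx) < nCases || length(ctlIdx) < nControls)
      stop("population generated too few cases or controls")
    sel <- c(sample(caseIdx, nCases), sample(ctlIdx, nControls))
    ids <- sprintf("S%06d", seq_along(sel))
    tables <- list(
      genotype = data.frame(subject_id = ids,
                            G[sel, , drop = FALSE],
                            check.names = FALSE),
      methylation = data.frame(subject_id = ids,
                               M[sel, , drop = FALSE],
                               check.names = FALSE),
      covariates = data.frame(subject_id = ids,
                              covdf[sel, , drop = FALSE],
                              check.names = FALSE, row.names = NULL),
      outcome = data.frame(subject_id = ids, case = y[sel]))
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- vapply(names(tables), function(nm) {
        path <- file.path(dir, paste0(nm, ".tsv"))
        utils::write.table(tables[[nm]], path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        path
      }, character(1))
    }
    invisible(list(tables = tables, paths = paths,
                   truth = list(theta0 = theta0, theta1 = theta1,
                                theta2 = stats::setNames(theta2,
                                                         table$cpg_id),
                                beta1 = stats::setNames(beta1,
                                                        table$cpg_id),
                                achievedPrevalence = mean(p),
                                seed = seed)))
  })
}

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", object@snpId, "with", length(object@cpgIds),
      "mediator(s)\n")
  cat(sprintf("  raf %.2f  theta1 %.4f  prevalence %.3f\n", object@raf,
              object@theta1, object@prevalence))
  cat(sprintf("  true log NIE: %.4f\n",
              sum(object@beta1 * object@theta2)))
  cat(sprintf("  design: %d cases / %d controls, seed %d\n",
              object@nCases, object@nControls, object@seed))
  invisible(NULL)
})
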