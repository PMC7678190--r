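# Model fitting: logistic outcome model (all subjects) and linear mediator
# models (controls only). Internal numeric engines are shared with the
# bootstrap so resample refits avoid re-encoding covariates.

#' Construct an AnalysisSpec
#'
#' @param snpId exposure SNP label.
#' @param cpgIds character vector of K mediator CpG ids; their order fixes
#'   the mediator indexing of the fits and effects.
#' @param covariates raw covariate names to adjust for (must be declared in
#'   [covariateSchema()]); default none (unadjusted). Use
#'   [studyCovariates()] for the full study adjustment set.
#' @param a,astar exposure contrast levels; the default 1 vs 0 gives
#'   per-risk-allele odds ratios.
#' @param interaction include an exposure-mediator product term in the
#'   outcome model (single mediator only).
#' @return an [AnalysisSpec-class].
#' @export
analysisSpec <- function(snpId, cpgIds, covariates = character(0),
                         a = 1, astar = 0, interaction = FALSE) {
  new("AnalysisSpec", snpId = as.character(snpId),
      cpgIds = as.character(cpgIds),
      covariates = as.character(covariates),
      a = a, astar = astar, interaction = isTRUE(interaction))
}

#' The full study covariate adjustment set
#'
#' Raw covariate names for the matching variables and confounders used in
#' the study models: trial arm, age at baseline, enrollment year, follow-up
#' time, DNA extraction method, race/ethnicity, smoking status and
#' pack-years of smoking.
#'
#' @return character vector of raw covariate names.
#' @export
studyCovariates <- function() {
  c("arm", "age", "enrollment_year", "followup_years", "extraction",
    "race", "smoking", "pack_years")
}

# Assemble aligned numeric pieces for one cohort/spec; complete cases only.
.mediationData <- function(cohort, spec) {
  stopifnot(is(cohort, "MethCohort"), is(spec, "AnalysisSpec"))
  A <- as.numeric(genotypes(cohort))
  y <- as.numeric(caseStatus(cohort))
  Mall <- t(mvalues(cohort))
  miss <- setdiff(spec@cpgIds, colnames(Mall))
  if (length(miss))
    stop("cohort lacks mediator CpG(s): ", paste(miss, collapse = ", "))
  M <- Mall[, spec@cpgIds, drop = FALSE]
  C <- encodeCovariates(covariateTable(cohort), which = spec@covariates)
  if (anyNA(A) || anyNA(y) || anyNA(M) || anyNA(C))
    stop("missing values present; apply exclusions first ",
         "(complete-case analysis)")
  if (!any(y == 1) || !any(y == 0))
    stop("cohort must contain at least one case and one control")
  list(y = y, A = A, M = M, C = C)
}

.outcomeDesign <- function(d, spec) {
  X <- cbind(`(Intercept)` = 1, A = d$A, d$M, d$C)
  if (spec@interaction) X <- cbind(X, `A:M` = d$A * d$M[, 1L])
  X
}

.mediatorDesign <- function(d) {
  cbind(`(Intercept)` = 1, A = d$A, d$C)
}

# Maximum-likelihood logistic fit. `core` names the columns whose
# coefficients enter the effect formulas (intercept, exposure, mediators,
# interaction): rank deficiency or divergence there is a hard error.
# Nuisance covariate columns follow standard GLM practice instead --
# aliased columns are pivoted out (NA coefficient, excluded from the
# model) and a diverging dummy for a perfectly predicted cell is
# tolerated, as lm/glm do.
.fitLogistic <- function(X, y, core = colnames(X)) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 100L)))
  coefs <- fit$coefficients
  if (any(is.na(coefs[core])))
    stop("design error: outcome design matrix is rank deficient in the ",
         "exposure/mediator columns")
  if (!fit$converged)
    stop("logistic fit did not converge within 100 iterations")
  if (max(abs(coefs[core])) > 30)
    stop("logistic fit diverged (|coefficient| > 30); ",
         "separation suspected")
  list(coefficients = coefs, converged = fit$converged, n = length(y))
}

# OLS with (possibly) matrix response. Aliased nuisance columns are
# pivoted out as in lm.fit; aliasing in `core` columns is a design error.
# Unbiased residual variance with denominator n - rank (n - p - 2 for a
# full-rank design with p covariate columns).
.fitOLS <- function(X, Y, core = colnames(X)) {
  Y <- as.matrix(Y)
  if (nrow(X) <= ncol(X))
    stop("too few observations for the mediator model (need > ",
         ncol(X), " controls)")
  fit <- stats::lm.fit(X, Y)
  co <- as.matrix(fit$coefficients)
  if (any(is.na(co[core, ])))
    stop("design error: mediator design matrix is rank deficient in the ",
         "exposure column")
  res <- as.matrix(fit$residuals)
  sigma2 <- colSums(res^2) / (nrow(X) - fit$rank)
  list(coefficients = co, sigma2 = sigma2, n = nrow(X))
}

#' Fit the logistic outcome model
#'
#' Maximum-likelihood logistic regression of case status on the risk-allele
#' count, all K mediator M-values and the encoded covariates, fit among all
#' subjects (cases and controls). Under the interaction flag (K = 1) an
#' exposure-mediator product term is added.
#'
#' @param cohort a [MethCohort-class] with exclusions already applied.
#' @param spec an [AnalysisSpec-class].
#' @return an [OutcomeFit-class].
#' @export
fitOutcomeModel <- function(cohort, spec) {
  d <- .mediationData(cohort, spec)
  if (stats::var(d$A) == 0)
    stop("design error: exposure has no contrast (constant genotype)")
  X <- .outcomeDesign(d, spec)
  core <- c("(Intercept)", "A", spec@cpgIds,
            if (spec@interaction) "A:M")
  fit <- .fitLogistic(X, d$y, core = core)
  co <- fit$coefficients
  K <- length(spec@cpgIds)
  covNames <- colnames(d$C)
  new("OutcomeFit",
      theta0 = unname(co[1L]),
      theta1 = unname(co["A"]),
      theta2 = co[spec@cpgIds],
      theta3 = if (spec@interaction) unname(co["A:M"]) else numeric(0),
      theta4 = if (length(covNames)) co[covNames] else
        stats::setNames(numeric(0), character(0)),
      converged = fit$converged, nUsed = as.integer(fit$n))
}

#' Fit the linear mediator models among controls
#'
#' Ordinary least squares of each mediator M-value on the risk-allele count
#' and the encoded covariates, restricted internally to controls
#' (case status 0); passing a cohort that still contains cases changes
#' nothing. Residual variance uses the unbiased denominator
#' n - (covariate columns) - 2.
#'
#' @inheritParams fitOutcomeModel
#' @return list of K [MediatorFit-class] objects named and ordered by
#'   \code{spec@cpgIds}.
#' @export
fitMediatorModels <- function(cohort, spec) {
  d <- .mediationData(cohort, spec)
  ctl <- d$y == 0
  Xm <- .mediatorDesign(d)[ctl, , drop = FALSE]
  fit <- .fitOLS(Xm, d$M[ctl, , drop = FALSE],
                 core = c("(Intercept)", "A"))
  covNames <- colnames(d$C)
  out <- lapply(seq_along(spec@cpgIds), function(i) {
    co <- fit$coefficients[, i]
    new("MediatorFit",
        cpgId = spec@cpgIds[i],
        beta0 = unname(co[1L]),
        beta1 = unname(co["A"]),
        beta2 = if (length(covNames)) co[covNames] else
          stats::setNames(numeric(0), character(0)),
        sigma2 = unname(fit$sigma2[i]),
        nUsed = as.integer(fit$n))
  })
  names(out) <- spec@cpgIds
  out
}

setMethod("show", "OutcomeFit", function(object) {
  cat("OutcomeFit (logistic, cases + controls, n =", object@nUsed, ")\n")
  cat(sprintf("  theta0 (intercept): %.4f\n", object@theta0))
  cat(sprintf("  theta1 (exposure):  %.4f  [OR %.3f]\n", object@theta1,
              exp(object@theta1)))
  for (nm in names(object@theta2))
    cat(sprintf("  theta2[%s]: %.4f\n", nm, object@theta2[[nm]]))
  if (length(object@theta3))
    cat(sprintf("  theta3 (A x M): %.4f\n", object@theta3))
  if (length(object@theta4))
    cat("  theta4:", length(object@theta4), "covariate coefficient(s)\n")
  invisible(NULL)
})

setMethod("show", "MediatorFit", function(object) {
  cat(sprintf("MediatorFit %s (controls only, n = %d)\n", object@cpgId,
              object@nUsed))
  cat(sprintf("  beta0 %.4f  beta1 %.4f  sigma2 %.4f\n", object@beta0,
              object@beta1, object@sigma2))
  invisible(NULL)
})
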