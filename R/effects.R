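# Effect decomposition on the odds-ratio scale under the rare-disease
# approximation: NDE = exp(theta1 (a - a*)),
# NIE = exp((a - a*) sum_i beta1_i theta2_i), TE = NDE * NIE, plus the
# closed forms for the single-mediator interaction model.

#' Natural direct effect odds ratio
#'
#' exp(theta1 (a - astar)); with the default per-risk-allele contrast,
#' exp(theta1). Valid for the no-interaction model only.
#'
#' @param ofit an [OutcomeFit-class] without interaction term.
#' @param spec the [AnalysisSpec-class] that produced the fit.
#' @return odds ratio (> 0).
#' @export
naturalDirectEffect <- function(ofit, spec) {
  if (spec@interaction || length(ofit@theta3))
    stop("model has an exposure-mediator interaction; ",
         "use effectsWithInteraction()")
  exp(ofit@theta1 * (spec@a - spec@astar))
}

#' Natural indirect effect odds ratio through K mediators
#'
#' exp((a - astar) sum_i beta1_i theta2_i). The sum lets individual
#' mediators cancel one another, reflecting that the SNP shifts all its CpG
#' sites simultaneously. Mediator fits must be aligned (same CpGs, same
#' order) with the outcome fit's theta2 vector.
#'
#' @param mfits list of [MediatorFit-class], ordered as \code{spec@cpgIds}.
#' @param ofit an [OutcomeFit-class].
#' @param spec the [AnalysisSpec-class].
#' @return list with \code{or} (the NIE odds ratio) and
#'   \code{contributions} (named per-mediator products beta1_i theta2_i).
#' @export
naturalIndirectEffect <- function(mfits, ofit, spec) {
  ids <- vapply(mfits, function(f) f@cpgId, character(1))
  if (!identical(unname(ids), unname(names(ofit@theta2))) ||
      !identical(unname(ids), unname(spec@cpgIds)))
    stop("mediator ordering misaligned between mediator fits, ",
         "outcome fit and spec")
  beta1 <- vapply(mfits, function(f) f@beta1, numeric(1))
  contributions <- stats::setNames(beta1 * unname(ofit@theta2), ids)
  list(or = exp((spec@a - spec@astar) * sum(contributions)),
       contributions = contributions)
}

#' Total effect odds ratio
#'
#' The product of the NDE and NIE odds ratios. For plug-in point estimates
#' this decomposition is an exact identity; bootstrap interval endpoints
#' need not satisfy it.
#'
#' @param nde,nie odds ratios (> 0).
#' @return odds ratio.
#' @export
totalEffect <- function(nde, nie) {
  .assertScalarNumber(nde, "nde")
  .assertScalarNumber(nie, "nie")
  if (nde <= 0 || nie <= 0) stop("odds ratios must be > 0")
  nde * nie
}

#' Percent of the total effect attributed to the indirect pathway
#'
#' Two conventions are computed:
#' \describe{
#'   \item{\code{or_ratio}}{100 * NIE / TE (= 100 / NDE), the ratio of the
#'     indirect-effect OR to the total-effect OR. The default.}
#'   \item{\code{proportion_mediated}}{100 * NDE (NIE - 1) / (NDE NIE - 1),
#'     the excess-odds proportion mediated; undefined (NA) when TE = 1.}
#' }
#'
#' @param nde,nie odds ratios (> 0).
#' @param method which convention to return.
#' @return percent (possibly outside [0, 100] when effects oppose), or NA
#'   when undefined.
#' @examples
#' niePercent(1, 1.2)            # all of the effect is indirect: 100
#' niePercent(1.04, 1.10, "proportion_mediated")
#' @export
niePercent <- function(nde, nie,
                       method = c("or_ratio", "proportion_mediated")) {
  method <- match.arg(method)
  te <- totalEffect(nde, nie)
  if (method == "or_ratio") return(100 * nie / te)
  if (abs(te - 1) < 1e-12) return(NA_real_)
  100 * nde * (nie - 1) / (te - 1)
}

#' Effect decomposition under an exposure-mediator interaction (K = 1)
#'
#' Rare-outcome closed forms for the single-mediator logistic outcome model
#' with product term theta3, given the mediator model coefficients, its
#' residual variance sigma2 and a covariate profile c:
#' \deqn{OR^{NDE} = \exp\{(\theta_1 + \theta_3(\beta_0 + \beta_1 a^* +
#'   \beta_2'c + \theta_2 \sigma^2))(a - a^*) +
#'   \tfrac12 \theta_3^2 \sigma^2 (a^2 - a^{*2})\}}
#' \deqn{OR^{NIE} = \exp\{(\theta_2 \beta_1 + \theta_3 \beta_1 a)
#'   (a - a^*)\}}
#' \deqn{OR^{CDE}(m) = \exp\{(\theta_1 + \theta_3 m)(a - a^*)\}}
#' With theta3 = 0 these reduce exactly to [naturalDirectEffect()] and
#' [naturalIndirectEffect()].
#'
#' @param ofit an [OutcomeFit-class] carrying theta3.
#' @param mfit the single [MediatorFit-class].
#' @param spec an [AnalysisSpec-class] with the interaction flag set.
#' @param profile named covariate profile c on the encoded design columns
#'   (typically control-sample means, see [controlProfile()]); may be NULL
#'   only when the models are unadjusted.
#' @param m mediator level for the controlled direct effect; default the
#'   model mediator mean at the reference exposure and profile,
#'   beta0 + beta1 astar + beta2' c.
#' @return list with \code{or_nde}, \code{or_nie}, \code{or_cde}, the
#'   \code{m} used and the \code{profile} used.
#' @export
effectsWithInteraction <- function(ofit, mfit, spec, profile = NULL,
                                   m = NULL) {
  if (!spec@interaction || length(ofit@theta3) != 1L)
    stop("effectsWithInteraction() requires a single-mediator fit with an ",
         "interaction term")
  beta2 <- mfit@beta2
  if (is.null(profile)) {
    if (length(beta2))
      stop("a covariate profile is required for adjusted models; ",
           "see controlProfile()")
    profile <- stats::setNames(numeric(0), character(0))
  }
  beta2 <- beta2[!is.na(beta2)]  # aliased columns carry no effect
  if (length(beta2) && !all(names(beta2) %in% names(profile)))
    stop("profile must cover every mediator-model covariate column")
  beta2c <- if (length(beta2)) sum(beta2 * profile[names(beta2)]) else 0
  a <- spec@a; astar <- spec@astar; d <- a - astar
  th1 <- ofit@theta1; th2 <- unname(ofit@theta2[1L]); th3 <- ofit@theta3
  s2 <- mfit@sigma2
  if (is.null(m)) m <- mfit@beta0 + mfit@beta1 * astar + beta2c
  logNde <- (th1 + th3 * (mfit@beta0 + mfit@beta1 * astar + beta2c +
                            th2 * s2)) * d +
    0.5 * th3^2 * s2 * (a^2 - astar^2)
  logNie <- (th2 * mfit@beta1 + th3 * mfit@beta1 * a) * d
  logCde <- (th1 + th3 * m) * d
  list(or_nde = exp(logNde), or_nie = exp(logNie), or_cde = exp(logCde),
       m = m, profile = profile)
}

#' Control-sample means of the encoded covariates
#'
#' The default covariate profile for the interaction-model closed forms.
#'
#' @param cohort a [MethCohort-class].
#' @param spec an [AnalysisSpec-class].
#' @return named numeric vector over the encoded design columns.
#' @export
controlProfile <- function(cohort, spec) {
  d <- .mediationData(cohort, spec)
  colMeans(d$C[d$y == 0, , drop = FALSE])
}

# Numeric engine used by both the point estimate and every bootstrap
# resample: all log-scale effects from raw aligned vectors/matrices.
.estimateLogEffects <- function(y, A, M, C, spec, profile = NULL) {
  if (stats::var(A) == 0)
    stop("design error: exposure has no contrast (constant genotype)")
  Xo <- cbind(`(Intercept)` = 1, A = A, M, C)
  if (spec@interaction) Xo <- cbind(Xo, `A:M` = A * M[, 1L])
  core <- c("(Intercept)", "A", spec@cpgIds,
            if (spec@interaction) "A:M")
  of <- .fitLogistic(Xo, y, core = core)
  co <- of$coefficients
  theta1 <- unname(co["A"])
  theta2 <- co[spec@cpgIds]
  ctl <- y == 0
  Xm <- cbind(`(Intercept)` = 1, A = A, C)[ctl, , drop = FALSE]
  mf <- .fitOLS(Xm, M[ctl, , drop = FALSE],
                core = c("(Intercept)", "A"))
  beta1 <- mf$coefficients["A", ]
  a <- spec@a; astar <- spec@astar; d <- a - astar
  contributions <- stats::setNames(beta1 * unname(theta2), spec@cpgIds)
  if (!spec@interaction) {
    logNde <- theta1 * d
    logNie <- d * sum(contributions)
    logCde <- numeric(0)
  } else {
    th3 <- unname(co["A:M"])
    s2 <- unname(mf$sigma2[1L])
    beta0 <- unname(mf$coefficients[1L, 1L])
    covNames <- colnames(C)
    if (is.null(profile))
      profile <- colMeans(C[ctl, , drop = FALSE])
    b2 <- if (length(covNames)) mf$coefficients[covNames, 1L] else
      numeric(0)
    ok <- !is.na(b2)  # aliased covariate columns are excluded
    beta2c <- if (any(ok)) sum(b2[ok] * profile[covNames][ok]) else 0
    th2 <- unname(theta2[1L])
    b1 <- unname(beta1[1L])
    logNde <- (theta1 + th3 * (beta0 + b1 * astar + beta2c + th2 * s2)) *
      d + 0.5 * th3^2 * s2 * (a^2 - astar^2)
    logNie <- (th2 * b1 + th3 * b1 * a) * d
    m <- beta0 + b1 * astar + beta2c
    logCde <- (theta1 + th3 * m) * d
  }
  list(logNde = logNde, logNie = logNie, logTe = logNde + logNie,
       logCde = logCde, contributions = contributions)
}

#' Point-estimate mediation analysis for one SNP
#'
#' Fits the outcome and mediator models and assembles the NDE/NIE/TE
#' decomposition, both NIE-percent conventions and the per-mediator
#' contributions into a [MediationResult-class] (without confidence
#' intervals; see [bootstrapMediation()]).
#'
#' @param cohort a [MethCohort-class] with exclusions applied.
#' @param spec an [AnalysisSpec-class].
#' @param profile covariate profile for the interaction closed forms;
#'   default control-sample means.
#' @return a [MediationResult-class].
#' @export
runMediation <- function(cohort, spec, profile = NULL) {
  d <- .mediationData(cohort, spec)
  est <- .estimateLogEffects(d$y, d$A, d$M, d$C, spec, profile = profile)
  .mediationResult(spec, est)
}

.mediationResult <- function(spec, est, ci = NULL, boot = list(),
                             info = list()) {
  nde <- exp(est$logNde); nie <- exp(est$logNie)
  new("MediationResult",
      snpId = spec@snpId,
      estimates = c(or_nde = nde, or_nie = nie, or_te = exp(est$logTe)),
      niePercent = c(
        or_ratio = niePercent(nde, nie, "or_ratio"),
        proportion_mediated = niePercent(nde, nie, "proportion_mediated")),
      contributions = est$contributions,
      orCde = if (length(est$logCde)) exp(est$logCde) else numeric(0),
      ci = if (is.null(ci))
        matrix(numeric(0), nrow = 0, ncol = 2,
               dimnames = list(NULL, c("lower", "upper"))) else ci,
      boot = boot, spec = spec, info = info)
}

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult:", object@snpId, "\n")
  est <- object@estimates
  hasCi <- nrow(object@ci) == 3L
  lab <- c(or_nde = "NDE", or_nie = "NIE", or_te = "TE")
  for (i in seq_along(est)) {
    line <- sprintf("  %-4s %.3f", lab[[names(est)[i]]], est[[i]])
    if (hasCi)
      line <- paste0(line, sprintf(" (%.3f, %.3f)", object@ci[i, 1L],
                                   object@ci[i, 2L]))
    cat(line, "\n")
  }
  cat(sprintf("  NIE percent: %.1f (OR ratio), %.1f (proportion mediated)\n",
              object@niePercent[["or_ratio"]],
              object@niePercent[["proportion_mediated"]]))
  if (length(object@orCde))
    cat(sprintf("  CDE %.3f (interaction model)\n", object@orCde))
  if (length(object@boot))
    cat(sprintf("  bootstrap: B = %d, dropped = %d, seed = %d\n",
                object@boot$B, object@boot$nDropped, object@boot$seed))
  invisible(NULL)
})
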