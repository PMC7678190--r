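#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' MqtlSpec: one mQTL SNP and its associated CpG sites
#'
#' Describes a methylation quantitative trait locus: the SNP identity, its
#' risk allele and risk-allele frequency, and the CpG sites whose methylation
#' it shifts, with the signed effect size on the beta (proportion-methylated)
#' scale, defined as the difference in median proportion methylated between
#' the two homozygote groups.
#'
#' @slot snpId SNP identifier (e.g. \code{"rs2294008"}).
#' @slot snpLocation genomic location label.
#' @slot region cytogenetic band label.
#' @slot gene gene or locus label.
#' @slot riskAllele risk-allele base.
#' @slot raf risk-allele frequency in (0, 1).
#' @slot cpgs data.frame with one row per CpG: \code{cpg_id},
#'   \code{cpg_location}, \code{cpg_gene}, \code{direction} (+1/-1) and
#'   \code{effect_size} (unsigned homozygote difference, beta scale, < 1).
#' @seealso [mqtlSpec()], [mqtlTable()]
#' @export
setClass("MqtlSpec",
  representation(
    snpId = "character", snpLocation = "character", region = "character",
    gene = "character", riskAllele = "character", raf = "numeric",
    cpgs = "data.frame"
  )
)

setValidity("MqtlSpec", function(object) {
  msg <- character(0)
  if (nrow(object@cpgs) < 1L)
    msg <- c(msg, "at least one CpG site is required (K >= 1)")
  if (length(object@raf) != 1L || !is.finite(object@raf) ||
      object@raf <= 0 || object@raf >= 1)
    msg <- c(msg, "raf must be a single value in (0, 1)")
  need <- c("cpg_id", "direction", "effect_size")
  if (!all(need %in% names(object@cpgs))) {
    msg <- c(msg, sprintf("cpgs must have columns %s",
                          paste(need, collapse = ", ")))
  } else {
    if (!all(object@cpgs$direction %in% c(-1, 1)))
      msg <- c(msg, "direction must be +1 or -1 per CpG")
    if (!all(abs(object@cpgs$effect_size) < 1))
      msg <- c(msg, "|effect_size| must be < 1 (beta scale)")
    if (anyDuplicated(object@cpgs$cpg_id))
      msg <- c(msg, "duplicate cpg_id")
  }
  if (length(msg)) msg else TRUE
})

#' MethCohort: subject-level case-control cohort for mediation analysis
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one methylation
#' M-value assay (CpG sites in rows, subjects in columns) together with the
#' per-subject risk-allele count (\code{genotype}), case indicator
#' (\code{case}) and covariates in \code{colData}. Non-missing genotypes must
#' lie in \{0, 1, 2\} and non-missing case indicators in \{0, 1\}; missing
#' values are permitted at construction and are handled by
#' [applyExclusions()] (complete-case policy).
#'
#' @seealso [MethCohort()] constructor, [genotypes()], [caseStatus()],
#'   [mvalues()], [covariateTable()]
#' @export
setClass("MethCohort", contains = "SummarizedExperiment")

setValidity("MethCohort", function(object) {
  msg <- character(0)
  cd <- colData(object)
  if (!all(c("genotype", "case") %in% names(cd)))
    return("colData must contain 'genotype' and 'case' columns")
  g <- cd$genotype
  if (!all(g[!is.na(g)] %in% 0:2))
    msg <- c(msg, "non-missing genotypes must be risk-allele counts in {0,1,2}")
  y <- cd$case
  if (!all(y[!is.na(y)] %in% 0:1))
    msg <- c(msg, "non-missing case status must be 0 (control) or 1 (case)")
  if (length(SummarizedExperiment::assays(object)) >= 1L) {
    m <- assay(object, 1L)
    if (!is.numeric(m))
      msg <- c(msg, "M-value assay must be numeric")
    else if (any(is.infinite(m)))
      msg <- c(msg, "M-values must be finite (or NA before exclusions)")
  }
  if (length(msg)) msg else TRUE
})

#' ExclusionReport: bookkeeping of subject exclusions
#'
#' Records, for an ordered set of named exclusion rules, how many subjects
#' each rule removed (a subject hit by several rules is attributed to the
#' first), and the retained case/control split. The counts always reconcile:
#' \code{nInput == nRetained + sum(excluded)}.
#'
#' @slot nInput number of subjects before exclusions.
#' @slot excluded named integer vector, one count per rule in declaration order.
#' @slot nRetained number of subjects retained.
#' @slot nCases,nControls retained case/control split.
#' @export
setClass("ExclusionReport",
  representation(nInput = "integer", excluded = "integer",
                 nRetained = "integer", nCases = "integer",
                 nControls = "integer")
)

setValidity("ExclusionReport", function(object) {
  msg <- character(0)
  if (any(c(object@nInput, object@excluded, object@nRetained,
            object@nCases, object@nControls) < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (object@nInput != object@nRetained + sum(object@excluded))
    msg <- c(msg, "counts do not reconcile: nInput != nRetained + sum(excluded)")
  if (length(msg)) msg else TRUE
})

#' AnalysisSpec: what to estimate for one SNP
#'
#' Names the exposure SNP, the K CpG mediators (order fixes the mediator
#' indexing everywhere downstream), the raw covariates to adjust for, the
#' exposure contrast levels \code{a} and \code{astar} (default 1 vs 0, i.e.
#' per risk allele), and whether to include an exposure-mediator interaction
#' (single mediator only).
#'
#' @seealso [analysisSpec()]
#' @export
setClass("AnalysisSpec",
  representation(snpId = "character", cpgIds = "character",
                 covariates = "character", a = "numeric", astar = "numeric",
                 interaction = "logical")
)

setValidity("AnalysisSpec", function(object) {
  msg <- character(0)
  if (length(object@cpgIds) < 1L)
    msg <- c(msg, "at least one mediator CpG is required")
  if (anyDuplicated(object@cpgIds))
    msg <- c(msg, "duplicate mediator cpg ids")
  if (isTRUE(object@a == object@astar))
    msg <- c(msg, "exposure contrast levels a and astar must differ")
  if (isTRUE(object@interaction) && length(object@cpgIds) != 1L)
    msg <- c(msg, "exposure-mediator interaction is supported for K = 1 only")
  if (length(msg)) msg else TRUE
})

#' OutcomeFit: logistic outcome model coefficients
#'
#' Maximum-likelihood fit of the case-control logistic model
#' logit P(Y = 1 | a, m, c) = theta0 + theta1 a + sum_i theta2_i m_i
#' (+ theta3 a m, under interaction) + theta4' c, fit among all subjects.
#'
#' @slot theta0 intercept.
#' @slot theta1 exposure (risk-allele count) coefficient.
#' @slot theta2 named mediator coefficients, one per CpG.
#' @slot theta3 exposure-mediator interaction coefficient (length 0 when the
#'   model has no interaction term).
#' @slot theta4 named covariate coefficients.
#' @slot converged logical convergence flag.
#' @slot nUsed number of subjects in the fit.
#' @export
setClass("OutcomeFit",
  representation(theta0 = "numeric", theta1 = "numeric", theta2 = "numeric",
                 theta3 = "numeric", theta4 = "numeric",
                 converged = "logical", nUsed = "integer")
)

#' MediatorFit: linear model for one CpG mediator, controls only
#'
#' Ordinary least squares fit of E[M | a, c] = beta0 + beta1 a + beta2' c
#' among controls, with unbiased residual variance sigma2 (denominator
#' n - p - 2 for p covariate columns plus exposure and intercept).
#'
#' @slot cpgId mediator identity.
#' @slot beta0 intercept; @slot beta1 exposure coefficient.
#' @slot beta2 named covariate coefficients.
#' @slot sigma2 residual variance (>= 0).
#' @slot nUsed number of controls in the fit.
#' @export
setClass("MediatorFit",
  representation(cpgId = "character", beta0 = "numeric", beta1 = "numeric",
                 beta2 = "numeric", sigma2 = "numeric", nUsed = "integer")
)

setValidity("MediatorFit", function(object) {
  if (length(object@sigma2) == 1L && is.finite(object@sigma2) &&
      object@sigma2 < 0) "sigma2 must be >= 0" else TRUE
})

#' BootstrapConfig: percentile-bootstrap settings
#'
#' @slot B number of resamples (>= 2; 1000 in typical use).
#' @slot seed integer RNG seed; the same seed and inputs give bit-identical
#'   intervals.
#' @slot stratified resample cases and controls separately (default TRUE),
#'   preserving the case/control margin of the design in every resample.
#' @slot level confidence level in (0, 1).
#' @seealso [bootstrapConfig()], [bootstrapMediation()]
#' @export
setClass("BootstrapConfig",
  representation(B = "integer", seed = "integer", stratified = "logical",
                 level = "numeric")
)

setValidity("BootstrapConfig", function(object) {
  msg <- character(0)
  if (object@B < 2L) msg <- c(msg, "B must be >= 2")
  if (object@level <= 0 || object@level >= 1)
    msg <- c(msg, "level must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' MediationResult: effect decomposition for one SNP
#'
#' Point estimates of the per-contrast odds ratios for the natural direct
#' effect (NDE), natural indirect effect (NIE) and total effect (TE), the
#' NIE percent under both conventions, the per-mediator contributions
#' beta1_i * theta2_i to the log NIE, and (after [bootstrapMediation()])
#' percentile confidence intervals. For plug-in point estimates the identity
#' TE = NDE * NIE holds exactly; bootstrap interval endpoints need not
#' satisfy it.
#'
#' @slot snpId SNP label.
#' @slot estimates named numeric: \code{or_nde}, \code{or_nie}, \code{or_te}.
#' @slot niePercent named numeric: \code{or_ratio} (100 * NIE / TE, the
#'   primary definition) and \code{proportion_mediated}
#'   (100 * NDE (NIE - 1) / (NDE NIE - 1)); NA when undefined.
#' @slot contributions named numeric, per-mediator beta1_i * theta2_i.
#' @slot orCde controlled direct effect OR at mediator level m (interaction
#'   model only; length 0 otherwise).
#' @slot ci numeric matrix (rows nde/nie/te, columns lower/upper); 0 rows
#'   until bootstrapped.
#' @slot boot list of bootstrap metadata (B, seed, stratified, level,
#'   nDropped, log-scale resample estimates).
#' @slot spec the [AnalysisSpec-class] analysed.
#' @slot info free-form annotation list (region, gene, risk allele, ...).
#' @export
setClass("MediationResult",
  representation(snpId = "character", estimates = "numeric",
                 niePercent = "numeric", contributions = "numeric",
                 orCde = "numeric", ci = "matrix", boot = "list",
                 spec = "AnalysisSpec", info = "list")
)

setValidity("MediationResult", function(object) {
  est <- object@estimates
  if (!all(c("or_nde", "or_nie", "or_te") %in% names(est)))
    return("estimates must contain or_nde, or_nie, or_te")
  if (any(est <= 0)) return("odds ratios must be > 0")
  TRUE
})

#' SimTruth: generating parameters of a synthetic cohort
#'
#' Records every parameter of the synthetic-cohort generating model: the
#' risk-allele frequency, the linear mediator models on the M-value scale
#' (beta0, beta1 per allele, optional covariate effects beta2, residual sd),
#' the population logistic disease model (theta0 tuned to the target
#' prevalence, theta1, theta2, optional theta3 interaction, covariate
#' effects theta4), the rare-disease sampling design (prevalence in
#' (0, 0.05], case/control counts, population size), and the seed. It is the
#' oracle for parameter-recovery tests via [closedFormTruth()].
#'
#' @seealso [simTruth()], [simulateCaseControl()]
#' @export
setClass("SimTruth",
  representation(snpId = "character", cpgIds = "character", raf = "numeric",
                 beta0 = "numeric", beta1 = "numeric", beta2 = "list",
                 residualSd = "numeric", theta0 = "numeric",
                 theta1 = "numeric", theta2 = "numeric", theta3 = "numeric",
                 theta4 = "numeric", prevalence = "numeric",
                 nCases = "integer", nControls = "integer",
                 nPopulation = "integer", includeCovariates = "logical",
                 achievedPrevalence = "numeric", seed = "integer")
)

setValidity("SimTruth", function(object) {
  msg <- character(0)
  K <- length(object@cpgIds)
  if (K < 1L) msg <- c(msg, "at least one mediator CpG")
  if (length(object@beta1) != K || length(object@theta2) != K ||
      length(object@beta0) != K || length(object@residualSd) != K)
    msg <- c(msg, "beta0, beta1, theta2, residualSd must have one entry per CpG")
  if (object@prevalence <= 0 || object@prevalence > 0.05)
    msg <- c(msg, "prevalence must be in (0, 0.05] (rare-disease regime)")
  if (!all(is.finite(c(object@beta0, object@beta1, object@theta1,
                       object@theta2, object@theta4, object@residualSd))))
    msg <- c(msg, "generating parameters must be finite")
  if (length(object@theta3) == 1L && K != 1L)
    msg <- c(msg, "interaction truth (theta3) requires K = 1")
  if (length(msg)) msg else TRUE
})
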