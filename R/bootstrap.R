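# Percentile-bootstrap inference for the mediation quantities.

#' Construct a BootstrapConfig
#'
#' @param B number of resamples (default 1000).
#' @param seed integer RNG seed; identical seed and inputs give
#'   bit-identical intervals. The caller's RNG state is left untouched.
#' @param stratified resample cases and controls separately (default TRUE),
#'   preserving the fixed case/control margin of the design.
#' @param level confidence level (default 0.95).
#' @return a [BootstrapConfig-class].
#' @export
bootstrapConfig <- function(B = 1000L, seed = 1L, stratified = TRUE,
                            level = 0.95) {
  new("BootstrapConfig", B = as.integer(B), seed = as.integer(seed),
      stratified = isTRUE(stratified), level = level)
}

#' Percentile interval from bootstrap estimates
#'
#' Empirical quantiles at (1 - level)/2 and 1 - (1 - level)/2 under the
#' inclusive linear-interpolation quantile definition
#' (\code{stats::quantile} type 7), fixed for bit-reproducibility. The
#' interval is equivariant under monotone transforms, so intervals computed
#' on the log-OR scale and exponentiated equal intervals of the
#' exponentiated samples.
#'
#' @param samples numeric vector of at least 2 finite estimates; non-finite
#'   values are a contract error (the caller must filter).
#' @param level confidence level in (0, 1).
#' @return numeric \code{c(lower, upper)}.
#' @examples
#' percentileInterval(1:100, 0.95) # 3.475, 97.525
#' @export
percentileInterval <- function(samples, level = 0.95) {
  if (length(samples) < 2L) stop("at least 2 samples are required")
  if (any(!is.finite(samples)))
    stop("non-finite values present; filter before calling")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  alpha <- (1 - level) / 2
  stats::quantile(samples, probs = c(alpha, 1 - alpha), type = 7,
                  names = FALSE)
}

# All resample indices are drawn up front from a single RNG stream in one
# documented order (per resample: case indices, then control indices), so
# intervals are bit-reproducible across platforms for a given seed.
.bootstrapIndices <- function(caseIdx, ctlIdx, n, B, stratified, seed) {
  .withSeed(seed, function() {
    lapply(seq_len(B), function(b) {
      if (stratified)
        c(caseIdx[sample.int(length(caseIdx), replace = TRUE)],
          ctlIdx[sample.int(length(ctlIdx), replace = TRUE)])
      else sample.int(n, replace = TRUE)
    })
  })
}

#' Bootstrap confidence intervals for the mediation decomposition
#'
#' For each of B resamples (stratified by case/control status by default)
#' the outcome model is refit on the full resample and the mediator models
#' on its controls, and the NDE/NIE/TE are recomputed. Percentile intervals
#' are formed on the log-OR scale and exponentiated (equivariant, so purely
#' presentational). Resamples whose fits fail (non-convergence, separation,
#' rank deficiency) are dropped and counted; more than 10 percent dropped,
#' or fewer than 2 usable resamples, is an inference error.
#'
#' Resample indices are drawn in one documented order from a single RNG
#' stream seeded by \code{cfg@seed}: for b = 1, ..., B, case indices then
#' control indices (stratified), or all indices at once (unstratified).
#'
#' @param cohort a [MethCohort-class] with exclusions applied.
#' @param spec an [AnalysisSpec-class].
#' @param cfg a [BootstrapConfig-class].
#' @return a [MediationResult-class] whose point estimates are the plug-in
#'   fits on the original data, with \code{ci} filled (rows nde/nie/te) and
#'   bootstrap metadata (including the log-scale resample estimates) in
#'   \code{boot}.
#' @export
bootstrapMediation <- function(cohort, spec, cfg = bootstrapConfig()) {
  stopifnot(is(cfg, "BootstrapConfig"))
  d <- .mediationData(cohort, spec)
  point <- .estimateLogEffects(d$y, d$A, d$M, d$C, spec)
  n <- length(d$y)
  caseIdx <- which(d$y == 1)
  ctlIdx <- which(d$y == 0)
  B <- cfg@B
  samples <- matrix(NA_real_, nrow = B, ncol = 3L,
                    dimnames = list(NULL, c("nde", "nie", "te")))
  idxList <- .bootstrapIndices(caseIdx, ctlIdx, n, B, cfg@stratified,
                               cfg@seed)
  for (b in seq_len(B)) {
    idx <- idxList[[b]]
    est <- tryCatch(
      .estimateLogEffects(d$y[idx], d$A[idx], d$M[idx, , drop = FALSE],
                          d$C[idx, , drop = FALSE], spec),
      error = function(e) NULL)
    if (!is.null(est))
      samples[b, ] <- c(est$logNde, est$logNie, est$logTe)
  }
  ok <- stats::complete.cases(samples)
  nDropped <- sum(!ok)
  if (nDropped > 0.1 * B)
    stop("inference error: ", nDropped, " of ", B,
         " bootstrap resamples failed to fit (> 10%)")
  if (sum(ok) < 2L)
    stop("inference error: fewer than 2 usable bootstrap resamples")
  use <- samples[ok, , drop = FALSE]
  ci <- t(vapply(c("nde", "nie", "te"), function(k)
    exp(percentileInterval(use[, k], cfg@level)), numeric(2)))
  colnames(ci) <- c("lower", "upper")
  .mediationResult(spec, point, ci = ci,
                   boot = list(B = B, seed = cfg@seed,
                               stratified = cfg@stratified,
                               level = cfg@level, nDropped = nDropped,
                               logSamples = samples))
}
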