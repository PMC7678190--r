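#' Convert between methylation beta-values and M-values
#'
#' The M-value is the base-2 logit of the proportion methylated (beta-value):
#' M = log2(beta / (1 - beta)). Normalized array data can contain exact 0s
#' and 1s, so beta-values are clamped to \code{[clip, 1 - clip]} before the
#' logit; values outside \code{[0, 1]} are a domain error. The two functions
#' are mutual inverses on (0, 1) to better than 1e-12.
#'
#' @param beta proportion methylated in [0, 1] (vector or matrix).
#' @param m M-value (vector or matrix).
#' @param clip boundary clamp applied before the logit (default 1e-6).
#' @return numeric of the same shape on the other scale.
#' @examples
#' betaToMvalue(c(0.2, 0.5, 0.8)) # -2, 0, 2
#' mvalueToBeta(betaToMvalue(0.31415))
#' @export
betaToMvalue <- function(beta, clip = 1e-6) {
  ok <- is.na(beta) | (beta >= 0 & beta <= 1)
  if (!all(ok))
    stop("beta-values must lie in [0, 1]; offending value: ",
         format(beta[!ok][1L]), call. = FALSE)
  b <- pmin(pmax(beta, clip), 1 - clip)
  log2(b / (1 - b))
}

#' @rdname betaToMvalue
#' @export
mvalueToBeta <- function(m) {
  1 / (1 + 2^(-m))
}
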