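#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the Hardy-Weinberg expectation computed from the observed allele
#' frequency. Monomorphic input (allele frequency 0 or 1) is flagged and
#' returns a statistic of 0. The statistic is invariant to relabelling the
#' alleles (swapping the two homozygote counts).
#'
#' @param counts numeric length-3 vector \code{(n_AA, n_Aa, n_aa)} of
#'   genotype counts; total must be positive.
#' @return list with \code{statistic}, \code{p.value}, \code{monomorphic}
#'   flag, observed allele frequency \code{p} and \code{expected} counts.
#' @examples
#' hweChisq(c(25, 50, 25)) # exact HWE proportions: statistic 0, p 1
#' hweChisq(c(50, 0, 50))  # maximal departure at p = 0.5
#' @export
hweChisq <- function(counts) {
  if (length(counts) != 3L || any(counts < 0) || !all(is.finite(counts)))
    stop("counts must be three non-negative genotype counts (n_AA, n_Aa, n_aa)")
  n <- sum(counts)
  if (n <= 0) stop("total genotype count must be > 0")
  p <- (2 * counts[1L] + counts[2L]) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(statistic = 0, p.value = 1, monomorphic = TRUE,
                p = p, expected = counts))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       monomorphic = FALSE, p = unname(p), expected = unname(expected))
}

#' Genotype call rate
#'
#' Fraction of non-missing genotype calls. The QC gate used by [qcReport()]
#' passes iff the fraction strictly exceeds the threshold (default 0.99), so
#' 99 of 100 calls fails the strict gate.
#'
#' @param calls vector of genotype calls with NA as the missing marker.
#' @return fraction in [0, 1].
#' @export
genotypeCallRate <- function(calls) {
  if (length(calls) < 1L) stop("at least one call is required")
  mean(!is.na(calls))
}

#' Genotype QC report for a cohort
#'
#' Computes the call rate and the Hardy-Weinberg test for the cohort's SNP,
#' with pass flags for a strict call-rate gate (rate > \code{callRateMin})
#' and an HWE gate (p > \code{hwePMin}).
#'
#' @param cohort a [MethCohort-class].
#' @param callRateMin strict call-rate threshold (default 0.99).
#' @param hwePMin HWE p-value threshold (default 0.05).
#' @return list with the counts, call rate, HWE results and pass flags; has
#'   a \code{format} through [formatQcReport()].
#' @export
qcReport <- function(cohort, callRateMin = 0.99, hwePMin = 0.05) {
  g <- genotypes(cohort)
  rate <- genotypeCallRate(g)
  gc <- g[!is.na(g)]
  counts <- c(sum(gc == 2L), sum(gc == 1L), sum(gc == 0L))
  hwe <- hweChisq(counts)
  list(snp_id = snpId(cohort), n = length(g),
       genotype_counts = stats::setNames(counts, c("n_AA", "n_Aa", "n_aa")),
       call_rate = rate, call_rate_pass = rate > callRateMin,
       hwe = hwe, hwe_pass = hwe$monomorphic || hwe$p.value > hwePMin)
}

#' Render a QC report as plain text lines
#'
#' @param qc list returned by [qcReport()].
#' @return character vector of report lines.
#' @export
formatQcReport <- function(qc) {
  c(sprintf("SNP: %s", qc$snp_id),
    sprintf("subjects: %d", qc$n),
    sprintf("genotype counts (risk-allele hom / het / other hom): %d / %d / %d",
            qc$genotype_counts[1L], qc$genotype_counts[2L],
            qc$genotype_counts[3L]),
    sprintf("call rate: %.4f (%s)", qc$call_rate,
            if (qc$call_rate_pass) "PASS" else "FAIL"),
    sprintf("HWE chi-square: %.4f, p = %.4g%s (%s)", qc$hwe$statistic,
            qc$hwe$p.value,
            if (qc$hwe$monomorphic) " [monomorphic]" else "",
            if (qc$hwe_pass) "PASS" else "FAIL"))
}
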