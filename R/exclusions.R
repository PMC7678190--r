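#' The study's subject exclusion rules
#'
#' Complete-case exclusions used for the nested case-control analysis, in
#' declaration order: missing race/ethnicity, missing pack-years of
#' smoking, and DNA extracted with the salt or Bioserve method. Each rule
#' is a predicate taking the cohort and returning TRUE for subjects to
#' exclude.
#'
#' @return named list of predicate functions for [applyExclusions()].
#' @export
studyExclusionRules <- function() {
  list(
    missing_race = function(x) is.na(covariateTable(x)$race),
    missing_pack_years = function(x) is.na(covariateTable(x)$pack_years),
    salt_bioserve_extraction = function(x) {
      e <- covariateTable(x)$extraction
      !is.na(e) & e %in% c("Salt", "Bioserve")
    }
  )
}

#' Apply ordered exclusion rules to a cohort
#'
#' Rules are evaluated in declaration order and a subject hit by several
#' rules is attributed to the first one, so the per-rule counts always sum
#' to the number excluded. The retained cohort contains exactly the
#' subjects failing no rule.
#'
#' @param cohort a [MethCohort-class].
#' @param rules named list of predicate functions \code{function(cohort)}
#'   returning a logical exclusion mask; an empty list is the identity.
#' @return list with \code{cohort} (retained subjects) and \code{report}
#'   (an [ExclusionReport-class]).
#' @examples
#' sim <- simulateCaseControl(simTruth(nCases = 30L, nControls = 30L,
#'                                     seed = 7L))
#' applyExclusions(sim$cohort, list())$report
#' @export
applyExclusions <- function(cohort, rules = studyExclusionRules()) {
  n <- ncol(cohort)
  attributed <- rep(NA_character_, n)
  counts <- integer(length(rules))
  names(counts) <- names(rules)
  for (r in seq_along(rules)) {
    hit <- rules[[r]](cohort)
    if (!is.logical(hit) || length(hit) != n)
      stop("rule '", names(rules)[r],
           "' must return one logical per subject")
    hit[is.na(hit)] <- FALSE
    new_hit <- hit & is.na(attributed)
    attributed[new_hit] <- names(rules)[r]
    counts[r] <- sum(new_hit)
  }
  keep <- is.na(attributed)
  if (!any(keep))
    stop("all subjects excluded; nothing left to analyse")
  retained <- cohort[, keep]
  report <- new("ExclusionReport",
                nInput = as.integer(n), excluded = counts,
                nRetained = as.integer(sum(keep)),
                nCases = as.integer(nCases(retained)),
                nControls = as.integer(nControls(retained)))
  list(cohort = retained, report = report)
}

setMethod("show", "ExclusionReport", function(object) {
  cat("ExclusionReport:", object@nInput, "subjects in\n")
  for (nm in names(object@excluded))
    cat(sprintf("  excluded by %-28s %d\n", paste0(nm, ":"),
                object@excluded[[nm]]))
  cat(sprintf("  retained: %d (%d cases / %d controls)\n",
              object@nRetained, object@nCases, object@nControls))
  invisible(NULL)
})

#' Serialize an exclusion report to a data.frame
#'
#' @param report an [ExclusionReport-class].
#' @return data.frame with one row per rule plus input/retained rows,
#'   suitable for writing as TSV.
#' @export
exclusionReportTable <- function(report) {
  data.frame(
    step = c("input", names(report@excluded), "retained"),
    n = c(report@nInput, unname(report@excluded), report@nRetained),
    stringsAsFactors = FALSE)
}
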