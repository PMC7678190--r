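#' Build a MethCohort from per-subject vectors and matrices
#'
#' @param genotype integer vector of risk-allele counts (0, 1, 2; NA allowed
#'   before exclusions).
#' @param mvalues numeric matrix of methylation M-values, subjects in rows
#'   and CpG sites in columns (column names are the CpG ids). Stored
#'   internally in the assay orientation (CpGs x subjects).
#' @param covariates data.frame of raw (unencoded) covariates, one row per
#'   subject.
#' @param case integer 0/1 case indicator.
#' @param subjectIds character subject labels; defaults to rownames of
#'   \code{mvalues} or \code{S1, S2, ...}.
#' @param snpId,riskAllele optional SNP annotation stored in metadata.
#' @return a [MethCohort-class] object.
#' @examples
#' mc <- MethCohort(
#'   genotype = c(0L, 1L, 2L),
#'   mvalues = matrix(rnorm(6), 3, dimnames = list(NULL, c("cg1", "cg2"))),
#'   covariates = data.frame(age = c(55, 61, 70)),
#'   case = c(1L, 0L, 0L)
#' )
#' nCases(mc)
#' @export
MethCohort <- function(genotype, mvalues, covariates, case,
                       subjectIds = NULL, snpId = NA_character_,
                       riskAllele = NA_character_) {
  mvalues <- as.matrix(mvalues)
  n <- nrow(mvalues)
  stopifnot(length(genotype) == n, length(case) == n,
            nrow(covariates) == n)
  if (is.null(colnames(mvalues)))
    stop("mvalues must carry CpG ids as column names")
  if (is.null(subjectIds)) {
    subjectIds <- rownames(mvalues)
    if (is.null(subjectIds)) subjectIds <- paste0("S", seq_len(n))
  }
  if (anyDuplicated(subjectIds)) stop("duplicate subject id")
  rownames(mvalues) <- subjectIds
  cd <- S4Vectors::DataFrame(genotype = as.integer(genotype),
                             case = as.integer(case),
                             covariates, row.names = subjectIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(M = t(mvalues)),
    colData = cd,
    metadata = list(snp_id = snpId, risk_allele = riskAllele)
  )
  new("MethCohort", se)
}

#' @rdname cohort-accessors
#' @export
setMethod("genotypes", "MethCohort", function(x) {
  g <- colData(x)$genotype
  names(g) <- colnames(x)
  g
})

#' @rdname cohort-accessors
#' @export
setMethod("caseStatus", "MethCohort", function(x) {
  y <- colData(x)$case
  names(y) <- colnames(x)
  y
})

#' @rdname cohort-accessors
#' @export
setMethod("mvalues", "MethCohort", function(x) assay(x, "M"))

#' @rdname cohort-accessors
#' @export
setMethod("covariateTable", "MethCohort", function(x) {
  cd <- colData(x)
  keep <- setdiff(names(cd), c("genotype", "case"))
  as.data.frame(cd[, keep, drop = FALSE])
})

#' @rdname cohort-accessors
#' @export
setMethod("snpId", "MethCohort", function(x) metadata(x)$snp_id)

#' @rdname cohort-accessors
#' @export
setMethod("cpgIds", "MethCohort", function(x) rownames(x))

#' Case and control counts of a cohort
#'
#' @param x a [MethCohort-class].
#' @return integer count of cases (\code{nCases}) or controls
#'   (\code{nControls}); missing case status is not counted.
#' @export
nCases <- function(x) sum(caseStatus(x) == 1L, na.rm = TRUE)

#' @rdname nCases
#' @export
nControls <- function(x) sum(caseStatus(x) == 0L, na.rm = TRUE)

setMethod("show", "MethCohort", function(object) {
  cat("MethCohort:", ncol(object), "subjects,", nrow(object),
      "CpG mediator(s)\n")
  sid <- metadata(object)$snp_id
  if (!is.null(sid) && !is.na(sid)) cat("  SNP:", sid, "\n")
  cat("  cases:", nCases(object), " controls:", nControls(object), "\n")
  cat("  CpGs:", paste(rownames(object), collapse = " "), "\n")
  cov <- setdiff(names(colData(object)), c("genotype", "case"))
  cat("  covariates:", if (length(cov)) paste(cov, collapse = " ")
      else "(none)", "\n")
  invisible(NULL)
})
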