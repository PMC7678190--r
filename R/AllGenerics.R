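#' Accessors for MethCohort and MqtlSpec objects
#'
#' \code{genotypes} returns the per-subject risk-allele counts,
#' \code{caseStatus} the 0/1 case indicator, \code{mvalues} the M-value
#' matrix (CpG sites in rows, subjects in columns, following the assay
#' convention), \code{covariateTable} the raw covariate data.frame,
#' \code{snpId} the SNP label and \code{cpgIds} the mediator CpG labels in
#' their fixed analysis order.
#'
#' @param x a [MethCohort-class], [MqtlSpec-class] or [AnalysisSpec-class]
#'   object, as applicable.
#' @return see description.
#' @name cohort-accessors
#' @aliases genotypes caseStatus mvalues covariateTable snpId cpgIds
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname cohort-accessors
#' @export
setGeneric("caseStatus", function(x) standardGeneric("caseStatus"))

#' @rdname cohort-accessors
#' @export
setGeneric("mvalues", function(x) standardGeneric("mvalues"))

#' @rdname cohort-accessors
#' @export
setGeneric("covariateTable", function(x) standardGeneric("covariateTable"))

#' @rdname cohort-accessors
#' @export
setGeneric("snpId", function(x) standardGeneric("snpId"))

#' @rdname cohort-accessors
#' @export
setGeneric("cpgIds", function(x) standardGeneric("cpgIds"))
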