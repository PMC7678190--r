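# Reading and writing the four subject-level tables.
#
# Dialect: comma- or tab-delimited text with a header row and a character
# "subject_id" column; the delimiter is sniffed from the header line.

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), quote = "\"",
                           comment.char = "")
  if (!"subject_id" %in% names(tab))
    stop("table ", basename(path), " lacks a 'subject_id' column")
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject id in ", basename(path))
  tab
}

#' Read a cohort from the four subject-level tables
#'
#' Joins the genotype, methylation, covariate and outcome tables by
#' \code{subject_id}, keeping the deterministic subject order of the
#' genotype table. Every subject of the genotype table must appear in the
#' other three tables (disjoint ids are a validation error). Missing values
#' are preserved as NA and handled later by [applyExclusions()].
#'
#' @param genotypeFile table with \code{subject_id} and one column of
#'   risk-allele counts per SNP; the column named after
#'   \code{spec@snpId} is used. Values outside \{0, 1, 2, NA\} are a
#'   validation error.
#' @param methylationFile table with \code{subject_id} and one numeric
#'   column per CpG; must contain every CpG of \code{spec} (a missing CpG
#'   column is a format error).
#' @param covariateFile table with \code{subject_id} and raw covariate
#'   columns.
#' @param outcomeFile table with \code{subject_id} and a 0/1 \code{case}
#'   column.
#' @param spec an [MqtlSpec-class] naming the SNP and its CpG mediators.
#' @param methylationScale \code{"mvalue"} (default) or \code{"beta"}; beta
#'   values are converted through [betaToMvalue()].
#' @return a [MethCohort-class].
#' @seealso [writeCohort()] for the inverse; the pair round-trips a cohort
#'   within floating-point printing precision.
#' @export
readCohort <- function(genotypeFile, methylationFile, covariateFile,
                       outcomeFile, spec,
                       methylationScale = c("mvalue", "beta")) {
  methylationScale <- match.arg(methylationScale)
  stopifnot(is(spec, "MqtlSpec"))
  g <- .readTable(genotypeFile)
  m <- .readTable(methylationFile)
  cv <- .readTable(covariateFile)
  y <- .readTable(outcomeFile)

  if (!spec@snpId %in% names(g))
    stop("genotype table lacks a column for SNP '", spec@snpId, "'")
  cpg <- cpgIds(spec)
  miss <- setdiff(cpg, names(m))
  if (length(miss))
    stop("methylation table lacks CpG column(s): ",
         paste(miss, collapse = ", "))
  if (!"case" %in% names(y))
    stop("outcome table lacks a 'case' column")

  ids <- g$subject_id
  for (other in list(m = m, cv = cv, y = y)) {
    absent <- setdiff(ids, other$subject_id)
    if (length(absent) == length(ids))
      stop("tables share no subject ids")
    if (length(absent))
      stop("subject id(s) missing from a table: ",
           paste(utils::head(absent, 3L), collapse = ", "))
  }

  geno <- g[[spec@snpId]]
  ok <- is.na(geno) | geno %in% 0:2
  if (!all(ok))
    stop("genotype outside {0, 1, 2, NA}: ", geno[!ok][1L])

  mm <- as.matrix(m[match(ids, m$subject_id), cpg, drop = FALSE])
  storage.mode(mm) <- "double"
  if (methylationScale == "beta") mm[] <- betaToMvalue(mm)
  covs <- cv[match(ids, cv$subject_id),
             setdiff(names(cv), "subject_id"), drop = FALSE]
  rownames(covs) <- NULL
  MethCohort(genotype = geno, mvalues = mm, covariates = covs,
             case = y$case[match(ids, y$subject_id)],
             subjectIds = ids, snpId = spec@snpId,
             riskAllele = spec@riskAllele)
}

#' Write a cohort as the four subject-level tables
#'
#' Writes \code{genotype.tsv}, \code{methylation.tsv} (M-values),
#' \code{covariates.tsv} and \code{outcome.tsv} into \code{dir}, in the
#' dialect [readCohort()] reads.
#'
#' @param cohort a [MethCohort-class].
#' @param dir output directory (created if absent).
#' @return named character vector of the four paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- colnames(cohort)
  snp <- snpId(cohort)
  if (is.null(snp) || is.na(snp)) snp <- "snp"
  wt <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  gt <- data.frame(subject_id = ids, g = unname(genotypes(cohort)))
  names(gt)[2L] <- snp
  mt <- data.frame(subject_id = ids, t(mvalues(cohort)),
                   check.names = FALSE)
  ct <- data.frame(subject_id = ids, covariateTable(cohort),
                   check.names = FALSE, row.names = NULL)
  yt <- data.frame(subject_id = ids, case = unname(caseStatus(cohort)))
  invisible(c(genotype = wt(gt, "genotype.tsv"),
              methylation = wt(mt, "methylation.tsv"),
              covariates = wt(ct, "covariates.tsv"),
              outcome = wt(yt, "outcome.tsv")))
}
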