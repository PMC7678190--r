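# Config-driven orchestration: QC -> exclusions -> per-SNP mediation with
# bootstrap -> publication-style report.

#' Read and validate a pipeline run configuration
#'
#' YAML configuration with keys: \code{seed} (integer), \code{snps}
#' ("all" or a vector), \code{mqtl} (path to an alternative mQTL table,
#' null = packaged fixture), exactly one of \code{synthetic} (keys
#' \code{n_cases}, \code{n_controls}, \code{prevalence}, ...) or
#' \code{input} (paths \code{genotype}, \code{methylation},
#' \code{covariates}, \code{outcome}, optional \code{methylation_scale}),
#' \code{covariates} (raw covariate names; null = all declared covariates
#' present), \code{exclusions} ("default" or "none"), \code{filter}
#' (optional row-filter expression on the covariate columns, e.g.
#' \code{race == "White"}), \code{bootstrap} (\code{B},
#' \code{stratified}, \code{level}) and \code{out} (output directory).
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validateRunConfig(yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @param config a config list (as from YAML) to validate and fill with
#'   defaults.
#' @export
validateRunConfig <- function(config) {
  stopifnot(is.list(config))
  hasSyn <- !is.null(config$synthetic)
  hasInp <- !is.null(config$input)
  if (hasSyn == hasInp)
    stop("config must contain exactly one of 'synthetic' or 'input'")
  if (hasInp) {
    need <- c("genotype", "methylation", "covariates", "outcome")
    miss <- setdiff(need, names(config$input))
    if (length(miss))
      stop("input block lacks path(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$snps)) config$snps <- "all"
  if (is.null(config$exclusions)) config$exclusions <- "default"
  if (!config$exclusions %in% c("default", "none"))
    stop("exclusions must be 'default' or 'none'")
  bs <- config$bootstrap
  if (is.null(bs)) bs <- list()
  if (is.null(bs$B)) bs$B <- 1000L
  if (is.null(bs$stratified)) bs$stratified <- TRUE
  if (is.null(bs$level)) bs$level <- 0.95
  config$bootstrap <- bs
  config
}

#' Run the full mediation pipeline
#'
#' For each analysed SNP: read (or synthesize) the cohort, run genotype QC,
#' apply exclusions, optionally filter rows, and estimate the NDE/NIE/TE
#' decomposition with percentile-bootstrap intervals. Writes a
#' publication-style results TSV, a machine-readable \code{results.json},
#' per-SNP QC and exclusion reports, and a run log recording the seed,
#' bootstrap settings, package version and dropped resamples. A failure in
#' one SNP is recorded (with the stage that failed) without aborting the
#' others; partial results are still written. The output is a pure
#' function of (config, seed): reruns reproduce the result files
#' byte-for-byte apart from the log timestamp.
#'
#' @param config path to a YAML config or a config list
#'   (see [readRunConfig()]).
#' @param outDir output directory override.
#' @param seed seed override; per-SNP bootstrap seeds are derived as
#'   seed, seed + 1, ... in table order.
#' @param B bootstrap resample override.
#' @return invisible list with \code{results} (per-SNP
#'   [MediationResult-class]), \code{table} (the formatted data.frame),
#'   \code{errors} (per-SNP failure messages), \code{qc}, \code{paths} and
#'   \code{outDir}.
#' @examples
#' cfg <- system.file("extdata", "demo_config.yaml", package = "mqtlmed")
#' \donttest{
#' run <- runPipeline(cfg, outDir = tempfile("demo"), B = 50)
#' run$table
#' }
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL, B = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- validateRunConfig(config)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(B)) config$bootstrap$B <- B
  if (is.null(outDir)) outDir <- config$out
  if (is.null(outDir)) outDir <- tempfile("mqtlmed_run_")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  table <- mqtlTable(config$mqtl)
  allSnps <- unique(table$snp_id)
  snps <- config$snps
  if (length(snps) == 1L && identical(snps, "all")) snps <- allSnps
  unknown <- setdiff(snps, allSnps)
  if (length(unknown))
    stop("SNP(s) absent from the mQTL table: ",
         paste(unknown, collapse = ", "))

  logLines <- c(
    sprintf("mqtlmed %s", as.character(utils::packageVersion("mqtlmed"))),
    sprintf("seed: %d", as.integer(config$seed)),
    sprintf("bootstrap: B = %d, stratified = %s, level = %g",
            as.integer(config$bootstrap$B),
            config$bootstrap$stratified, config$bootstrap$level),
    sprintf("snps: %s", paste(snps, collapse = ", ")))

  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    sim <- simulateStudy(
      table = table[table$snp_id %in% snps, , drop = FALSE],
      nCases = if (is.null(syn$n_cases)) 412L else syn$n_cases,
      nControls = if (is.null(syn$n_controls)) 424L else syn$n_controls,
      prevalence = if (is.null(syn$prevalence)) 0.01 else syn$prevalence,
      seed = as.integer(config$seed),
      dir = file.path(outDir, "tables"))
    files <- as.list(sim$paths)
    names(files) <- c("genotype", "methylation", "covariates", "outcome")
    scale <- "mvalue"
    logLines <- c(logLines, "input: synthetic tables (written to tables/)")
  } else {
    files <- config$input
    scale <- if (is.null(files$methylation_scale)) "mvalue" else
      files$methylation_scale
    logLines <- c(logLines,
                  sprintf("input: %s", paste(unlist(
                    files[c("genotype", "methylation", "covariates",
                            "outcome")]), collapse = ", ")))
  }

  rules <- if (identical(config$exclusions, "default"))
    studyExclusionRules() else list()
  results <- list(); errors <- list(); qcs <- list()

  for (i in seq_along(snps)) {
    snp <- snps[i]
    stage <- "setup"
    res <- tryCatch({
      stage <- "read"
      spec <- mqtlSpec(snp, table)
      cohort <- readCohort(files$genotype, files$methylation,
                           files$covariates, files$outcome, spec,
                           methylationScale = scale)
      stage <- "qc"
      qc <- qcReport(cohort)
      qcs[[snp]] <- qc
      writeLines(formatQcReport(qc),
                 file.path(outDir, paste0(snp, "_qc.txt")))
      stage <- "exclusions"
      excl <- applyExclusions(cohort, rules)
      utils::write.table(exclusionReportTable(excl$report),
                         file.path(outDir,
                                   paste0(snp, "_exclusions.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cohort <- excl$cohort
      if (!is.null(config$filter)) {
        stage <- "filter"
        env <- cbind(covariateTable(cohort),
                     case = caseStatus(cohort))
        keep <- eval(parse(text = config$filter), envir = env)
        if (!is.logical(keep) || length(keep) != ncol(cohort))
          stop("filter must evaluate to one logical per subject")
        cohort <- cohort[, keep & !is.na(keep)]
      }
      stage <- "mediation"
      declared <- c(covariateSchema()$continuous,
                    names(covariateSchema()$factors))
      covs <- if (is.null(config$covariates))
        intersect(declared, names(covariateTable(cohort))) else
          config$covariates
      aspec <- analysisSpec(snp, cpgIds(spec), covariates = covs)
      cfg <- bootstrapConfig(B = config$bootstrap$B,
                             seed = as.integer(config$seed) + i - 1L,
                             stratified = config$bootstrap$stratified,
                             level = config$bootstrap$level)
      r <- bootstrapMediation(cohort, aspec, cfg)
      r@info <- list(region = spec@region, gene = spec@gene,
                     risk_allele = spec@riskAllele,
                     mediators = cpgIds(spec))
      logLines <- c(logLines,
                    sprintf("%s: n = %d, dropped resamples = %d", snp,
                            ncol(cohort), r@boot$nDropped))
      r
    }, error = function(e)
      simpleError(sprintf("SNP %s failed at stage '%s': %s", snp, stage,
                          conditionMessage(e))))
    if (inherits(res, "error")) {
      errors[[snp]] <- conditionMessage(res)
      logLines <- c(logLines, paste0("ERROR ", conditionMessage(res)))
    } else {
      results[[snp]] <- res
    }
  }

  fmt <- if (length(results)) formatResultsTable(results) else NULL
  paths <- c(results_tsv = file.path(outDir, "results.tsv"),
             results_json = file.path(outDir, "results.json"),
             log = file.path(outDir, "log.txt"))
  if (!is.null(fmt))
    utils::write.table(fmt, paths[["results_tsv"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(results, function(r) list(
      snp_id = r@snpId,
      estimates = as.list(r@estimates),
      ci = list(nde = unname(r@ci["nde", ]), nie = unname(r@ci["nie", ]),
                te = unname(r@ci["te", ])),
      nie_percent = as.list(r@niePercent),
      contributions = as.list(r@contributions),
      bootstrap = r@boot[c("B", "seed", "stratified", "level",
                           "nDropped")],
      info = r@info)),
    paths[["results_json"]], auto_unbox = TRUE, digits = NA)
  writeLines(c(logLines, sprintf("finished: %s",
                                 format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             paths[["log"]])
  invisible(list(results = results, table = fmt, errors = errors,
                 qc = qcs, paths = paths, outDir = outDir))
}

#' Format an odds ratio (with optional interval) for the results table
#'
#' Two-decimal formatting, \code{"x.xx (l.ll, u.uu)"}. Decimal rounding is
#' done by \code{sprintf}, i.e. the closest-representable binary value is
#' rounded, so a printed "1.005" (stored slightly below 1.005) formats as
#' "1.00".
#'
#' @param or odds ratio.
#' @param lower,upper optional interval endpoints.
#' @return character scalar.
#' @examples
#' formatOr(1.1023, 0.846, 1.379) # "1.10 (0.85, 1.38)"
#' @export
formatOr <- function(or, lower = NULL, upper = NULL) {
  if (is.null(lower)) sprintf("%.2f", or) else
    sprintf("%.2f (%.2f, %.2f)", or, lower, upper)
}

#' Assemble the publication-style results table
#'
#' One row per SNP with the annotation columns, the mediator list, and the
#' NDE/NIE/TE odds ratios with confidence intervals at two decimals, plus
#' both NIE-percent conventions at one decimal.
#'
#' @param results list of [MediationResult-class] objects (with bootstrap
#'   intervals).
#' @return data.frame.
#' @export
formatResultsTable <- function(results) {
  stopifnot(length(results) >= 1L)
  rows <- lapply(results, function(r) {
    info <- r@info
    gv <- function(k) if (is.null(info[[k]])) NA_character_ else
      as.character(info[[k]])
    med <- if (is.null(info$mediators)) paste(r@spec@cpgIds,
                                              collapse = " ") else
      paste(info$mediators, collapse = " ")
    ci <- function(k) if (nrow(r@ci) == 3L)
      formatOr(r@estimates[[paste0("or_", k)]], r@ci[k, "lower"],
               r@ci[k, "upper"]) else
      formatOr(r@estimates[[paste0("or_", k)]])
    data.frame(
      SNP = r@snpId, Region = gv("region"), Gene = gv("gene"),
      RA = gv("risk_allele"), Mediators = med,
      NDE = ci("nde"), NIE = ci("nie"), TE = ci("te"),
      NIE_pct_or_ratio = sprintf("%.1f", r@niePercent[["or_ratio"]]),
      NIE_pct_proportion_mediated =
        sprintf("%.1f", r@niePercent[["proportion_mediated"]]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
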