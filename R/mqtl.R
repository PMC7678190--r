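#' The packaged mQTL-CpG table
#'
#' Reads the table of bladder-cancer mQTL SNPs and their associated CpG
#' sites that ships with the package: four SNPs (rs798766, rs401681,
#' rs2294008, rs8102137) and ten CpG rows, each with the risk allele,
#' risk-allele frequency, the direction of the SNP-methylation association
#' and the unsigned effect size (difference in median proportion methylated
#' between homozygote groups, beta scale).
#'
#' @param file path to an alternative table with the same columns; default
#'   the packaged fixture.
#' @return data.frame with columns \code{snp_id}, \code{snp_location},
#'   \code{region}, \code{gene}, \code{risk_allele}, \code{raf},
#'   \code{cpg_id}, \code{cpg_location}, \code{cpg_gene}, \code{direction}
#'   ("+"/"-") and \code{effect_size}.
#' @examples
#' tab <- mqtlTable()
#' table(tab$snp_id)
#' @export
mqtlTable <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "mqtl_sites.tsv", package = "mqtlmed",
                        mustWork = TRUE)
  tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("snp_id", "risk_allele", "raf", "cpg_id", "direction",
            "effect_size")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("mQTL table lacks column(s): ", paste(miss, collapse = ", "))
  tab$raf <- as.numeric(tab$raf)
  tab$effect_size <- as.numeric(tab$effect_size)
  if (!all(tab$direction %in% c("+", "-")))
    stop("direction must be '+' or '-'")
  tab
}

#' Build an MqtlSpec for one SNP
#'
#' @param snp SNP identifier present in \code{table}.
#' @param table mQTL-CpG table as returned by [mqtlTable()].
#' @return an [MqtlSpec-class] with the SNP's CpG rows in table order and
#'   directions coded +1/-1.
#' @examples
#' sp <- mqtlSpec("rs401681")
#' sp
#' @export
mqtlSpec <- function(snp, table = mqtlTable()) {
  rows <- table[table$snp_id == snp, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("SNP '", snp, "' is not present in the mQTL table")
  pick <- function(col) if (col %in% names(rows)) rows[[col]][1L] else
    NA_character_
  new("MqtlSpec",
      snpId = snp,
      snpLocation = pick("snp_location"),
      region = pick("region"),
      gene = pick("gene"),
      riskAllele = rows$risk_allele[1L],
      raf = rows$raf[1L],
      cpgs = data.frame(
        cpg_id = rows$cpg_id,
        cpg_location = if ("cpg_location" %in% names(rows))
          rows$cpg_location else NA_character_,
        cpg_gene = if ("cpg_gene" %in% names(rows)) rows$cpg_gene else
          NA_character_,
        direction = ifelse(rows$direction == "+", 1, -1),
        effect_size = rows$effect_size,
        stringsAsFactors = FALSE))
}

#' @rdname cohort-accessors
#' @export
setMethod("snpId", "MqtlSpec", function(x) x@snpId)

#' @rdname cohort-accessors
#' @export
setMethod("cpgIds", "MqtlSpec", function(x) x@cpgs$cpg_id)

setMethod("show", "MqtlSpec", function(object) {
  cat("MqtlSpec:", object@snpId,
      sprintf("[%s, RAF %.2f]", object@riskAllele, object@raf), "\n")
  cat("  region:", object@region, " gene:", object@gene, "\n")
  for (i in seq_len(nrow(object@cpgs))) {
    r <- object@cpgs[i, ]
    cat(sprintf("  %s  %s%.3f\n", r$cpg_id,
                if (r$direction > 0) "+" else "-", r$effect_size))
  }
  invisible(NULL)
})
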