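#' The study covariate schema
#'
#' Declares the covariates used for adjustment and how each is encoded:
#' categorical covariates with their full level sets (reference = first
#' declared level, dummy coded), continuous covariates passed through, and
#' the enrollment-year coding (calendar years 1994-1995 map to 1, 1996 to 2,
#' 1997 to 3, 1998 to 4, entering the models as a single continuous column).
#'
#' Declared categoricals: trial arm (OS, HT_DM, HT, DM), race/ethnicity
#' (White, Asian_PI, Black, Hispanic, Other; White is the reference as the
#' largest group), smoking status (Never, Former, Current) and DNA
#' extraction method (5-prime, Phenol). Continuous: age, enrollment_year
#' (after coding), followup_years, pack_years.
#'
#' @return list with elements \code{factors} (named list of level vectors),
#'   \code{continuous} (character) and \code{yearMap} (named numeric).
#' @export
covariateSchema <- function() {
  list(
    factors = list(
      arm = c("OS", "HT_DM", "HT", "DM"),
      race = c("White", "Asian_PI", "Black", "Hispanic", "Other"),
      smoking = c("Never", "Former", "Current"),
      extraction = c("5-prime", "Phenol")
    ),
    continuous = c("age", "enrollment_year", "followup_years", "pack_years"),
    yearMap = c("1994" = 1, "1995" = 1, "1996" = 2, "1997" = 3, "1998" = 4)
  )
}

#' Encode raw covariates into numeric design columns
#'
#' Applies the schema's encoding: continuous covariates pass through (with
#' calendar enrollment years mapped to the 1-4 coding), categoricals become
#' reference-level dummy columns named \code{<covariate><level>}. Column
#' order is fixed by the schema (continuous first, then dummies), so the
#' encoding -- and everything estimated from it -- is invariant to the
#' column order of the raw input. Unseen categorical levels are a
#' validation error; missing values propagate as NA (complete-case policy
#' is enforced downstream).
#'
#' @param covariates data.frame of raw covariates; only columns declared in
#'   the schema are encoded, others are ignored with a warning.
#' @param schema covariate schema, see [covariateSchema()].
#' @param which optional character vector restricting which declared
#'   covariates to encode (default: all present in the input).
#' @return numeric matrix, one row per subject.
#' @examples
#' encodeCovariates(data.frame(smoking = c("Never", "Current"),
#'                             age = c(55, 63)))
#' @export
encodeCovariates <- function(covariates, schema = covariateSchema(),
                             which = NULL) {
  declared <- c(schema$continuous, names(schema$factors))
  present <- intersect(declared, names(covariates))
  if (!is.null(which)) {
    bad <- setdiff(which, declared)
    if (length(bad))
      stop("undeclared covariate(s): ", paste(bad, collapse = ", "))
    miss <- setdiff(which, names(covariates))
    if (length(miss))
      stop("requested covariate(s) absent from input: ",
           paste(miss, collapse = ", "))
    present <- intersect(declared, which)
  }
  extra <- setdiff(names(covariates), declared)
  if (is.null(which) && length(extra))
    warning("ignoring undeclared covariate column(s): ",
            paste(extra, collapse = ", "))
  n <- nrow(covariates)
  cols <- list()
  for (v in intersect(schema$continuous, present)) {
    x <- covariates[[v]]
    if (v == "enrollment_year") {
      x <- as.character(x)
      known <- is.na(x) | x %in% names(schema$yearMap)
      if (!all(known))
        stop("enrollment_year outside the coded range 1994-1998: ",
             x[!known][1L])
      x <- unname(schema$yearMap[x])
    } else {
      x <- as.numeric(x)
    }
    cols[[v]] <- x
  }
  for (v in intersect(names(schema$factors), present)) {
    levs <- schema$factors[[v]]
    x <- as.character(covariates[[v]])
    bad <- !is.na(x) & !(x %in% levs)
    if (any(bad))
      stop("unseen level '", x[bad][1L], "' for covariate '", v, "'")
    for (lev in levs[-1L]) {
      cols[[paste0(v, lev)]] <- as.numeric(x == lev)
    }
  }
  if (!length(cols))
    return(matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(rownames(covariates), NULL)))
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(covariates)
  out
}
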