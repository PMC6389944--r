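## CNV penetrance: the built-in lookup of penetrance scores for schizophrenia
## (P_Sz) and intellectual disability / developmental delay / autism (P_DD),
## the Bayes-rate penetrance computation, and score assignment to a cohort.
##
## Penetrance is the probability (in percent) that a carrier of a given CNV
## manifests the phenotype. The shipped table covers the 12 study CNVs plus
## controls; the two entries whose source transcription is typographically
## ambiguous are flagged in the `transcription_uncertain` column.

the_penetrance_env <- new.env(parent = emptyenv())

#' The built-in CNV penetrance table
#'
#' Per CNV: hg19 locus, study carrier count and demographics, and penetrance
#' scores for schizophrenia (`p_sz`) and developmental delay (`p_dd`), both
#' in percent.
#'
#' @return Data frame with one row per CNV label plus a control row.
#' @export
penetrance_table <- function() {
  if (is.null(the_penetrance_env$table)) {
    path <- system.file("extdata", "cnv_penetrance.csv", package = "penetract",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(tab$p_sz >= 0), all(tab$p_sz <= 100),
              all(tab$p_dd >= 0), all(tab$p_dd <= 100))
    the_penetrance_env$table <- tab
  }
  the_penetrance_env$table
}

#' Penetrance of a CNV from carrier rates and disease prevalence
#'
#' Bayes-rate estimate: the probability of manifesting the phenotype given
#' the CNV is the rate of the CNV among cases, multiplied by the disease
#' prevalence, divided by the rate of the CNV in the general population,
#' clamped at 100% (a probability cannot exceed 1). With `prevalence = 1`
#' this reduces to the plain frequency ratio.
#'
#' @param freq_in_cases CNV carrier rate among cases, in `[0, 1]`.
#' @param freq_in_population CNV carrier rate in the general population,
#'   in `(0, 1]`.
#' @param prevalence Disease prevalence, in `(0, 1]` (default 1).
#' @return Penetrance in percent (vectorised).
#' @export
compute_penetrance <- function(freq_in_cases, freq_in_population, prevalence = 1) {
  if (any(freq_in_population <= 0)) {
    stop("freq_in_population must be strictly positive")
  }
  if (any(freq_in_cases < 0) || any(freq_in_cases > 1)) {
    stop("freq_in_cases must be a rate in [0, 1]")
  }
  if (any(freq_in_population > 1)) {
    stop("freq_in_population must be a rate in (0, 1]")
  }
  if (any(prevalence <= 0) || any(prevalence > 1)) {
    stop("prevalence must be in (0, 1]")
  }
  100 * pmin(1, freq_in_cases * prevalence / freq_in_population)
}

#' Look up the penetrance scores of a CNV label
#'
#' @param label A CNV label present in [penetrance_table()] (e.g.
#'   `"22q11.2 deletion"`, `"control"`).
#' @param table Penetrance table (default the built-in one).
#' @return Named numeric vector `c(p_sz = ..., p_dd = ...)` in percent.
#' @export
lookup_penetrance <- function(label, table = penetrance_table()) {
  i <- match(label, table$cnv_label)
  if (anyNA(i)) {
    stop("unknown CNV label(s): ",
         paste(label[is.na(i)], collapse = ", "),
         "; valid labels: ", paste(table$cnv_label, collapse = ", "))
  }
  if (length(label) == 1L) {
    c(p_sz = table$p_sz[i], p_dd = table$p_dd[i])
  } else {
    data.frame(cnv_label = label, p_sz = table$p_sz[i], p_dd = table$p_dd[i])
  }
}

#' Assign penetrance scores and carrier flags to a cohort table
#'
#' @param cohort Data frame with at least a `cnv_label` column.
#' @param table Penetrance table (default the built-in one).
#' @return The cohort with `p_sz`, `p_dd` (percent) and logical `carrier`
#'   columns populated; controls get zero scores.
#' @export
assign_scores <- function(cohort, table = penetrance_table()) {
  i <- match(cohort$cnv_label, table$cnv_label)
  if (anyNA(i)) {
    stop("unresolvable CNV label(s): ",
         paste(unique(cohort$cnv_label[is.na(i)]), collapse = ", "),
         "; valid labels: ", paste(table$cnv_label, collapse = ", "))
  }
  cohort$p_sz <- table$p_sz[i]
  cohort$p_dd <- table$p_dd[i]
  cohort$carrier <- cohort$cnv_label != "control"
  stopifnot(all(cohort$p_sz[!cohort$carrier] == 0),
            all(cohort$p_dd[!cohort$carrier] == 0))
  cohort
}
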