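#' Standardized mean differences between arms
#'
#' Pooled-SD standardized difference `(mean_A - mean_B) / sqrt((var_A +
#' var_B)/2)`; binary covariates are treated as 0/1 numerics. Degenerate
#' covariates (zero variance in both arms) report 0 with a warning.
#'
#' @param records Data frame with an `arm` column.
#' @param covariates Character vector of covariate column names.
#' @return Named numeric vector of SMDs.
#' @export
standardized_mean_difference <- function(records, covariates) {
  vapply(covariates, function(v) {
    x <- as.numeric(records[[v]])
    a <- x[records$arm == "A"]; b <- x[records$arm == "B"]
    s2 <- (stats::var(a) + stats::var(b)) / 2
    if (!is.finite(s2) || s2 <= 0) {
      warning(sprintf("covariate '%s' has zero variance; SMD set to 0", v),
              call. = FALSE)
      return(0)
    }
    (mean(a) - mean(b)) / sqrt(s2)
  }, numeric(1))
}

#' Greedy 1:1 propensity-score matching
#'
#' Estimates a propensity score by logistic regression of arm membership
#' on the covariates, then pairs each arm-A patient (processed in
#' descending propensity order) with the nearest unmatched arm-B patient
#' on the logit scale, without replacement. An optional caliper, in units
#' of the pooled SD of the logit score, rejects pairs that are too far
#' apart.
#'
#' @param records Data frame with `id`, `arm` and the covariates.
#' @param covariates Covariates for the propensity model (default age and
#'   sex, the two baseline characteristics used here).
#' @param caliper Caliper width as a multiple of SD(logit score), or
#'   `NULL` (default) for no caliper.
#' @return A `match_result` list: `pairs` (data frame `id_a`, `id_b`),
#'   `smd_before`, `smd_after`, `caliper`, `logit` scores.
#' @export
propensity_match <- function(records, covariates = c("age", "female"),
                             caliper = NULL) {
  stopifnot(all(covariates %in% names(records)),
            all(c("A", "B") %in% records$arm))
  fml <- stats::as.formula(paste("I(arm == \"A\") ~",
                                 paste(covariates, collapse = " + ")))
  fit <- stats::glm(fml, data = records, family = stats::binomial())
  logit <- as.numeric(stats::predict(fit, type = "link"))
  ia <- which(records$arm == "A"); ib <- which(records$arm == "B")
  if (!length(ia) || !length(ib)) stop("both arms must be non-empty", call. = FALSE)
  max_dist <- if (is.null(caliper)) Inf else caliper * stats::sd(logit)
  ord <- ia[order(logit[ia], decreasing = TRUE)]
  avail <- rep(TRUE, length(ib))
  pa <- pb <- integer(0)
  for (i in ord) {
    cand <- which(avail)
    if (!length(cand)) break
    dist <- abs(logit[ib[cand]] - logit[i])
    j <- cand[which.min(dist)]
    if (min(dist) <= max_dist) {
      avail[j] <- FALSE
      pa <- c(pa, i); pb <- c(pb, ib[j])
    }
  }
  if (!length(pa)) stop("no matches possible", call. = FALSE)
  matched <- records[c(pa, pb), , drop = FALSE]
  structure(list(
    pairs = data.frame(id_a = records$id[pa], id_b = records$id[pb]),
    smd_before = standardized_mean_difference(records, covariates),
    smd_after = standardized_mean_difference(matched, covariates),
    caliper = caliper,
    logit = stats::setNames(logit, records$id)
  ), class = "match_result")
}

#' Subset a cohort to its matched patients
#' @param records A `patient_cohort`.
#' @param match A `match_result` from [propensity_match()].
#' @return The matched rows, config attribute preserved.
#' @export
matched_records <- function(records, match) {
  keep <- records$id %in% c(match$pairs$id_a, match$pairs$id_b)
  out <- records[keep, , drop = FALSE]
  attr(out, "config") <- attr(records, "config")
  class(out) <- class(records)
  out
}
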