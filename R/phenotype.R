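#' Phenotype and covariate table
#'
#' Assembles the outcome/covariate table used by all tests: a binary
#' outcome (observed hypertension status or a dichotomized quantitative
#' trait), AGE and SEX covariates, and optionally the raw blood-pressure
#' and medication columns the outcome can be derived from.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param outcome binary (0/1) vector, `NA` allowed. If `NULL` and `sbp`,
#'   `dbp`, `meds` are supplied, the outcome is derived via
#'   [derive_hypertension()].
#' @param age,sex covariates (years; 0/1 code). `NA` allowed.
#' @param sbp,dbp,meds,q1 optional systolic/diastolic blood pressure
#'   (mm Hg), antihypertensive-medication flag, and quantitative trait.
#' @return A data frame of class `phenotype_table`.
#' @export
phenotype_table <- function(sample_ids, outcome = NULL, age = NULL,
                            sex = NULL, sbp = NULL, dbp = NULL,
                            meds = NULL, q1 = NULL) {
  n <- length(sample_ids)
  if (is.null(outcome)) {
    if (is.null(sbp) && is.null(dbp) && is.null(meds))
      stop("supply either `outcome` or the sbp/dbp/meds columns")
    outcome <- derive_hypertension(sbp %||% rep(NA_real_, n),
                                   dbp %||% rep(NA_real_, n),
                                   meds %||% rep(NA, n))
  }
  if (!all(outcome %in% c(0, 1, NA)))
    stop("outcome must be binary 0/1 (NA allowed)")
  pt <- data.frame(sample_id = as.character(sample_ids),
                   outcome = as.integer(outcome),
                   stringsAsFactors = FALSE)
  pt$age <- if (is.null(age)) NA_real_ else as.numeric(age)
  pt$sex <- if (is.null(sex)) NA_real_ else as.numeric(sex)
  if (!is.null(sbp)) pt$sbp <- as.numeric(sbp)
  if (!is.null(dbp)) pt$dbp <- as.numeric(dbp)
  if (!is.null(meds)) pt$meds <- as.logical(meds)
  if (!is.null(q1)) pt$q1 <- as.numeric(q1)
  class(pt) <- c("phenotype_table", class(pt))
  pt
}

#' Hypertension status from blood pressure and medication
#'
#' Conventional diagnostic rule: hypertensive if systolic blood pressure
#' exceeds 140 mm Hg, or diastolic exceeds 90 mm Hg, or the individual is
#' on antihypertensive medication (regardless of measured pressure).  The
#' inequalities are strict, so SBP exactly 140 / DBP exactly 90 without
#' medication is non-hypertensive.
#'
#' @param sbp,dbp numeric, mm Hg (`NA` allowed).
#' @param meds logical medication flag (`NA` allowed).
#' @return Integer 0/1 vector; `NA` where all three inputs are missing or
#'   the observed inputs cannot decide the status.
#' @export
derive_hypertension <- function(sbp, dbp, meds) {
  n <- max(length(sbp), length(dbp), length(meds))
  sbp <- rep_len(as.numeric(sbp), n)
  dbp <- rep_len(as.numeric(dbp), n)
  meds <- rep_len(as.logical(meds), n)
  pos <- (!is.na(sbp) & sbp > 140) | (!is.na(dbp) & dbp > 90) |
    (!is.na(meds) & meds)
  # negative only when every observed criterion is negative and none missing
  all_known <- !is.na(sbp) & !is.na(dbp) & !is.na(meds)
  out <- ifelse(pos, 1L, ifelse(all_known, 0L, NA_integer_))
  as.integer(out)
}

#' Complete-case mask for association analysis
#'
#' Samples with non-missing outcome, AGE and SEX.
#'
#' @param pt a [phenotype_table].
#' @return logical vector, `TRUE` for analyzable samples.
#' @export
complete_case_mask <- function(pt) {
  !is.na(pt$outcome) & !is.na(pt$age) & !is.na(pt$sex)
}

#' Covariate design matrix (intercept + AGE + SEX)
#'
#' @param pt a [phenotype_table] (already subset to complete cases).
#' @return numeric matrix with columns `(Intercept)`, `age`, `sex`.
#' @keywords internal
covariate_design <- function(pt) {
  cbind(`(Intercept)` = 1, age = pt$age, sex = pt$sex)
}
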