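# Canonical variable order of the change table, clinical endpoints first.
CHANGE_VARS <- c(TampaChg = "tampa_chg", VASChg = "vas_chg",
                 EQ5DChg = "eq5d_chg", HeadChg = "head_chg",
                 LeftChg = "left_chg", RightChg = "right_chg")

#' Clinical endpoint changes from baseline
#'
#' Computes per-participant endpoint changes as end-of-treatment minus
#' baseline for the Tampa Scale of Kinesiophobia, the overall-health VAS
#' and the EQ-5D-5L summed index. A score missing at either timepoint
#' yields a missing change (with a warning), which downstream correlation
#' handles by listwise deletion.
#'
#' @param baseline,end_of_treatment tibbles with columns `subject`,
#'   `tampa`, `vas`, `eq5d` (scores at the respective timepoint).
#' @return A tibble with columns `subject`, `tampa_chg`, `vas_chg`,
#'   `eq5d_chg`.
#' @export
clinical_changes <- function(baseline, end_of_treatment) {
  merged <- dplyr::full_join(baseline, end_of_treatment, by = "subject",
                             suffix = c("_bl", "_eot"))
  out <- tibble(
    subject = merged$subject,
    tampa_chg = merged$tampa_eot - merged$tampa_bl,
    vas_chg = merged$vas_eot - merged$vas_bl,
    eq5d_chg = merged$eq5d_eot - merged$eq5d_bl
  )
  n_missing <- sum(!stats::complete.cases(out))
  if (n_missing > 0L) {
    warning(n_missing, " participant(s) have a missing change ",
            "(score absent at baseline or end of treatment)",
            call. = FALSE)
  }
  out
}

#' Correlation matrix of movement and clinical changes
#'
#' Computes the square correlation matrix over the six change variables
#' (Tampa, VAS, EQ-5D clinical changes; head, left, right movement
#' changes) with listwise deletion: any participant missing any of the
#' six values is dropped before either method is applied. Pearson is the
#' product-moment correlation on raw values; Spearman is the same
#' computation on midranks (ties averaged). A zero-variance column makes
#' its correlations undefined; those entries are `NA` and the column is
#' named in the `undefined_variables` field rather than failing silently.
#'
#' @param table change table in [load_table1_fixture()] layout (columns
#'   `subject`, `tampa_chg`, `vas_chg`, `eq5d_chg`, `head_chg`,
#'   `left_chg`, `right_chg`).
#' @param method `"pearson"` or `"spearman"`.
#' @param exclude participant ids (values of `subject`) to drop before
#'   anything else, e.g. a short-participation participant.
#' @return An object of class `correlation_report`: a list with `method`,
#'   `variables`, `matrix` (full precision, symmetric, unit diagonal),
#'   `n_used`, `excluded_participants`, `deleted_listwise` (subjects
#'   dropped for missingness) and `undefined_variables`.
#' @export
correlation_matrix <- function(table, method = c("pearson", "spearman"),
                               exclude = NULL) {
  method <- match.arg(method)
  missing_cols <- setdiff(unname(CHANGE_VARS), names(table))
  if (length(missing_cols) > 0L) {
    stop("change table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  kept <- table[!(table$subject %in% exclude), , drop = FALSE]
  values <- as.data.frame(kept[, unname(CHANGE_VARS)])
  names(values) <- names(CHANGE_VARS)
  complete <- stats::complete.cases(values)
  deleted <- kept$subject[!complete]
  values <- values[complete, , drop = FALSE]
  if (nrow(values) < 3L) {
    stop("fewer than 3 complete rows after exclusion and listwise ",
         "deletion; correlation matrix is not meaningful", call. = FALSE)
  }
  degenerate <- vapply(values, function(v) sd(v) == 0, logical(1))
  if (any(degenerate)) {
    warning("zero variance in column(s): ",
            paste(names(values)[degenerate], collapse = ", "),
            "; their correlations are undefined (NA)", call. = FALSE)
  }
  mat <- suppressWarnings(cor(values, method = method))
  diag(mat) <- 1
  mat[degenerate, ] <- NA_real_
  mat[, degenerate] <- NA_real_
  diag(mat)[degenerate] <- 1
  structure(
    list(method = method, variables = names(CHANGE_VARS), matrix = mat,
         n_used = nrow(values),
         excluded_participants = exclude %||% integer(0),
         deleted_listwise = deleted,
         undefined_variables = names(values)[degenerate]),
    class = "correlation_report"
  )
}

#' @export
print.correlation_report <- function(x, digits = 2, ...) {
  label <- paste0(toupper(substring(x$method, 1, 1)),
                  substring(x$method, 2))
  cat(sprintf("%s correlations, listwise deletion (n = %d",
              label, x$n_used))
  if (length(x$excluded_participants) > 0L) {
    cat("; excluded: ", paste(x$excluded_participants, collapse = ", "),
        sep = "")
  }
  cat(")\n")
  print(round(x$matrix, digits))
  invisible(x)
}

#' Rounded matrix of a correlation report
#'
#' Reported matrices are conventionally displayed at 2 decimals; the
#' report object keeps full precision internally.
#'
#' @param report a `correlation_report`.
#' @param digits decimal places (default 2).
#' @return The rounded correlation matrix.
#' @export
report_matrix <- function(report, digits = 2) {
  round(report$matrix, digits)
}

#' Correlations with and without flagged participants
#'
#' Robustness check for influential participants (e.g. one with most
#' study days missing): the correlation matrix is computed on the full
#' table and again with the flagged participants removed, together with
#' the elementwise difference (full minus excluded).
#'
#' @inheritParams correlation_matrix
#' @param flagged participant ids to remove in the comparison run; all
#'   must be present in the table.
#' @return A list with `full` and `excluded` (`correlation_report`s) and
#'   `difference` (matrix of full minus excluded entries).
#' @export
robustness_compare <- function(table, flagged,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  absent <- setdiff(flagged, table$subject)
  if (length(absent) > 0L) {
    stop("flagged participant(s) not in table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  full <- correlation_matrix(table, method = method)
  excluded <- correlation_matrix(table, method = method, exclude = flagged)
  list(full = full, excluded = excluded,
       difference = full$matrix - excluded$matrix)
}
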