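# Behavioral table handling and the residual dependent measures used by
# both mapping analyses. The packaged fixture is the verbatim behavioral /
# demographic table of a published 57-participant left-hemisphere stroke
# cohort: hand-posture accuracy when gesturing tool use (gts_hp) and when
# imitating meaningless gestures (imi_hp), three-trial-averaged grip
# strength per hand (missing where grip testing was not possible), months
# post-stroke, lesion volume in 1 mm^3 voxels, and demographics.

TABLE1_MD5 <- "1509814db4cb6028b18433a26935aed8"

behavior_columns <- c("subject_id", "gts_hp", "imi_hp", "lh_grip", "rh_grip",
                      "months_post", "lesion_volume", "education", "gender",
                      "age")

#' Validate a behavior table
#'
#' Checks the schema invariants: proportion scores in [0, 1], positive
#' months post-stroke, non-negative lesion volume, and missingness confined
#' to the grip columns.
#'
#' @param tab Data frame with the behavior-table columns.
#' @return The table, invisibly, with class `behavior_table`.
#' @export
validate_behavior_table <- function(tab) {
  missing_cols <- setdiff(behavior_columns, names(tab))
  if (length(missing_cols))
    stop("behavior table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(tab$gts_hp < 0 | tab$gts_hp > 1, na.rm = TRUE) || anyNA(tab$gts_hp))
    stop("gts_hp must be a complete proportion column in [0, 1]")
  if (any(tab$imi_hp < 0 | tab$imi_hp > 1, na.rm = TRUE) || anyNA(tab$imi_hp))
    stop("imi_hp must be a complete proportion column in [0, 1]")
  if (any(tab$months_post <= 0, na.rm = TRUE) || anyNA(tab$months_post))
    stop("months_post must be > 0")
  if (any(tab$lesion_volume < 0, na.rm = TRUE) || anyNA(tab$lesion_volume))
    stop("lesion_volume must be >= 0")
  for (col in setdiff(behavior_columns, c("lh_grip", "rh_grip")))
    if (anyNA(tab[[col]]))
      stop("missing values allowed only in grip columns, found in ", col)
  if (!inherits(tab, "behavior_table"))
    class(tab) <- c("behavior_table", class(tab))
  invisible(tab)
}

#' Load the packaged 57-participant behavioral table
#'
#' Returns the published cohort's behavioral and demographic data: 57 rows,
#' with grip strength missing exactly for the 16 participants who could not
#' perform the right-hand grip test (5 of whom have no grip data at all).
#' The file's checksum is verified so silent fixture corruption is caught.
#'
#' @return A `behavior_table` data frame with 57 rows.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_behavior.tsv", package = "disconlsm",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, TABLE1_MD5))
    stop("behavior fixture checksum mismatch: expected ", TABLE1_MD5,
         ", got ", md5)
  tab <- utils::read.delim(path, colClasses = c(subject_id = "character"))
  validate_behavior_table(tab)
  tab
}

#' Average grip-strength trials
#'
#' The grip protocol records three dynamometer trials per hand; the final
#' per-hand score is their arithmetic mean.
#'
#' @param trials Numeric vector of trial readings (>= 1 finite value).
#' @return The mean of the finite trials.
#' @export
average_grip_trials <- function(trials) {
  trials <- trials[is.finite(trials)]
  if (!length(trials)) stop("no finite grip trials to average")
  mean(trials)
}

#' Pearson correlation with schema guards
#'
#' Plain product-moment correlation; errors on degenerate input instead of
#' returning `NA`. Invariant under positive affine maps of either variable,
#' so accuracy and error proportions give identical r.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, nonzero variance.
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input to pearson_r")
  stats::cor(x, y)
}

#' Residualize a behavioral score on control regressors
#'
#' Ordinary least-squares residuals with an intercept. Used to isolate
#' variance unique to the primary measure: e.g. tool-use hand-posture
#' accuracy residualized on meaningless-imitation accuracy (negative
#' residual = worse tool-use gesturing than the control task predicts), or
#' right-hand grip residualized on left-hand grip.
#'
#' @param y Numeric response vector (no missing values; filter first).
#' @param regressors Numeric vector, matrix or data frame of regressors.
#' @param subject_ids Optional subject identifiers (default names of `y` or
#'   the row index).
#' @return Object of class `residual_scores`: `subject_ids`, `values`
#'   (zero-mean residuals orthogonal to every regressor), `formula_terms`.
#' @export
residualize <- function(y, regressors, subject_ids = NULL) {
  X <- as.matrix(regressors)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (anyNA(y) || anyNA(X)) stop("missing values: filter rows before residualizing")
  if (length(y) <= ncol(X) + 1L)
    stop("need n > number of regressors + 1")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  design <- cbind(`(intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("rank-deficient design; collinear regressor(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qrd, y)
  if (is.null(subject_ids))
    subject_ids <- if (!is.null(names(y))) names(y) else as.character(seq_along(y))
  structure(list(
    subject_ids = subject_ids,
    values = unname(res),
    formula_terms = colnames(X)
  ), class = "residual_scores")
}

#' @export
print.residual_scores <- function(x, ...) {
  cat("residual_scores: n =", length(x$values), "| removed:",
      paste(x$formula_terms, collapse = ", "), "\n")
  invisible(x)
}

# Extract a plain numeric target from residual_scores or numeric input.
as_target <- function(target) {
  if (inherits(target, "residual_scores")) target$values else as.numeric(target)
}
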