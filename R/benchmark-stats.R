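## Validation statistics for simulated-vs-experimental property vectors:
## average deviation (AVED) with its SD, and ordinary least-squares
## regression with a single-pass two-residual-SD outlier exclusion.

#' Average deviation between simulated and experimental values
#'
#' AVED is the mean of (simulated - experimental) over the molecules of one
#' property, together with its standard deviation. Entries must all belong
#' to the same property (units differ between properties).
#'
#' @param entries data.frame with columns `simulated`, `experimental` and
#'   optionally `property` (must then be a single value) and `molecule`.
#' @return List `aved`, `sd`, `n`.
#' @export
aved <- function(entries) {
  entries <- as.data.frame(entries)
  if (!nrow(entries)) stop("need at least one entry")
  if ("property" %in% names(entries) &&
      length(unique(entries$property)) > 1L)
    stop("entries mix properties: ",
         paste(unique(entries$property), collapse = ", "))
  dev <- entries$simulated - entries$experimental
  list(aved = mean(dev), sd = stats::sd(dev), n = length(dev))
}

#' Linear regression with single-pass 2-SD outlier exclusion
#'
#' Fits simulated ~ experimental by ordinary least squares; points whose
#' absolute residual exceeds twice the residual SD of that initial fit are
#' excluded in a single pass and the line is refit. R is the Pearson
#' correlation of the refit set.
#'
#' @param entries data.frame with columns `simulated`, `experimental` and
#'   optionally `molecule` (used to name the outliers).
#' @return Object of class `regression_summary`: `slope`, `intercept`, `R`,
#'   `n_used`, `outlier_names`, `outlier_idx`.
#' @export
regression_outlier_excluded <- function(entries) {
  entries <- as.data.frame(entries)
  if (nrow(entries) < 3L) stop("need at least 3 entries for a regression")
  if ("property" %in% names(entries) &&
      length(unique(entries$property)) > 1L)
    stop("entries mix properties")
  fit0 <- stats::lm(simulated ~ experimental, data = entries)
  res <- stats::residuals(fit0)
  keep <- abs(res) <= 2 * stats::sd(res)
  if (!any(keep)) stop("all points excluded as outliers")
  refit <- stats::lm(simulated ~ experimental, data = entries[keep, ])
  nms <- if ("molecule" %in% names(entries)) entries$molecule
         else as.character(seq_len(nrow(entries)))
  structure(list(slope = unname(stats::coef(refit)[2]),
                 intercept = unname(stats::coef(refit)[1]),
                 R = stats::cor(entries$experimental[keep],
                                entries$simulated[keep]),
                 n_used = sum(keep),
                 outlier_names = nms[!keep],
                 outlier_idx = unname(which(!keep))),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("y = %.4f x %+.4f,  R = %.3f,  n = %d%s\n",
              x$slope, x$intercept, x$R, x$n_used,
              if (length(x$outlier_names))
                paste0("  (excluded: ",
                       paste(x$outlier_names, collapse = ", "), ")")
              else ""))
  invisible(x)
}
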