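## Predictor-versus-endpoint correlation analysis over a variant panel:
## each in-silico predictor column is correlated (Pearson) against a measured
## endpoint, overall and within each design round, with the linear fit
## parameters used for plotting.

#' Pearson correlation with strict preconditions
#'
#' Standard product-moment correlation, refusing degenerate input (fewer
#' than 3 pairs, or zero variance in either vector) instead of returning
#' `NA`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return The correlation coefficient.
#' @export
pearsonR <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Round membership for panel variants
#'
#' The parental molecule is grouped with round 1 (it anchors the round-1
#' panel in the published correlation figure).
#'
#' @param names character vector of variant names.
#' @return Factor-like character vector, `"round1"` or `"round2"`.
#' @export
assignRound <- function(names) {
  ifelse(grepl("^R2-", names), "round2", "round1")
}

#' Correlate predictors against a measured endpoint
#'
#' For each predictor column and each subset (overall, round 1 including the
#' parental, round 2) computes the Pearson correlation with the endpoint
#' column and the least-squares line for plotting.  Correlations are
#' computed on the panel columns as given (the published, printed scores);
#' to correlate recomputed sequence scores instead, replace the columns via
#' [scoreVariantPanel()] first — that is a deliberately separate mode.
#'
#' @param panel a panel data frame, see [variantPanel()].
#' @param predictors character vector of predictor column names.
#' @param endpoint endpoint column name (default the concentration at which
#'   viscosity reaches 20 cP).
#' @param subsets which subsets to report.
#' @return A data frame with columns `predictor`, `subset`, `r`, `n`,
#'   `slope`, `intercept`.
#'
#' @examples
#' correlationSweep(variantPanel(), c("fv_charge", "sharma_score"))
#' @export
correlationSweep <- function(panel,
                             predictors = c("fv_charge", "sharma_score",
                                            "tomar_score", "scm_score"),
                             endpoint = "conc_at_20cp",
                             subsets = c("overall", "round1", "round2")) {
  miss <- setdiff(c(predictors, endpoint), names(panel))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  round <- assignRound(panel$name)
  rows <- list()
  for (p in predictors) {
    for (s in subsets) {
      keep <- if (s == "overall") rep(TRUE, nrow(panel)) else round == s
      x <- panel[[p]][keep]
      y <- panel[[endpoint]][keep]
      ok <- stats::complete.cases(x, y)
      fit <- stats::lsfit(x[ok], y[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = p, subset = s, r = pearsonR(x, y), n = sum(ok),
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Scatter plot of a predictor against the endpoint
#'
#' One panel of the correlation figure: endpoint against predictor with the
#' overall and per-round least-squares lines.
#'
#' @inheritParams correlationSweep
#' @param predictor a single predictor column name.
#' @param ... passed to [plot()].
#' @return The sweep rows for this predictor, invisibly.
#' @export
plotCorrelation <- function(panel, predictor, endpoint = "conc_at_20cp",
                            ...) {
  sweep <- correlationSweep(panel, predictor, endpoint)
  round <- assignRound(panel$name)
  col <- ifelse(round == "round2", "grey40", "black")
  pch <- ifelse(round == "round2", 1, 16)
  plot(panel[[predictor]], panel[[endpoint]], col = col, pch = pch,
       xlab = predictor, ylab = endpoint, ...)
  for (i in seq_len(nrow(sweep))) {
    lty <- match(sweep$subset[i], c("overall", "round1", "round2"))
    graphics::abline(sweep$intercept[i], sweep$slope[i], lty = lty)
  }
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("%s R = %.2f", sweep$subset, sweep$r),
                   lty = seq_len(nrow(sweep)))
  invisible(sweep)
}
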