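.PFT_MEASURES <- c(DLCO = "dlco_pct", FEV1 = "fev1_pct", FVC = "fvc_pct",
                   FEV1_FVC = "fev1_fvc")

#' Spearman rank correlation with tie handling
#'
#' Pearson correlation of the average-ranked inputs (tie-safe), with a
#' two-sided p-value from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}. A perfect correlation reports the
#' smallest positive double as its p-value. Zero rank variance in either
#' input makes the coefficient undefined (\code{NA}).
#'
#' @param x,y numeric vectors of equal length >= 3, finite.
#' @return A list with elements \code{rho} and \code{p}.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (var(rx) == 0 || var(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Significance stars for a p-value
#'
#' \code{"***"} for p < 0.005, \code{"**"} for p < 0.01, \code{"*"} for
#' p < 0.05, otherwise an empty string. The annotations are descriptive; no
#' multiple-testing correction is applied.
#'
#' @param p p-value in (0, 1].
#' @return A string of 0 to 3 stars.
#' @export
significanceStars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.005) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Rank MetricSpecs by Spearman correlation with one PFT measure
#'
#' Cases missing the measure are excluded pairwise (so DLCO rankings may use
#' fewer cases); specs whose score is undefined for at least one cohort case
#' are dropped. Ranking is by |rho| descending, ties by smaller p-value, then
#' by the canonical spec id string.
#'
#' @param scores score matrix from \code{\link{scoreCohort}} (rownames =
#'   case ids).
#' @param pft PFT data.frame (see \code{\link{readPftTable}}).
#' @param measure one of \code{"DLCO"}, \code{"FEV1"}, \code{"FVC"},
#'   \code{"FEV1_FVC"}.
#' @param k number of top specs to return (default 5).
#' @return A data.frame with columns \code{id}, \code{measure}, \code{rho},
#'   \code{p}, \code{stars}, \code{n}, ordered best first.
#' @export
rankSpecs <- function(scores, pft, measure, k = 5L) {
  measure <- match.arg(measure, names(.PFT_MEASURES))
  y <- pft[[.PFT_MEASURES[[measure]]]][match(rownames(scores), pft$case_id)]
  use <- !is.na(y)
  if (sum(use) < 3L)
    stop("fewer than 3 cases with ", measure, " present")
  defined <- colSums(is.na(scores)) == 0L
  sub <- scores[use, defined, drop = FALSE]
  yy <- y[use]
  # vectorized Spearman: Pearson on average ranks, column-wise
  n <- length(yy)
  rk <- apply(sub, 2L, rank, ties.method = "average")
  ry <- rank(yy, ties.method = "average")
  rkc <- rk - rep(colMeans(rk), each = n)
  ryc <- ry - mean(ry)
  den2 <- colSums(rkc^2) * sum(ryc^2)
  rho <- as.numeric(crossprod(rkc, ryc)) / sqrt(den2)
  rho[den2 == 0] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- ifelse(abs(rho) >= 1, .Machine$double.xmin,
              2 * pt(-abs(tstat), df = n - 2))
  ok <- !is.na(rho)
  df <- data.frame(id = colnames(sub)[ok], measure = measure, rho = rho[ok],
                   p = p[ok], stars = vapply(p[ok], significanceStars,
                                             character(1)),
                   n = sum(use), stringsAsFactors = FALSE)
  df <- df[order(-abs(df$rho), df$p, df$id), , drop = FALSE]
  rownames(df) <- NULL
  head(df, k)
}

#' Brute-force correlation search over the whole spec space
#'
#' Correlates every enumerated MetricSpec score with each requested PFT
#' measure, returning the top-k table per measure (the shape of the study's
#' ranked-metric tables) and a best-|rho| grid per scenario and measure (the
#' shape of its heatmaps). Measures with fewer than 3 usable cases are
#' skipped with a warning.
#'
#' @param scores score matrix from \code{\link{scoreCohort}} (with its
#'   \code{"specs"} attribute, or any matrix whose columns are spec ids).
#' @param pft PFT data.frame.
#' @param measures PFT measures to rank against.
#' @param topK top specs retained per measure.
#' @return A list with \code{topk} (named list of data.frames), \code{best}
#'   (one-row-per-measure data.frame of the single best spec), and
#'   \code{heatmap} (data.frame scenario x measure of best |rho|).
#' @export
searchCorrelations <- function(scores, pft,
                               measures = names(.PFT_MEASURES), topK = 5L) {
  measures <- match.arg(measures, names(.PFT_MEASURES), several.ok = TRUE)
  topk <- list()
  full <- list()
  bestRows <- list()
  heat <- list()
  scenarioOf <- function(ids) vapply(strsplit(ids, "|", fixed = TRUE),
                                     `[[`, character(1), 1L)
  for (m in measures) {
    ranked <- tryCatch(
      rankSpecs(scores, pft, m, k = ncol(scores)),
      error = function(e) {
        warning("skipping ", m, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(ranked) || nrow(ranked) == 0L) next
    full[[m]] <- ranked
    topk[[m]] <- head(ranked, topK)
    bestRows[[m]] <- ranked[1L, ]
    sc <- scenarioOf(ranked$id)
    heat[[m]] <- vapply(.SCENARIOS, function(s) {
      sub <- ranked[sc == s, , drop = FALSE]
      if (nrow(sub)) sub$rho[which.max(abs(sub$rho))] else NA_real_
    }, numeric(1))
  }
  heatmap <- if (length(heat))
    data.frame(scenario = .SCENARIOS, as.data.frame(heat),
               check.names = FALSE) else NULL
  list(topk = topk, best = do.call(rbind, bestRows), heatmap = heatmap,
       full = full)
}
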