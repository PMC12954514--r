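#' Build the candidate covariate pool for classification
#'
#' Assembles the top-k global scores per PFT measure (DLCO, FEV1, FEV1/FVC;
#' FVC is excluded from classification for its comparatively weak
#' correlations) into a case x covariate matrix. Columns are named
#' \code{<measure>_top<rank>} and carry the spec-id map and the group
#' (measure) of each covariate as attributes.
#'
#' @param scores score matrix from \code{\link{scoreCohort}}.
#' @param pft PFT data.frame.
#' @param topK covariates retained per measure.
#' @param caseIds cases (rows) to keep; default all rows of \code{scores}.
#' @return Numeric matrix with attributes \code{"groups"} (measure per
#'   column) and \code{"specIds"} (spec id per column).
#' @export
candidatePool <- function(scores, pft, topK = 5L,
                          caseIds = rownames(scores)) {
  measures <- c("DLCO", "FEV1", "FEV1_FVC")
  cols <- list()
  groups <- character()
  ids <- character()
  for (m in measures) {
    ranked <- rankSpecs(scores, pft, m, k = topK)
    for (r in seq_len(nrow(ranked))) {
      nm <- sprintf("%s_top%d", m, r)
      cols[[nm]] <- scores[caseIds, ranked$id[r]]
      groups <- c(groups, m)
      ids <- c(ids, ranked$id[r])
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- caseIds
  attr(X, "groups") <- groups
  attr(X, "specIds") <- ids
  X
}

#' Classify normal vs abnormal lung function from global scores
#'
#' End-to-end classification protocol: label cases from the PFT thresholds
#' (cases missing DLCO are excluded), assemble the top-k global scores per
#' measure as candidate covariates, report full and cross-group variance
#' inflation factors, run the exhaustive best-subset LOOCV search, and
#' derive the ROC curve of the winning model.
#'
#' @param scores score matrix from \code{\link{scoreCohort}}.
#' @param pft PFT data.frame.
#' @param config a \code{\link{runConfig}}.
#' @return A list with \code{model} (the winning
#'   \code{\link{fitLogregLoocv}} result), \code{roc}, \code{vif_full},
#'   \code{vif_cross}, \code{pool} (candidate matrix), \code{labels}
#'   (label data.frame restricted to classified cases).
#' @export
classifyCohort <- function(scores, pft, config = runConfig()) {
  thr <- config$thresholds
  labels <- labelFunction(pft, thr)
  keep <- labels$case_id[!is.na(labels$label)]
  keep <- intersect(rownames(scores), keep)
  labels <- labels[match(keep, labels$case_id), ]
  y <- .asBinary(labels$label)
  # keep the pool small enough for the VIF diagnostics (need n > p + 1)
  topK <- min(config$topK, max(1L, (length(keep) - 2L) %/% 3L))
  if (topK < config$topK)
    warning("candidate pool reduced to top-", topK,
            " per measure for n = ", length(keep), " cases", call. = FALSE)
  pool <- candidatePool(scores, pft, topK = topK, caseIds = keep)
  vifFull <- vif(pool)
  vifCross <- crossGroupVif(pool, attr(pool, "groups"))
  model <- bestSubsetSearch(pool, y, maxSubsetSize = config$maxSubsetSize,
                            maxSubsets = config$maxSubsets)
  roc <- rocCurve(model$prob, y)
  list(model = model, roc = roc, vif_full = vifFull, vif_cross = vifCross,
       pool = pool, labels = labels)
}

#' Write correlation-search reports
#'
#' Emits \code{search_long.csv} (every spec x measure: id, measure, rho, p,
#' stars, n), \code{search_topk.csv} and \code{search_topk.json} (top-k per
#' measure), and \code{search_heatmap.csv} (best rho per scenario and
#' measure).
#'
#' @param search result of \code{\link{searchCorrelations}}.
#' @param dir output directory.
#' @return Invisibly, \code{dir}.
#' @export
writeSearchReport <- function(search, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, search$full)
  write.csv(long, file.path(dir, "search_long.csv"), row.names = FALSE)
  topk <- do.call(rbind, search$topk)
  write.csv(topk, file.path(dir, "search_topk.csv"), row.names = FALSE)
  jsonlite::write_json(search$topk, file.path(dir, "search_topk.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(search$heatmap))
    write.csv(search$heatmap, file.path(dir, "search_heatmap.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' Write classification reports
#'
#' Emits \code{model.json} (covariates with mean/sd coefficients, bias, AUC,
#' F1, accuracy, confusion counts), \code{roc.csv}, \code{confusion.csv} and
#' the VIF tables (\code{vif.csv}: full and cross-group).
#'
#' @param classification result of \code{\link{classifyCohort}}.
#' @param dir output directory.
#' @return Invisibly, \code{dir}.
#' @export
writeClassifyReport <- function(classification, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- classification$model
  rep <- list(
    covariates = model$covariates, subset = model$subset,
    bias_mean = model$bias_mean, bias_sd = model$bias_sd, auc = model$auc,
    f1 = model$f1, accuracy = model$accuracy,
    confusion = as.list(model$confusion), n = model$n,
    n_subsets_evaluated = model$n_evaluated,
    ridge_fallback_used = model$ridge_used)
  jsonlite::write_json(rep, file.path(dir, "model.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write.csv(classification$roc$points, file.path(dir, "roc.csv"),
            row.names = FALSE)
  conf <- as.data.frame(as.list(model$confusion))
  write.csv(conf, file.path(dir, "confusion.csv"), row.names = FALSE)
  vifTab <- data.frame(covariate = names(classification$vif_full),
                       group = attr(classification$pool, "groups"),
                       spec_id = attr(classification$pool, "specIds"),
                       vif_full = unname(classification$vif_full),
                       vif_cross_group = unname(classification$vif_cross),
                       stringsAsFactors = FALSE)
  write.csv(vifTab, file.path(dir, "vif.csv"), row.names = FALSE)
  invisible(dir)
}
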