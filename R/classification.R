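#' Normal/abnormal lung-function labels from PFT thresholds
#'
#' A case is labelled abnormal when DLCO < 60\% predicted, FEV1 < 70\%
#' predicted, or FEV1/FVC < 70 (strict inequalities, values compared exactly
#' as recorded); only when all three exceed their thresholds is it deemed
#' normal. Cases missing DLCO cannot be assessed against the full criterion
#' set and receive an \code{NA} label (they are excluded from
#' classification).
#'
#' @param pft PFT data.frame (see \code{\link{readPftTable}}).
#' @param thresholds named numeric: \code{dlco}, \code{fev1},
#'   \code{fev1_fvc}.
#' @return A data.frame with columns \code{case_id}, \code{label}
#'   (\code{"normal"}/\code{"abnormal"}/\code{NA}) and \code{triggered_by}
#'   (comma-separated subset of DLCO, FEV1, FEV1_FVC; empty for normal).
#' @export
labelFunction <- function(pft,
                          thresholds = c(dlco = 60, fev1 = 70,
                                         fev1_fvc = 70)) {
  if (any(is.na(pft$fev1_pct)) || any(is.na(pft$fev1_fvc)))
    stop("fev1_pct and fev1_fvc must be present for every case")
  trig <- function(dlco, fev1, ratio) {
    t <- c(DLCO = !is.na(dlco) && dlco < thresholds[["dlco"]],
           FEV1 = fev1 < thresholds[["fev1"]],
           FEV1_FVC = ratio < thresholds[["fev1_fvc"]])
    paste(names(t)[t], collapse = ",")
  }
  out <- data.frame(case_id = pft$case_id, label = NA_character_,
                    triggered_by = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pft))) {
    if (is.na(pft$dlco_pct[i])) next
    tb <- trig(pft$dlco_pct[i], pft$fev1_pct[i], pft$fev1_fvc[i])
    out$label[i] <- if (nzchar(tb)) "abnormal" else "normal"
    out$triggered_by[i] <- tb
  }
  out
}

#' Leave-one-out logistic regression of function labels on global scores
#'
#' For each of the n folds the held-out case is removed, the covariates are
#' z-scored on the training fold, an unpenalized maximum-likelihood logistic
#' regression is fitted (with a tiny ridge, 1e-8, as numerical fallback on
#' separable or degenerate folds; its use is disclosed in the report), and
#' the held-out probability of abnormality is predicted. AUC is computed
#' over the pooled held-out probabilities (rank/Mann-Whitney form); F1,
#' accuracy and the confusion matrix use probability threshold 0.5 with
#' abnormal as the positive class. Coefficients are reported as mean and sd
#' over the n fold fits (on the standardized scale).
#'
#' @param X numeric matrix, cases x covariates (colnames = covariate ids).
#' @param y labels: 0/1 numeric, logical, or \code{"normal"}/\code{"abnormal"}
#'   (abnormal = 1).
#' @return An object of class \code{"voroperfModel"}: a list with
#'   \code{covariates} (data.frame id, coef_mean, coef_sd), \code{bias_mean},
#'   \code{bias_sd}, \code{auc}, \code{f1}, \code{accuracy},
#'   \code{confusion} (tp, fp, tn, fn), \code{prob} (held-out
#'   probabilities), \code{n}, \code{ridge_used}.
#' @export
fitLogregLoocv <- function(X, y) {
  X <- as.matrix(X)
  y <- .asBinary(y)
  n <- nrow(X)
  if (n < 6L) stop("need at least 6 cases")
  if (length(y) != n) stop("label length mismatch")
  if (anyNA(X)) stop("undefined covariate values")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  res <- .loocvLogisticCpp(X, as.numeric(y))
  prob <- as.numeric(res$prob)
  coefs <- res$coef # n x (p+1), col 1 = intercept
  pred <- as.integer(prob > 0.5)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("x", seq_len(ncol(X)))
  structure(list(
    covariates = data.frame(id = ids,
                            coef_mean = apply(coefs[, -1L, drop = FALSE], 2,
                                              mean),
                            coef_sd = apply(coefs[, -1L, drop = FALSE], 2,
                                            sd),
                            stringsAsFactors = FALSE, row.names = NULL),
    bias_mean = mean(coefs[, 1L]), bias_sd = sd(coefs[, 1L]),
    auc = res$auc, f1 = f1, accuracy = (tp + tn) / n,
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    prob = prob, y = y, n = n, ridge_used = res$ridge_used),
    class = "voroperfModel")
}

.asBinary <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    if (!all(y %in% c("normal", "abnormal")))
      stop("labels must be 'normal'/'abnormal' or 0/1")
    as.integer(y == "abnormal")
  } else {
    y <- as.integer(y)
    if (!all(y %in% c(0L, 1L))) stop("labels must be binary")
    y
  }
}

#' @export
print.voroperfModel <- function(x, ...) {
  cat(sprintf(
    "LOOCV logistic model: %d cases, %d covariates\n  AUC %.3f  F1 %.3f  accuracy %.3f%s\n",
    x$n, nrow(x$covariates), x$auc, x$f1, x$accuracy,
    if (isTRUE(x$ridge_used)) "  (ridge fallback used)" else ""))
  cat(sprintf("  confusion: TP %d FP %d TN %d FN %d\n", x$confusion["tp"],
              x$confusion["fp"], x$confusion["tn"], x$confusion["fn"]))
  df <- x$covariates
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %s: %.3f +/- %.3f\n", df$id[i], df$coef_mean[i],
                df$coef_sd[i]))
  cat(sprintf("  bias: %.3f +/- %.3f\n", x$bias_mean, x$bias_sd))
  invisible(x)
}

#' ROC curve and AUC from pooled held-out probabilities
#'
#' Sweeps every distinct probability as a threshold and reports (FPR, TPR)
#' points; the AUC is the trapezoid integral, which equals the normalized
#' Mann-Whitney U statistic.
#'
#' @param prob predicted probabilities of the positive (abnormal) class.
#' @param y binary labels (see \code{\link{fitLogregLoocv}}).
#' @return A list with \code{points} (data.frame threshold, fpr, tpr) and
#'   \code{auc}.
#' @export
rocCurve <- function(prob, y) {
  y <- .asBinary(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  thr <- c(Inf, sort(unique(prob), decreasing = TRUE))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  tpr <- vapply(thr, function(t) sum(prob >= t & y == 1L) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(prob >= t & y == 0L) / n0, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

# R^2 of covariate j regressed (with intercept) on the given regressors.
.auxR2 <- function(xj, Z) {
  if (is.null(Z) || ncol(Z) == 0L) return(0)
  fit <- lm.fit(cbind(1, Z), xj)
  ssr <- sum(fit$residuals^2)
  sst <- sum((xj - mean(xj))^2)
  if (sst == 0) return(0)
  1 - ssr / sst
}

#' Variance inflation factors
#'
#' \code{vif} regresses each covariate on all the others (with intercept)
#' and reports \eqn{1/(1-R^2)}; exact collinearity is reported as
#' \code{Inf}. \code{crossGroupVif} restricts the regressors to covariates
#' from other groups (covariates targeting a different PFT measure),
#' removing the collinearity that is expected among metrics selected for the
#' same measure.
#'
#' @param X numeric matrix, cases x covariates.
#' @param groups character vector mapping each covariate to its PFT-measure
#'   group (\code{crossGroupVif} only).
#' @return Named numeric vector of VIFs (may contain \code{Inf}).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (nrow(X) <= p + 1L) stop("need n > number of regressors + 1")
  out <- vapply(seq_len(p), function(j) {
    r2 <- .auxR2(X[, j], X[, -j, drop = FALSE])
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}

#' @rdname vif
#' @export
crossGroupVif <- function(X, groups) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (length(groups) != p) stop("groups length must match covariate count")
  out <- vapply(seq_len(p), function(j) {
    other <- which(groups != groups[j])
    if (nrow(X) <= length(other) + 1L)
      stop("need n > number of cross-group regressors + 1")
    r2 <- .auxR2(X[, j], X[, other, drop = FALSE])
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}

#' Exhaustive best-subset covariate search under LOOCV
#'
#' Evaluates every non-empty subset of the candidate covariates (subject to
#' the size and count caps) by LOOCV AUC and returns the best model; ties go
#' to higher F1, then fewer covariates, then the canonical ordering of the
#' sorted covariate-id strings.
#'
#' @param X candidate covariate matrix (cases x covariates, colnames = ids),
#'   typically the top-k spec scores per PFT measure.
#' @param y binary labels.
#' @param maxSubsetSize cap on subset cardinality (default: no cap).
#' @param maxSubsets cap on the number of subsets evaluated (default
#'   \code{2^15 - 1}).
#' @return The winning model (\code{\link{fitLogregLoocv}} result) with
#'   extra fields \code{subset} (covariate ids) and \code{n_evaluated}.
#' @export
bestSubsetSearch <- function(X, y, maxSubsetSize = NULL,
                             maxSubsets = 2^15 - 1) {
  X <- as.matrix(X)
  y <- .asBinary(y)
  p <- ncol(X)
  if (p == 0L) stop("config error: empty candidate pool")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (is.null(maxSubsetSize) || is.na(maxSubsetSize)) maxSubsetSize <- p
  tab <- .bestSubsetCpp(X, as.numeric(y), as.integer(maxSubsetSize),
                        as.numeric(maxSubsets))
  if (nrow(tab) == 0L) stop("no subsets evaluated")
  masks <- tab[, "mask"]
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(p - 1))) > 0),
                  numeric(1))
  keys <- vapply(masks, function(m) {
    ids <- colnames(X)[bitwAnd(m, 2^(0:(p - 1))) > 0]
    paste(sort(ids), collapse = "+")
  }, character(1))
  ord <- order(-tab[, "auc"], -tab[, "f1"], sizes, keys)
  bestMask <- masks[ord[1L]]
  cols <- which(bitwAnd(bestMask, 2^(0:(p - 1))) > 0)
  model <- fitLogregLoocv(X[, cols, drop = FALSE], y)
  model$subset <- colnames(X)[cols]
  model$n_evaluated <- nrow(tab)
  model
}
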