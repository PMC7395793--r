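## Performance metrics: selectivity assignment, odor reconstruction,
## correlation performance, generalized ROC, normalized weight error,
## lifetime sparseness, M/T response variance.

#' Assign each cell's preferred odor by weight covariance
#'
#' Because learning is unsupervised, cell `j` is matched to the odor whose
#' true mixing-weight column has maximal covariance (across glomeruli)
#' with the cell's learned weight row.  Ties are broken deterministically
#' toward the lowest odor index.
#'
#' @param wLearned `M x N` learned weights (feedforward or readout).
#' @param WTrue `N x M` true mixing matrix.
#' @return integer vector of length `M`: odor index assigned to each cell
#'   (not necessarily injective).
#' @export
assignSelectivity <- function(wLearned, WTrue) {
  stopifnot(ncol(wLearned) == nrow(WTrue))
  a <- sweep(t(wLearned), 2, colMeans(t(wLearned)), `-`)  # N x M, centered
  b <- sweep(WTrue, 2, colMeans(WTrue), `-`)
  cv <- crossprod(a, b)                                   # cells x odors
  apply(cv, 1, which.max)                                 # first max: lowest index
}

#' Reconstruct odor concentrations from assigned cell responses
#'
#' The estimate for odor `j` is the mean response of the cells assigned to
#' it, or 0 when no cell is assigned.
#'
#' @param rates length-`M` cell responses (granule `cbar` or piriform
#'   `pbar`).
#' @param selectivity integer assignment from [assignSelectivity()],
#'   computed from the *previous* trial's weights.
#' @param M number of odors.
#' @return length-`M` estimated concentration vector.
#' @export
reconstructOdors <- function(rates, selectivity, M) {
  out <- numeric(M)
  sums <- tapply(rates, factor(selectivity, levels = seq_len(M)), mean)
  got <- !is.na(sums)
  out[got] <- sums[got]
  out
}

#' Pooled correlation between estimated and true concentrations
#'
#' Pearson correlation pooled jointly over odors and trials in the
#' evaluation block.  Returns `NA` when either side has zero variance.
#'
#' @param cHat matrix (trials x M) of estimates.
#' @param cTrue matrix (trials x M) of true values.
#' @param perTrial also return the mean of per-trial correlations.
#' @return the pooled correlation, or a list with both when
#'   `perTrial = TRUE`.
#' @export
performanceCorrelation <- function(cHat, cTrue, perTrial = FALSE) {
  cHat <- as.matrix(cHat); cTrue <- as.matrix(cTrue)
  stopifnot(all(dim(cHat) == dim(cTrue)))
  pooled <- if (sd(cHat) == 0 || sd(cTrue) == 0) NA_real_ else
    cor(as.vector(cHat), as.vector(cTrue))
  if (!perTrial) return(pooled)
  pt <- vapply(seq_len(nrow(cHat)), function(i) {
    if (sd(cHat[i, ]) == 0 || sd(cTrue[i, ]) == 0) NA_real_ else
      cor(cHat[i, ], cTrue[i, ])
  }, 0)
  list(pooled = pooled, perTrial = mean(pt, na.rm = TRUE))
}

#' Generalized ROC curve for odor detection
#'
#' Trials are grouped by the number of simultaneously presented odors.
#' For each detection threshold (log-spaced from 1e-6 to 10 with 20%
#' steps), the true-positive fraction is the fraction of presented odors
#' whose estimate exceeds the threshold, and the false-positive count is
#' the number of absent odors whose estimate exceeds it (both averaged
#' over trials in the group).
#'
#' @inheritParams performanceCorrelation
#' @param thresholds detection threshold grid; the default implements the
#'   1.2-fold ladder.
#' @return data frame with columns `nOdors`, `threshold`, `tpFraction`,
#'   `fpCount`.
#' @export
rocCurve <- function(cHat, cTrue,
                     thresholds = 1e-6 * 1.2^(0:ceiling(log(1e7, 1.2)))) {
  cHat <- as.matrix(cHat); cTrue <- as.matrix(cTrue)
  stopifnot(all(dim(cHat) == dim(cTrue)))
  thresholds <- thresholds[thresholds <= 1e1 * 1.2]
  nPresented <- rowSums(cTrue > 0)
  out <- lapply(sort(unique(nPresented)), function(k) {
    rows <- which(nPresented == k)
    tp <- vapply(thresholds, function(th)
      mean(vapply(rows, function(i)
        sum(cHat[i, ] > th & cTrue[i, ] > 0) / k, 0)), 0)
    fp <- vapply(thresholds, function(th)
      mean(vapply(rows, function(i)
        sum(cHat[i, ] > th & cTrue[i, ] == 0), 0)), 0)
    data.frame(nOdors = k, threshold = thresholds, tpFraction = tp,
               fpCount = fp)
  })
  do.call(rbind, out)
}

#' Normalized error between learned and true mixing weights
#'
#' Root-mean-square distance between each cell's learned weight row --
#' rescaled by `Z_j = sum_i wLearned[j,i] / sum_i WTrue[i, o(j)]`, which
#' absorbs any global scale -- and the true column of its assigned odor,
#' averaged over cells.
#'
#' @inheritParams assignSelectivity
#' @param selectivity assignment from [assignSelectivity()].
#' @param rescale optional display multiplier (a 7/3 factor is used in
#'   some sparse-prior comparisons); default 1.
#' @return the scalar weight error.
#' @export
weightError <- function(wLearned, WTrue, selectivity, rescale = 1) {
  M <- nrow(wLearned); N <- ncol(wLearned)
  zw <- rowSums(wLearned) / colSums(WTrue)[selectivity]
  if (any(zw == 0)) stop("degenerate weight scale Z = 0", call. = FALSE)
  perCell <- vapply(seq_len(M), function(j)
    sqrt(mean((wLearned[j, ] / zw[j] - WTrue[, selectivity[j]])^2)), 0)
  rescale * mean(perCell)
}

#' Lifetime sparseness of single-odor responses
#'
#' `S_j = (mean_m r_j^(m))^2 / mean_m (r_j^(m))^2` over stimuli `m`;
#' 1 for perfectly uniform tuning, `1/M` for one-hot tuning, `NA` for a
#' silent cell.
#'
#' @param responses `M x M` matrix of responses, stimuli in rows, cells in
#'   columns.
#' @return length-`M` vector of sparseness values.
#' @export
lifetimeSparseness <- function(responses) {
  responses <- as.matrix(responses)
  num <- colMeans(responses)^2
  den <- colMeans(responses^2)
  s <- ifelse(den > 0, num / den, NA_real_)
  unname(s)
}

#' Pooled variance of M/T responses over cells and trials
#'
#' @param mMat matrix of steady-state M/T rates, trials in rows.
#' @return the pooled sample variance.
#' @export
mtVariance <- function(mMat) {
  var(as.vector(as.matrix(mMat)))
}
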