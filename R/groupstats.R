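# Group-level paired permutation tests with cluster-based correction for
# multiple comparisons, over 1D coherence spectra or 2D comodulograms.

#' Permutation test configuration
#'
#' @param nPerm number of sign-flip permutations (default 1000)
#' @param alpha cluster significance level (default 0.05)
#' @param clusterFormingP two-sided per-bin threshold forming clusters
#'   (default 0.05)
#' @param seed RNG seed for the permutation draws
#' @return a list with the four settings
#' @export
permutationConfig <- function(nPerm = 1000, alpha = 0.05,
                              clusterFormingP = 0.05, seed = 1) {
  stopIfNot(nPerm >= 100, "nPerm must be >= 100")
  stopIfNot(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  stopIfNot(clusterFormingP > 0 && clusterFormingP < 1,
            "clusterFormingP must lie in (0, 1)")
  list(nPerm = as.integer(nPerm), alpha = alpha,
       clusterFormingP = clusterFormingP, seed = as.integer(seed))
}

# Contiguity labels for suprathreshold cells: 1D runs or 2D 4-connectivity.
labelClusters <- function(flag) {
  if (is.matrix(flag)) label2D(flag)
  else cumsum(flag & !c(FALSE, flag[-length(flag)])) * flag
}

label2D <- function(flag) {
  nr <- nrow(flag); nc <- ncol(flag)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(flag)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cell - 1L) %% nr + 1L
      cl <- (cell - 1L) %/% nr + 1L
      nb <- c(if (r > 1L) cell - 1L, if (r < nr) cell + 1L,
              if (cl > 1L) cell - nr, if (cl < nc) cell + nr)
      nb <- nb[flag[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  lab
}

# Paired t statistics per bin for a given sign-flip vector; the sum of
# squares is sign-invariant, so only the signed mean is recomputed.
pairedT <- function(dMat, signs, SS) {
  n <- nrow(dMat)
  m <- as.vector(crossprod(dMat, signs)) / n
  v <- pmax(0, (SS - n * m^2) / (n - 1))
  t <- m / sqrt(v / n)
  t[!is.finite(t)] <- 0     # zero-variance bins carry no evidence
  t
}

# Max |cluster mass| for one t vector (shaped as dims) at threshold tcrit.
maxClusterMass <- function(t, dims, tcrit) {
  best <- 0
  for (pol in c(1, -1)) {
    flag <- pol * t > tcrit
    if (!any(flag)) next
    lab <- labelClusters(array(flag, dims))
    mass <- vapply(split(t[lab > 0], lab[lab > 0]), sum, numeric(1))
    best <- max(best, abs(mass))
  }
  best
}

#' Cluster-corrected paired permutation test
#'
#' Compares per-subject real values against paired surrogate values over a
#' 1D (spectrum) or 2D (comodulogram) frequency grid. Per bin, a paired t
#' statistic of (real - surrogate) is computed; bins whose |t| exceeds the
#' two-sided \code{clusterFormingP} threshold are grouped into clusters by
#' adjacency (neighboring bins in 1D, 4-connectivity in 2D) separately for
#' each polarity, and each cluster's mass is its summed t. The null
#' distribution is the maximum |cluster mass| over \code{nPerm} random
#' per-subject sign flips, and each observed cluster gets
#' \eqn{p = (1 + \#\{null \ge |mass|\}) / (nPerm + 1)}.
#'
#' Subjects are internally put into a canonical order (by their difference
#' rows) before the sign-flip draws, so results do not depend on the input
#' subject order.
#'
#' @param real per-subject real values: a list of equal-shaped numeric
#'   arrays, a subjects x bins matrix, or a subjects x rows x cols 3D array
#' @param surrogate paired surrogate values, same shape and subject order
#' @param config from \code{\link{permutationConfig}}
#' @return list of \linkS4class{ClusterResult}, ordered by p value
#' @examples
#' real <- matrix(rnorm(8 * 20), 8); real[, 9:12] <- real[, 9:12] + 1.5
#' res <- clusterPermutationPaired(real, matrix(rnorm(8 * 20), 8),
#'                                 permutationConfig(nPerm = 200))
#' @export
clusterPermutationPaired <- function(real, surrogate,
                                     config = permutationConfig()) {
  toArr <- function(x) {
    if (is.list(x)) {
      shapes <- lapply(x, function(e) dim(e) %||% length(e))
      stopIfNot(length(unique(shapes)) == 1L,
                "per-subject arrays differ in shape")
      t(vapply(x, as.vector, numeric(length(as.vector(x[[1]])))))
    } else if (length(dim(x)) == 3L) {
      matrix(x, nrow = dim(x)[1])
    } else as.matrix(x)
  }
  dims <- function(x) {
    if (is.list(x)) dim(x[[1]]) %||% length(x[[1]])
    else if (length(dim(x)) == 3L) dim(x)[-1]
    else ncol(as.matrix(x))
  }
  shape <- dims(real)
  stopIfNot(identical(dims(surrogate), shape),
            "real and surrogate shapes differ")
  dR <- toArr(real); dS <- toArr(surrogate)
  stopIfNot(nrow(dR) == nrow(dS), "subject counts differ")
  n <- nrow(dR)
  stopIfNot(n >= 5, "need at least 5 subjects (sign-flip null too coarse)")
  d <- dR - dS
  # canonical subject order: p values independent of input row order
  d <- d[do.call(order, as.data.frame(cbind(rowSums(d), d))), ,
         drop = FALSE]
  SS <- colSums(d^2)
  tcrit <- stats::qt(1 - config$clusterFormingP / 2, df = n - 1)
  tObs <- pairedT(d, rep(1, n), SS)
  obs <- list()
  for (pol in c(1, -1)) {
    flag <- pol * tObs > tcrit
    if (!any(flag)) next
    lab <- labelClusters(array(flag, shape))
    for (k in seq_len(max(lab))) {
      mask <- array(lab == k, shape)
      obs[[length(obs) + 1L]] <-
        list(mask = mask, stat = sum(tObs[mask]), polarity = pol)
    }
  }
  if (!length(obs)) return(list())
  set.seed(config$seed)
  null <- vapply(seq_len(config$nPerm), function(p) {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    maxClusterMass(pairedT(d, signs, SS), shape, tcrit)
  }, numeric(1))
  res <- lapply(obs, function(cl) {
    p <- (1 + sum(null >= abs(cl$stat))) / (config$nPerm + 1)
    new("ClusterResult", mask = cl$mask, clusterStat = cl$stat,
        pValue = p, polarity = cl$polarity)
  })
  res[order(vapply(res, function(cl) cl@pValue, numeric(1)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Union mask of significant positive clusters
#'
#' Combines the masks of all clusters with \code{pValue < alpha} and
#' positive polarity (real > surrogate) into one boolean mask, the mask
#' consumed by \code{\link{bandPeak}} / \code{\link{pacPeak}}.
#'
#' @param clusters list of \linkS4class{ClusterResult}
#' @param alpha significance level (default 0.05)
#' @param dim shape of the returned mask when \code{clusters} is empty
#' @return logical vector or matrix; all-FALSE when nothing is significant
#' @export
significantMask <- function(clusters, alpha = 0.05, dim = NULL) {
  if (!length(clusters)) {
    stopIfNot(!is.null(dim),
              "dim must be given when the cluster list is empty")
    return(array(FALSE, dim))
  }
  mask <- array(FALSE, dim(clusters[[1]]@mask) %||%
                         length(clusters[[1]]@mask))
  for (cl in clusters)
    if (cl@pValue < alpha && cl@polarity > 0) mask <- mask | cl@mask
  mask
}

#' Cluster summary table
#'
#' Tidy summary of a cluster list: extent, mass, p value, polarity and
#' bounding frequencies on the supplied grids.
#'
#' @param clusters list of \linkS4class{ClusterResult}
#' @param freqs frequency grid for 1D masks, or list(phase, amp) for 2D
#' @return data.frame with one row per cluster
#' @export
clusterSummary <- function(clusters, freqs = NULL) {
  if (!length(clusters))
    return(data.frame(cluster_id = integer(0), p_value = numeric(0),
                      extent = integer(0), polarity = numeric(0)))
  rows <- lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    out <- data.frame(cluster_id = k, p_value = cl@pValue,
                      extent = sum(cl@mask), mass = cl@clusterStat,
                      polarity = cl@polarity)
    if (!is.null(freqs)) {
      if (is.matrix(cl@mask)) {
        idx <- which(cl@mask, arr.ind = TRUE)
        out$phase_lo <- freqs$phase[min(idx[, 1])]
        out$phase_hi <- freqs$phase[max(idx[, 1])]
        out$amp_lo <- freqs$amp[min(idx[, 2])]
        out$amp_hi <- freqs$amp[max(idx[, 2])]
      } else {
        idx <- which(cl@mask)
        out$freq_lo <- freqs[min(idx)]
        out$freq_hi <- freqs[max(idx)]
      }
    }
    out
  })
  do.call(rbind, rows)
}
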