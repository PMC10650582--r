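#' Spectral PCA denoising
#'
#' Treats each masked voxel's Z-spectrum as an observation, mean-centers
#' along the offset axis, eigendecomposes the offset-offset covariance
#' and reconstructs the data from the `k` leading principal components;
#' trailing components carry mostly noise. `k` is chosen by one of three
#' component-selection criteria (or forced with `k_override`):
#'
#' * `median`: keep eigenvalues above twice the median nonzero eigenvalue.
#' * `malinowski`: minimize the empirical indicator function
#'   `IND(n) = RE(n) / (dyn - n)^2` with
#'   `RE(n) = sqrt(sum_{j>n} lambda_j / (n_voxels (dyn - n)))`.
#' * `nelson`: keep leading components whose loading vector has lag-1
#'   autocorrelation above 0.5, stopping at the first failure.
#'
#' The criterion formulas are reconstructions of the classical chemometric
#' rules; the benchmark naming convention is `PCA-Median` etc. Background
#' voxels pass through untouched.
#'
#' @param vol a [cest_volume()] with at least 3 offsets.
#' @param criterion `"median"`, `"nelson"` or `"malinowski"`.
#' @param k_override optional fixed component count in `[1, dyn]`.
#' @return list with the denoised `volume` and the retained component
#'   count `k`.
#' @examples
#' v <- cest_volume(array(runif(8 * 8 * 10), c(8, 8, 10)), seq(-2, 2, length.out = 10))
#' out <- pca_denoise(v, "median")
#' out$k
#' @export
pca_denoise <- function(vol, criterion = c("median", "nelson", "malinowski"),
                        k_override = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(vol, "cest_volume"), vol$dyn >= 3)
  if (!any(vol$mask)) stop("empty mask")
  d <- dim(vol$data)
  X <- matrix(vol$data, d[1] * d[2], d[3])[as.vector(vol$mask), , drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  lam_cov <- sv$d^2 / max(1, nrow(X) - 1)   # covariance eigenvalues
  k <- if (!is.null(k_override)) {
    stopifnot(k_override >= 1, k_override <= vol$dyn)
    as.integer(k_override)
  } else switch(criterion,
    median = select_k_median(lam_cov),
    malinowski = select_k_malinowski(sv$d^2, nrow(X), vol$dyn),
    nelson = select_k_nelson(sv$v))
  if (k == 0) {
    warning("criterion retained 0 components; clamping to 1")
    k <- 1L
  }
  k <- min(k, length(sv$d))
  Xk <- sv$u[, 1:k, drop = FALSE] %*%
    (sv$d[1:k] * t(sv$v[, 1:k, drop = FALSE]))
  Xk <- sweep(Xk, 2, mu, `+`)
  out <- matrix(vol$data, d[1] * d[2], d[3])
  out[as.vector(vol$mask), ] <- Xk
  list(volume = update_data(vol, array(out, d)), k = k)
}

#' Component-selection criteria for spectral PCA
#'
#' See [pca_denoise()] for the definitions.
#'
#' @param eigvals eigenvalues in descending order (`select_k_median`
#'   expects covariance-scale eigenvalues; `select_k_malinowski` the raw
#'   sums of squares, i.e. squared singular values).
#' @param n_voxels,dyn data-matrix dimensions for the Malinowski
#'   indicator.
#' @param components `dyn x r` loading matrix (columns = components) for
#'   the Nelson autocorrelation rule.
#' @return retained component count (possibly 0; [pca_denoise()] clamps).
#' @export
select_k_median <- function(eigvals) {
  nz <- eigvals[eigvals > max(eigvals) * 1e-12]
  if (!length(nz)) return(0L)
  sum(eigvals > 2 * stats::median(nz))
}

#' @rdname select_k_median
#' @export
select_k_malinowski <- function(eigvals, n_voxels, dyn) {
  stopifnot(length(eigvals) >= 2)
  ns <- seq_len(min(dyn, length(eigvals)) - 1L)
  ind <- vapply(ns, function(n) {
    re <- sqrt(sum(eigvals[(n + 1):length(eigvals)]) / (n_voxels * (dyn - n)))
    re / (dyn - n)^2
  }, 0)
  ns[which.min(ind)]   # which.min ties break toward smaller n
}

#' @rdname select_k_median
#' @export
select_k_nelson <- function(components, threshold = 0.5) {
  k <- 0L
  for (c in seq_len(ncol(components))) {
    v <- components[, c]
    v <- v - mean(v)
    den <- sum(v^2)
    ac <- if (den == 0) 0 else sum(head(v, -1) * tail(v, -1)) / den
    if (ac > threshold) k <- k + 1L else break
  }
  k
}

#' @rdname select_k_median
#' @param threshold lag-1 autocorrelation cutoff for the Nelson rule.
#' @name select_k_nelson
NULL
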