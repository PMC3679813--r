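#' Bayesian Information Criterion for a K-component fit
#'
#' `BIC = -2 * loglik + C_K * log(N * D)` with `C_K = K * (D + 1) - 1`
#' free parameters (K - 1 mixing proportions plus K x D occurrence
#' probabilities) and `N * D` binary data points. Natural logarithm.
#' Smaller is better.
#'
#' @param loglik Observed-data log-likelihood of the fit.
#' @param K Number of clusters.
#' @param D Number of tracks.
#' @param N Number of regions.
#' @return Scalar BIC.
#' @examples
#' bic(-100, K = 2, D = 3, N = 10) # 200 + 7 * log(30)
#' @export
bic <- function(loglik, K, D, N) {
  stopifnot(K >= 1, D >= 1, N >= 1, is.finite(loglik))
  -2 * loglik + (K * (D + 1) - 1) * log(N * D)
}

#' Elbow of a log-likelihood-versus-K curve
#'
#' The log-likelihood always increases with K; the elbow is the interior
#' K after which the gains flatten. We formalize the usual visual rule as
#' the K maximizing the negative discrete second difference
#' `-(L[K+1] - 2 L[K] + L[K-1])`, i.e. the sharpest concave kink. Ties
#' (including an exactly linear curve) resolve to the smallest K with a
#' `"degenerate"` attribute set; fewer than 3 points returns the smallest
#' K, also flagged degenerate. A non-monotone curve (possible when
#' independent fits land in local optima) still yields an answer but
#' raises a warning.
#'
#' @param loglik Numeric vector of per-K log-likelihoods.
#' @param k_values The K each entry corresponds to (consecutive
#'   integers); defaults to `seq_along(loglik)`.
#' @return The suggested K (integer) with attribute `"degenerate"`.
#' @examples
#' elbow_k(c(-1000, -200, -190, -185), 1:4) # kink at K = 2
#' @export
elbow_k <- function(loglik, k_values = seq_along(loglik)) {
  stopifnot(length(loglik) == length(k_values))
  n <- length(loglik)
  if (n < 3L) {
    out <- as.integer(k_values[1L])
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (any(diff(loglik) < -1e-6)) {
    warning("log-likelihood curve is not monotone in K; some fits ",
      "probably reached local optima")
  }
  curv <- -(loglik[3:n] - 2 * loglik[2:(n - 1)] + loglik[1:(n - 2)])
  j <- which.max(curv) # first max: smaller-K tie-break
  out <- as.integer(k_values[j + 1L])
  attr(out, "degenerate") <- diff(range(curv)) <=
    1e-12 * max(1, max(abs(curv)))
  out
}

#' Fit the mixture over a range of K
#'
#' Fits each K independently (fresh K-means initialization, seed derived
#' from `seed`) and records the log-likelihood and BIC curves together
#' with two suggestions: the BIC minimizer and the elbow of the
#' log-likelihood curve. With large N, BIC often keeps decreasing with K;
#' the elbow is then the more interpretable choice, and both curves are
#' always exposed so the user can override either.
#'
#' @param Y Binary overlap matrix.
#' @param k_min,k_max Range of K to scan, `1 <= k_min <= k_max <= N`.
#' @param seed Integer seed; the fit at K uses `seed + 97 * K`.
#' @param tol,max_iter,n_restarts Passed to [fit_em()].
#' @return An object of class `bernmix_scan`: list with `k_values`,
#'   `fits`, `loglik`, `bic`, `suggested_k_bic`, `suggested_k_elbow`,
#'   `elbow_degenerate`.
#' @examples
#' sim <- simulate_matrix(sim_params(K = 2, D = 4), n = 300, seed = 7)
#' scan <- scan_k(sim$Y, k_min = 1, k_max = 4, seed = 7)
#' scan$suggested_k_elbow
#' @export
scan_k <- function(Y, k_min = 1, k_max, seed = 1L, tol = 1e-6,
                   max_iter = 1000, n_restarts = 10) {
  Y <- as_overlap_matrix(Y)
  if (!(1 <= k_min && k_min <= k_max && k_max <= nrow(Y))) {
    stop("need 1 <= k_min <= k_max <= N")
  }
  ks <- as.integer(k_min:k_max)
  fits <- vector("list", length(ks))
  names(fits) <- sprintf("K%d", ks)
  for (j in seq_along(ks)) {
    fits[[j]] <- tryCatch(
      fit_em(Y, ks[j], tol = tol, max_iter = max_iter,
        seed = seed + 97L * ks[j], n_restarts = n_restarts),
      error = function(e) e
    )
  }
  ok <- vapply(fits, inherits, logical(1L), "bernmix_fit")
  if (any(!ok)) {
    warning("fit failed for K = ",
      paste(ks[!ok], collapse = ", "),
      "; recorded as missing points")
  }
  ll <- ifelse(ok, vapply(fits, function(f) {
    if (inherits(f, "bernmix_fit")) f$loglik else NA_real_
  }, numeric(1L)), NA_real_)
  bc <- ifelse(ok, vapply(fits, function(f) {
    if (inherits(f, "bernmix_fit")) f$bic else NA_real_
  }, numeric(1L)), NA_real_)

  k_bic <- if (any(ok)) ks[which.min(bc)] else NA_integer_
  if (sum(ok) >= 1L) {
    kel <- elbow_k(ll[ok], ks[ok])
  } else {
    kel <- structure(NA_integer_, degenerate = TRUE)
  }

  structure(
    list(
      k_values = ks,
      fits = fits,
      loglik = stats::setNames(ll, names(fits)),
      bic = stats::setNames(bc, names(fits)),
      suggested_k_bic = k_bic,
      suggested_k_elbow = as.integer(kel),
      elbow_degenerate = isTRUE(attr(kel, "degenerate")),
      seed = seed
    ),
    class = "bernmix_scan"
  )
}

#' @export
print.bernmix_scan <- function(x, ...) {
  cat(sprintf("Model scan over K = %d..%d\n",
    min(x$k_values), max(x$k_values)))
  print(as.data.frame(x), row.names = FALSE, ...)
  cat(sprintf("suggested K: BIC minimum = %s, log-likelihood elbow = %s%s\n",
    x$suggested_k_bic, x$suggested_k_elbow,
    if (x$elbow_degenerate) " (degenerate elbow)" else ""))
  invisible(x)
}

#' @export
as.data.frame.bernmix_scan <- function(x, ...) {
  ok <- vapply(x$fits, inherits, logical(1L), "bernmix_fit")
  data.frame(
    K = x$k_values,
    loglik = unname(x$loglik),
    bic = unname(x$bic),
    n_iter = ifelse(ok, vapply(x$fits, function(f) {
      if (inherits(f, "bernmix_fit")) f$n_iter else NA_integer_
    }, integer(1L)), NA_integer_),
    converged = ifelse(ok, vapply(x$fits, function(f) {
      if (inherits(f, "bernmix_fit")) f$converged else NA
    }, logical(1L)), NA)
  )
}

#' Plot log-likelihood and BIC against K
#'
#' @param x A `bernmix_scan`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bernmix_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$k_values, x$loglik, type = "b",
    xlab = "K", ylab = "log-likelihood", ...)
  graphics::abline(v = x$suggested_k_elbow, lty = 2)
  graphics::plot(x$k_values, x$bic, type = "b",
    xlab = "K", ylab = "BIC", ...)
  graphics::abline(v = x$suggested_k_bic, lty = 2)
  invisible(x)
}
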