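#' Bernoulli-mixture parameters
#'
#' Container for the parameters of a K-component product-of-Bernoulli
#' mixture: mixing proportions `pi` (cluster size fractions) and the K x D
#' occurrence-probability matrix `q`, where `q[k, d]` is the probability
#' that track `d` occurs in a region of cluster `k`.
#'
#' Probabilities may be exactly 0 or 1 (printed parameter tables often
#' are); every likelihood computation clamps them to `[1e-6, 1 - 1e-6]`
#' internally so log terms stay finite, and estimation routines store
#' clamped values.
#'
#' @param pi Numeric vector of K non-negative mixing proportions; must sum
#'   to 1 (renormalized if within 1e-8, rejected otherwise).
#' @param q K x D numeric matrix of occurrence probabilities in `[0, 1]`.
#' @param track_ids Column labels for `q`; defaults to existing colnames.
#' @param clamp If `TRUE`, store `q` clamped away from 0/1 (used by the
#'   estimation routines).
#' @return An object of class `mixture_params` with elements `pi`, `q`,
#'   `K`, `D`.
#' @examples
#' mixture_params(c(0.6, 0.4), rbind(c(0.9, 0.1), c(0.1, 0.9)))
#' @export
mixture_params <- function(pi, q, track_ids = NULL, clamp = FALSE) {
  pi <- as.numeric(pi)
  q <- as.matrix(q)
  storage.mode(q) <- "double"
  K <- length(pi)
  if (K < 1L) stop("need at least one component")
  if (nrow(q) != K) stop("nrow(q) must equal length(pi)")
  if (any(pi < 0) || anyNA(pi)) stop("mixing proportions must be >= 0")
  if (abs(sum(pi) - 1) > 1e-8) stop("mixing proportions must sum to 1")
  pi <- pi / sum(pi)
  if (anyNA(q) || any(q < 0) || any(q > 1)) {
    stop("occurrence probabilities must lie in [0, 1]")
  }
  if (clamp) q <- clamp_q(q)
  if (!is.null(track_ids)) {
    stopifnot(length(track_ids) == ncol(q))
    colnames(q) <- track_ids
  } else if (is.null(colnames(q))) {
    colnames(q) <- sprintf("track_%d", seq_len(ncol(q)))
  }
  rownames(q) <- NULL
  structure(
    list(pi = pi, q = q, K = K, D = ncol(q)),
    class = "mixture_params"
  )
}

#' @export
print.mixture_params <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Bernoulli mixture parameters: K = %d components, D = %d tracks\n",
    x$K, x$D
  ))
  tab <- rbind(pi = x$pi, t(x$q))
  colnames(tab) <- sprintf("cluster_%d", seq_len(x$K))
  print(round(tab, digits), ...)
  invisible(x)
}

# N x K matrix of per-component log-likelihoods log P(Y_i | Z_i = k).
# q is clamped here so stored boundary values never produce log(0).
log_component_lik <- function(Y, params) {
  q <- clamp_q(params$q)
  Y %*% t(log(q)) + (1 - Y) %*% t(log1p(-q))
}

#' Observed-data log-likelihood
#'
#' The marginal log-likelihood
#' `sum_i log sum_k pi_k prod_d q_kd^Y_id (1 - q_kd)^(1 - Y_id)`,
#' evaluated in log space with a log-sum-exp over components. This is the
#' quantity EM monotonically increases and the one BIC penalizes.
#'
#' @param Y Binary overlap matrix (N x D).
#' @param params A [mixture_params()] object with matching `D`.
#' @return Scalar log-likelihood.
#' @export
observed_loglik <- function(Y, params) {
  Y <- as_overlap_matrix(Y)
  stopifnot(ncol(Y) == params$D)
  lp <- sweep(log_component_lik(Y, params), 2L, log(params$pi), "+")
  sum(row_log_sum_exp(lp))
}

#' E-step: posterior cluster responsibilities
#'
#' Computes `mu[i, k] = P(Z_i = k | Y_i, params)` by Bayes' rule,
#' `pi_k P(Y_i | k) / sum_k' pi_k' P(Y_i | k')`, in log space followed by
#' a softmax so that extreme probabilities cannot underflow to `NaN`.
#'
#' @inheritParams observed_loglik
#' @return N x K matrix of responsibilities; rows sum to 1.
#' @export
e_step <- function(Y, params) {
  Y <- as_overlap_matrix(Y)
  stopifnot(ncol(Y) == params$D)
  lp <- sweep(log_component_lik(Y, params), 2L, log(params$pi), "+")
  mx <- apply(lp, 1L, max)
  w <- exp(lp - mx)
  mu <- w / rowSums(w)
  dimnames(mu) <- list(rownames(Y), sprintf("cluster_%d", seq_len(params$K)))
  mu
}

#' M-step: maximize the expected complete-data log-likelihood
#'
#' Closed-form updates: `pi_k = sum_i mu_ik / N` and
#' `q_kd = sum_i mu_ik Y_id / sum_i mu_ik`, with `q` clamped to
#' `[1e-6, 1 - 1e-6]`. A component whose total responsibility vanishes is
#' reset to `q = 0.5` and flagged via the `"degenerate"` attribute.
#'
#' @param Y Binary overlap matrix (N x D).
#' @param mu N x K responsibility matrix with rows summing to 1.
#' @return A [mixture_params()] object; `attr(., "degenerate")` is `TRUE`
#'   when an empty component was reset.
#' @export
m_step <- function(Y, mu) {
  Y <- as_overlap_matrix(Y)
  mu <- as.matrix(mu)
  stopifnot(nrow(mu) == nrow(Y))
  if (max(abs(rowSums(mu) - 1)) > 1e-6) {
    stop("responsibility rows must sum to 1")
  }
  N <- nrow(Y)
  nk <- colSums(mu)
  pi <- nk / N
  q <- crossprod(mu, Y) # K x D, = t(mu) %*% Y
  empty <- nk < 1e-12
  if (any(!empty)) {
    q[!empty, ] <- q[!empty, , drop = FALSE] / nk[!empty]
  }
  if (any(empty)) {
    q[empty, ] <- 0.5
    warning("empty mixture component(s) reset to q = 0.5: ",
      paste(which(empty), collapse = ", "))
  }
  out <- mixture_params(pi / sum(pi), q, track_ids = colnames(Y),
    clamp = TRUE)
  attr(out, "degenerate") <- any(empty)
  out
}

#' K-means starting values for EM
#'
#' Runs K-means (Euclidean distance on the raw 0/1 rows) `n_restarts`
#' times with distinct sub-seeds and keeps the run with the smallest
#' total within-cluster sum of squares. Cluster centers become the
#' initial `q` (clamped) and relative cluster sizes the initial `pi`.
#'
#' @param Y Binary overlap matrix.
#' @param K Requested number of clusters. When `Y` has fewer distinct
#'   rows than `K`, the effective `K` is reduced to that number with a
#'   warning.
#' @param n_restarts Number of K-means restarts (default 10).
#' @param seed Integer seed; restart `r` uses `seed + r - 1`.
#' @return A [mixture_params()] object; `attr(., "k_reduced")` is `TRUE`
#'   when `K` had to be reduced.
#' @export
kmeans_init <- function(Y, K, n_restarts = 10, seed = 1L) {
  Y <- as_overlap_matrix(Y)
  if (K < 1L) stop("K must be >= 1")
  uy <- unique(Y)
  k_eff <- min(K, nrow(uy))
  reduced <- k_eff < K
  if (reduced) {
    warning("only ", nrow(uy), " distinct rows; reducing K from ", K,
      " to ", k_eff)
  }
  if (k_eff == 1L) {
    out <- mixture_params(1, matrix(colMeans(Y), nrow = 1L),
      track_ids = colnames(Y), clamp = TRUE)
    attr(out, "k_reduced") <- reduced
    return(out)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- withr::with_seed(seed + r - 1L, tryCatch(
      {
        centers <- uy[sample.int(nrow(uy), k_eff), , drop = FALSE]
        stats::kmeans(Y, centers = centers, iter.max = 100L)
      },
      error = function(e) NULL # rare empty-cluster failures: skip restart
    ))
    if (!is.null(km) &&
      (is.null(best) || km$tot.withinss < best$tot.withinss)) {
      best <- km
    }
  }
  if (is.null(best)) {
    # every restart failed (pathological); fall back to distinct rows
    centers <- uy[seq_len(k_eff), , drop = FALSE]
    pi <- rep(1 / k_eff, k_eff)
  } else {
    centers <- best$centers
    pi <- best$size / nrow(Y)
  }
  out <- mixture_params(pi, centers, track_ids = colnames(Y), clamp = TRUE)
  attr(out, "k_reduced") <- reduced
  out
}

#' Fit the Bernoulli mixture by EM
#'
#' Alternates [e_step()] and [m_step()] from K-means starting values
#' (or a user-supplied `mixture_params`) until the relative change in the
#' observed-data log-likelihood falls below `tol` or `max_iter` is
#' reached. The log-likelihood trace is monotone non-decreasing up to
#' numerical noise. Components are relabelled in decreasing `pi` order
#' before return; hard assignments take the maximum-responsibility
#' cluster, ties resolved toward the lowest cluster index.
#'
#' @param Y Binary overlap matrix (N x D), e.g. from [overlap_matrix()]
#'   or [simulate_matrix()].
#' @param K Number of clusters, `1 <= K <= N`.
#' @param init `"kmeans"` (default) or a [mixture_params()] object.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param seed Integer seed controlling the K-means initialization.
#' @param n_restarts K-means restarts passed to [kmeans_init()].
#' @return An object of class `bernmix_fit`: list with `params`,
#'   `responsibilities` (N x K), `loglik_trace`, `loglik`, `bic`,
#'   `assignments`, `converged`, `n_iter`, `degenerate`, and the
#'   dimensions `N`, `D`, `K`.
#' @examples
#' sim <- simulate_matrix(sim_params(K = 2, D = 4), n = 200, seed = 1)
#' fit <- fit_em(sim$Y, K = 2, seed = 1)
#' fit$params
#' @export
fit_em <- function(Y, K, init = "kmeans", tol = 1e-6, max_iter = 1000,
                   seed = 1L, n_restarts = 10) {
  Y <- as_overlap_matrix(Y)
  N <- nrow(Y)
  D <- ncol(Y)
  if (K < 1L || K > N) stop("K must satisfy 1 <= K <= N")
  if (identical(init, "kmeans")) {
    params <- kmeans_init(Y, K, n_restarts = n_restarts, seed = seed)
  } else {
    stopifnot(inherits(init, "mixture_params"), init$D == D)
    params <- init
  }
  K <- params$K # may have been reduced for too few distinct rows

  trace <- numeric(0L)
  degenerate <- FALSE
  converged <- FALSE
  ll_old <- -Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu <- e_step(Y, params)
    params <- withCallingHandlers(
      m_step(Y, mu),
      warning = function(w) {
        if (grepl("empty mixture component", conditionMessage(w))) {
          degenerate <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    ll <- observed_loglik(Y, params)
    if (!is.finite(ll)) {
      stop("non-finite log-likelihood at EM iteration ", it)
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
      abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  mu <- e_step(Y, params)
  ord <- order(params$pi, decreasing = TRUE)
  params <- mixture_params(params$pi[ord], params$q[ord, , drop = FALSE],
    track_ids = colnames(Y))
  mu <- mu[, ord, drop = FALSE]
  colnames(mu) <- sprintf("cluster_%d", seq_len(K))
  ll <- trace[length(trace)]

  structure(
    list(
      params = params,
      responsibilities = mu,
      loglik_trace = trace,
      loglik = ll,
      bic = bic(ll, K, D, N),
      assignments = max.col(mu, ties.method = "first"),
      converged = converged,
      n_iter = it,
      degenerate = degenerate,
      N = N, D = D, K = K,
      seed = seed
    ),
    class = "bernmix_fit"
  )
}

#' @export
print.bernmix_fit <- function(x, ...) {
  cat(sprintf(
    "Bernoulli mixture fit: N = %d regions, D = %d tracks, K = %d clusters\n",
    x$N, x$D, x$K
  ))
  cat(sprintf(
    "log-likelihood = %.3f, BIC = %.3f, %d iterations (%s)%s\n",
    x$loglik, x$bic, x$n_iter,
    if (x$converged) "converged" else "max_iter reached",
    if (x$degenerate) " [degenerate component encountered]" else ""
  ))
  cat("cluster sizes:",
    paste(sprintf("%.3f", x$params$pi), collapse = " "), "\n")
  invisible(x)
}

#' Export fitted parameters as a tab-separated table
#'
#' Layout mirrors the usual published presentation: columns are clusters,
#' the first row is `pi` and subsequent rows are the per-track occurrence
#' probabilities.
#'
#' @param params A [mixture_params()] object (or a `bernmix_fit`, whose
#'   `$params` is used).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_params <- function(params, path) {
  if (inherits(params, "bernmix_fit")) params <- params$params
  stopifnot(inherits(params, "mixture_params"))
  tab <- rbind(pi = params$pi, t(params$q))
  df <- data.frame(param = rownames(tab), tab, check.names = FALSE,
    stringsAsFactors = FALSE)
  colnames(df) <- c("param", sprintf("cluster_%d", seq_len(params$K)))
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a parameter table written by [write_params()]
#'
#' Also reads hand-made tables in the same layout (first row `pi`, one
#' row per track). Probabilities are clamped to `[1e-6, 1 - 1e-6]` on
#' read so that queries on tables printed with boundary values (0.00 /
#' 1.00) are well defined and reproducible, and a `pi` row that misses 1
#' by up to 0.05 (printed rounding) is renormalized.
#'
#' @param path Path to the TSV.
#' @return A [mixture_params()] object.
#' @export
read_params <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
    stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) < 2L) {
    stop("parameter table needs a label column, >= 1 cluster column, ",
      "a pi row and >= 1 track row")
  }
  labels <- df[[1L]]
  if (tolower(labels[1L]) != "pi") {
    stop("first row of a parameter table must be 'pi'")
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  pi <- vals[1L, ]
  # published tables are rounded (often to 2 decimals), so pi may miss 1
  # by a little; renormalize, but refuse grossly inconsistent tables
  if (abs(sum(pi) - 1) > 0.05) {
    stop("pi row sums to ", sum(pi), "; not a valid parameter table")
  }
  mixture_params(
    pi = pi / sum(pi),
    q = t(vals[-1L, , drop = FALSE]),
    track_ids = labels[-1L],
    clamp = TRUE
  )
}
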