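# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no log-space tricks, no interval indexes) so they can
# stand as references.

# Marginal log-likelihood by direct arithmetic: sum_i log sum_k pi_k
# prod_d q^y (1-q)^(1-y), with explicit loops.
oracle_loglik_direct <- function(Y, pi, q) {
  pi <- unname(pi)
  q <- unname(q)
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    tot <- 0
    for (k in seq_along(pi)) {
      lik <- pi[k]
      for (d in seq_len(ncol(Y))) {
        lik <- lik * if (Y[i, d] == 1) q[k, d] else 1 - q[k, d]
      }
      tot <- tot + lik
    }
    ll <- ll + log(tot)
  }
  ll
}

# Marginal likelihood via full enumeration of all K^N latent assignment
# vectors: sum_z prod_i pi_{z_i} P(Y_i | z_i). Feasible for N <= 8 and
# small K only.
oracle_loglik_enum <- function(Y, pi, q) {
  pi <- unname(pi)
  q <- unname(q)
  N <- nrow(Y)
  K <- length(pi)
  grid <- expand.grid(rep(list(seq_len(K)), N))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    z <- as.integer(grid[r, ])
    lik <- 1
    for (i in seq_len(N)) {
      lik <- lik * pi[z[i]]
      for (d in seq_len(ncol(Y))) {
        lik <- lik *
          if (Y[i, d] == 1) q[z[i], d] else 1 - q[z[i], d]
      }
    }
    total <- total + lik
  }
  log(total)
}

# Row-wise Bayes rule with plain arithmetic.
oracle_estep <- function(Y, pi, q) {
  pi <- unname(pi)
  q <- unname(q)
  N <- nrow(Y)
  K <- length(pi)
  mu <- matrix(0, N, K)
  for (i in seq_len(N)) {
    for (k in seq_len(K)) {
      lik <- pi[k]
      for (d in seq_len(ncol(Y))) {
        lik <- lik * if (Y[i, d] == 1) q[k, d] else 1 - q[k, d]
      }
      mu[i, k] <- lik
    }
    mu[i, ] <- mu[i, ] / sum(mu[i, ])
  }
  mu
}

# Expected complete-data log-likelihood (the EM Q-function) for the
# m_step perturbation check; clamps q only to keep logs finite.
oracle_qfun <- function(Y, mu, pi, q) {
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  pi <- pmax(pi, 1e-300)
  lq <- Y %*% t(log(q)) + (1 - Y) %*% t(log(1 - q))
  sum(mu * sweep(lq, 2, log(pi), "+"))
}

# O(n^2) pairwise merge fixpoint on a data.frame of BED intervals
# (chrom, start, end; half-open). Merges overlapping OR abutting pairs
# until no pair merges.
oracle_merge <- function(df) {
  repeat {
    merged <- FALSE
    i <- 1
    while (i <= nrow(df)) {
      j <- i + 1
      while (j <= nrow(df)) {
        if (df$chrom[i] == df$chrom[j] &&
          df$start[i] <= df$end[j] && df$start[j] <= df$end[i]) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, , drop = FALSE]
          merged <- TRUE
        } else {
          j <- j + 1
        }
      }
      i <- i + 1
    }
    if (!merged) break
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# All-pairs half-open intersection test: does region (chrom, s, e) hit
# any interval of the track data.frame?
oracle_overlap <- function(regions_df, track_df) {
  vapply(seq_len(nrow(regions_df)), function(i) {
    any(track_df$chrom == regions_df$chrom[i] &
      track_df$start < regions_df$end[i] &
      regions_df$start[i] < track_df$end)
  }, logical(1))
}

# Monte-Carlo joint occurrence probability: sample cluster labels then
# the constrained tracks only.
oracle_mc_joint <- function(pi, q, idx, val, n_draws, seed) {
  withr::with_seed(seed, {
    z <- sample.int(length(pi), n_draws, replace = TRUE, prob = pi)
    hit <- rep(TRUE, n_draws)
    for (j in seq_along(idx)) {
      y <- stats::rbinom(n_draws, 1, q[z, idx[j]])
      hit <- hit & (y == val[j])
    }
    mean(hit)
  })
}

# Small helpers for building fixtures.
write_bed_lines <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

random_intervals_df <- function(n, chroms = c("chr1", "chr2"),
                                span = 5000, max_len = 120) {
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = sample.int(span, n, replace = TRUE) - 1L
  ) -> df
  df$end <- df$start + sample.int(max_len, n, replace = TRUE)
  df
}

df_to_granges <- function(df) {
  gr <- GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(start = df$start + 1, end = df$end)
  )
  gr
}

random_params <- function(K, D, seed = NULL) {
  gen <- function() {
    pi <- stats::runif(K, 0.2, 1)
    mixture_params(pi / sum(pi),
      matrix(stats::runif(K * D, 0.05, 0.95), K, D))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
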