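#' Block-structured simulation parameters
#'
#' Builds a well-separated ground-truth parameter set for simulation
#' studies: every track has a low baseline occurrence probability and
#' component `k` turns its own disjoint block of `floor(D / K)`
#' consecutive tracks "on" at a high probability (any leftover tracks
#' stay at baseline). All components are exchangeable — equally strong
#' and pairwise equidistant, differing in `2 * floor(D / K)` coordinates
#' by `high - base` (0.8 with the defaults) — which is the appropriate
#' geometry for parameter- and model-order-recovery studies. With
#' uniform mixing proportions this emulates the typical structure of
#' co-binding data (clusters dominated by a subset of factors) while
#' staying fully synthetic.
#'
#' @param K Number of components.
#' @param D Number of tracks (default 10); must be >= K. Components get
#'   `floor(D / K)` signature tracks each, so choose `D >= 2 * K` when
#'   every component should carry a multi-track signature.
#' @param base Baseline occurrence probability (default 0.1).
#' @param high Within-block occurrence probability (default 0.9).
#' @param pi Mixing proportions (default uniform).
#' @return A [mixture_params()] object.
#' @examples
#' sim_params(K = 3, D = 10)$q
#' @export
sim_params <- function(K, D = 10, base = 0.1, high = 0.9,
                       pi = rep(1 / K, K)) {
  stopifnot(K >= 1, D >= K, base >= 0, high <= 1, base < high)
  w <- max(1L, floor(D / K))
  q <- matrix(base, nrow = K, ncol = D)
  for (k in seq_len(K)) {
    q[k, ((k - 1L) * w + 1L):(k * w)] <- high
  }
  mixture_params(pi, q, track_ids = sprintf("track_%d", seq_len(D)))
}

#' Simulate an overlap matrix from known parameters
#'
#' Draws `Z_i ~ Categorical(pi)` then, independently across tracks,
#' `Y_id ~ Bernoulli(q[Z_i, d])`. The stored `q` values are used exactly
#' as given (a generative `q = 1` yields a column of ones). Fully
#' deterministic given `seed`.
#'
#' @param params True [mixture_params()].
#' @param n Number of regions to simulate.
#' @param seed Integer seed.
#' @return List with `Y` (n x D binary matrix), `assignments` (true
#'   cluster labels), and `params`.
#' @export
simulate_matrix <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "mixture_params"), n >= 1)
  D <- params$D
  res <- withr::with_seed(as.integer(seed), {
    z <- sample.int(params$K, n, replace = TRUE, prob = params$pi)
    p <- params$q[z, , drop = FALSE]
    Y <- matrix(as.integer(stats::runif(n * D) < p), nrow = n, ncol = D)
    list(z = z, Y = Y)
  })
  dimnames(res$Y) <- list(
    sprintf("region_%d", seq_len(n)),
    colnames(params$q)
  )
  list(Y = res$Y, assignments = res$z, params = params)
}

#' Simulate BED fixtures realizing a known overlap matrix
#'
#' Generates an end-to-end interval-level fixture: `n` non-overlapping
#' regions laid out on synthetic chromosomes, plus one BED file per track
#' containing, for each region with `Y_id = 1`, a random sub-interval of
#' that region (so no track interval can touch any other region). By
#' construction, reading the files back and recomputing the overlap
#' matrix reproduces the simulated `Y` exactly.
#'
#' @param params True [mixture_params()].
#' @param n Number of regions.
#' @param seed Integer seed (drives both the matrix simulation and the
#'   interval placement).
#' @param dir Output directory (created if needed).
#' @param n_chrom Number of synthetic chromosomes (1-9; the cap keeps
#'   lexicographic chromosome order equal to numeric order, so region
#'   layout order survives sorting).
#' @param region_length Region length in bp (>= 50).
#' @param gap Gap between consecutive regions in bp (> 0).
#' @return List with `dir`, `regions_bed`, `track_beds` (named character
#'   vector), `truth_tsv` (region label, true cluster), `Y`,
#'   `assignments`, `params`.
#' @export
simulate_beds <- function(params, n, seed = 1L, dir = tempfile("simbed"),
                          n_chrom = 3, region_length = 500, gap = 500) {
  stopifnot(n >= 1)
  if (n_chrom < 1 || n_chrom > 9) {
    stop("n_chrom must be between 1 and 9")
  }
  region_length <- as.integer(region_length)
  gap <- as.integer(gap)
  if (region_length < 50L) {
    stop("region_length must be >= 50 bp")
  }
  if (gap <= 0L) {
    stop("gap must be positive so regions cannot merge or overlap")
  }
  sim <- simulate_matrix(params, n, seed = seed)
  Y <- sim$Y
  D <- params$D
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  # regions in sorted (chrom, start) order: consecutive block per chromosome
  per_chrom <- ceiling(n / n_chrom)
  chrom <- sprintf("chr%d", ((seq_len(n) - 1L) %/% per_chrom) + 1L)
  within <- (seq_len(n) - 1L) %% per_chrom
  start0 <- within * (region_length + gap) # BED start
  end0 <- start0 + region_length

  regions_bed <- file.path(dir, "regions.bed")
  writeLines(sprintf("%s\t%d\t%d", chrom, start0, end0), regions_bed)

  track_files <- withr::with_seed(as.integer(seed) + 1L, {
    files <- character(D)
    for (d in seq_len(D)) {
      rows <- which(Y[, d] == 1L)
      lines <- character(0L)
      if (length(rows)) {
        off <- sample.int(region_length - 49L, length(rows),
          replace = TRUE) - 1L
        len <- 50L + vapply(region_length - 50L - off, function(m) {
          if (m > 0L) sample.int(m + 1L, 1L) - 1L else 0L
        }, integer(1L))
        lines <- sprintf("%s\t%d\t%d", chrom[rows],
          start0[rows] + off, start0[rows] + off + len)
      }
      f <- file.path(dir, sprintf("track_%02d.bed", d))
      writeLines(lines, f)
      files[d] <- f
    }
    files
  })
  names(track_files) <- colnames(params$q)

  truth_tsv <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(
      region = sprintf("%s:%d-%d", chrom, start0, end0),
      cluster = sim$assignments
    ),
    truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE
  )

  list(
    dir = dir,
    regions_bed = regions_bed,
    track_beds = track_files,
    truth_tsv = truth_tsv,
    Y = Y,
    assignments = sim$assignments,
    params = params
  )
}

#' Match estimated components to the truth by best permutation
#'
#' Mixture components are identified only up to relabelling; to compare
#' an estimate against ground truth, find the component permutation
#' minimizing the mean absolute error of `q` and report the matched
#' errors.
#'
#' @param fitted,truth [mixture_params()] objects with equal `K` and `D`.
#' @return List with `perm` (index into fitted components for each true
#'   component), `q_mae`, `pi_mae`.
#' @export
match_components <- function(fitted, truth) {
  if (inherits(fitted, "bernmix_fit")) fitted <- fitted$params
  stopifnot(fitted$K == truth$K, fitted$D == truth$D)
  K <- truth$K
  # cost[k, j] = mean |q_true[k, ] - q_fit[j, ]|
  cost <- matrix(0, K, K)
  for (k in seq_len(K)) {
    for (j in seq_len(K)) {
      cost[k, j] <- mean(abs(truth$q[k, ] - fitted$q[j, ]))
    }
  }
  if (K <= 7L) {
    perms <- all_permutations(K)
    tot <- vapply(perms, function(p) {
      sum(cost[cbind(seq_len(K), p)])
    }, numeric(1L))
    perm <- perms[[which.min(tot)]]
  } else {
    # greedy matching for large K (adequate for well-separated components)
    perm <- integer(K)
    avail <- seq_len(K)
    for (k in order(apply(cost, 1L, min))) {
      j <- avail[which.min(cost[k, avail])]
      perm[k] <- j
      avail <- setdiff(avail, j)
    }
  }
  list(
    perm = perm,
    q_mae = mean(abs(truth$q - fitted$q[perm, , drop = FALSE])),
    pi_mae = mean(abs(truth$pi - fitted$pi[perm]))
  )
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- all_permutations(K - 1L)
  out <- vector("list", K * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(K)) {
      i <- i + 1L
      out[[i]] <- append(p, K, after = pos - 1L)
    }
  }
  out
}
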