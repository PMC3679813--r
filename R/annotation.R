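#' Cluster-versus-feature overlap with length-based baselines
#'
#' For every (cluster, feature) pair, reports the fraction of the
#' cluster's regions that overlap the feature track, next to the fraction
#' expected by chance for randomly placed regions: the feature's merged
#' covered length divided by the genome length. A cluster whose observed
#' fraction greatly exceeds the expected one is positionally enriched in
#' that feature (e.g. promoter-bound clusters versus a TSS track covering
#' ~1% of the genome).
#'
#' Features are merged (overlap-reduced) internally before their covered
#' length is computed. The expected fraction is a pure function of the
#' feature and `genome_size` and does not depend on the clustering.
#' Feature tracks that overlap each other are allowed (a warning is
#' raised); constructing a mutually exclusive partition such as
#' TSS/TES/exon/intron/intergenic is the caller's responsibility.
#'
#' @param regions `GRanges` of regions of interest, in overlap-matrix row
#'   order.
#' @param assignments Integer cluster labels, one per region (e.g.
#'   `fit$assignments`). Empty clusters between 1 and `max(assignments)`
#'   are reported with `observed = NA`.
#' @param features `GRanges` or named list of `GRanges` feature tracks.
#' @param genome_size Total genome length in bp: a positive scalar or a
#'   named chromosome-length vector (e.g. from [read_chrom_sizes()]),
#'   which is summed. Never inferred from the data.
#' @return A `data.frame` with columns `cluster`, `feature`, `n_regions`,
#'   `observed`, `expected`.
#' @export
cluster_feature_overlap <- function(regions, assignments, features,
                                    genome_size) {
  if (methods::is(features, "GRanges")) {
    features <- list(feature = features)
  }
  assignments <- as.integer(assignments)
  if (length(assignments) != length(regions)) {
    stop("need one cluster assignment per region")
  }
  if (anyNA(assignments) || any(assignments < 1L)) {
    stop("cluster assignments must be positive integers")
  }
  if (is.numeric(genome_size) && length(genome_size) > 1L) {
    genome_size <- sum(genome_size)
  }
  if (!is.numeric(genome_size) || length(genome_size) != 1L ||
    genome_size <= 0) {
    stop("genome_size must be a positive scalar or chromosome-length vector")
  }

  ids <- track_ids(features)
  merged <- lapply(features, function(f) {
    GenomicRanges::reduce(GenomicRanges::granges(f), ignore.strand = TRUE)
  })

  if (length(merged) > 1L) {
    pairs <- utils::combn(length(merged), 2L)
    ov <- apply(pairs, 2L, function(p) {
      any(suppressWarnings(IRanges::overlapsAny(
        merged[[p[1L]]], merged[[p[2L]]], ignore.strand = TRUE)))
    })
    if (any(ov)) {
      warning("feature tracks overlap each other (",
        paste(apply(pairs[, ov, drop = FALSE], 2L, function(p) {
          paste(ids[p], collapse = "/")
        }), collapse = "; "),
        "); observed fractions are computed per feature and need not ",
        "sum to 1")
    }
  }

  expected <- vapply(merged, function(f) {
    sum(as.numeric(GenomicRanges::width(f))) / genome_size
  }, numeric(1L))
  if (any(expected > 1)) {
    warning("merged feature length exceeds genome_size for: ",
      paste(ids[expected > 1], collapse = ", "))
  }

  clusters <- seq_len(max(assignments))
  out <- expand.grid(cluster = clusters, feature = ids,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_regions <- as.vector(table(factor(assignments,
    levels = clusters))[out$cluster])
  out$observed <- NA_real_
  out$expected <- expected[out$feature]
  for (f in seq_along(merged)) {
    hit <- suppressWarnings(IRanges::overlapsAny(
      regions, merged[[f]], ignore.strand = TRUE))
    for (k in clusters) {
      sel <- assignments == k
      if (any(sel)) {
        row <- out$cluster == k & out$feature == ids[f]
        out$observed[row] <- mean(hit[sel])
      }
    }
  }
  rownames(out) <- NULL
  out
}
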