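#' Read a BED track of genomic intervals
#'
#' Parses a BED3+ file into a sorted `GRanges`. Coordinates in the file are
#' 0-based half-open (BED convention); the returned `GRanges` uses the usual
#' 1-based closed convention, so `start(gr) == bed_start + 1` and
#' `end(gr) == bed_end`. Lines starting with `#`, `track` or `browser` and
#' blank lines are skipped. Optional columns 4-6 are kept as `name`, `score`
#' and strand; strand is parsed but ignored by every overlap computation in
#' this package.
#'
#' @param path Path to a BED file (tab- or whitespace-separated).
#' @param track_id Track identifier; defaults to the file basename without
#'   the `.bed` extension.
#' @return A sorted `GRanges` with the track id stored in
#'   `S4Vectors::metadata(x)$track_id`. An empty file yields an empty
#'   `GRanges` with a warning.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr2\t50\t60", "chr1\t10\t20"), bed)
#' read_bed(bed)
#' @export
read_bed <- function(path, track_id = NULL) {
  if (!file.exists(path)) {
    stop("BED file not found: ", path)
  }
  if (is.null(track_id)) {
    track_id <- sub("\\.bed(\\.gz)?$", "", basename(path))
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^\\s*(#|track\\b|browser\\b)", lines)
  idx <- which(keep)

  if (length(idx) == 0L) {
    warning("no interval lines in ", path, "; returning an empty track")
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$track_id <- track_id
    S4Vectors::metadata(gr)$empty <- TRUE
    return(gr)
  }

  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- idx[which(nf < 3L)[1L]]
    stop("line ", bad, " of ", path, ": fewer than 3 fields")
  }

  chrom <- vapply(fields, `[`, character(1L), 1L)
  start_chr <- vapply(fields, `[`, character(1L), 2L)
  end_chr <- vapply(fields, `[`, character(1L), 3L)
  start <- suppressWarnings(as.numeric(start_chr))
  end <- suppressWarnings(as.numeric(end_chr))

  bad_num <- which(is.na(start) | is.na(end) |
    start != floor(start) | end != floor(end))
  if (length(bad_num)) {
    stop("line ", idx[bad_num[1L]], " of ", path,
      ": non-integer coordinates ('", start_chr[bad_num[1L]], "', '",
      end_chr[bad_num[1L]], "')")
  }
  bad_neg <- which(start < 0)
  if (length(bad_neg)) {
    stop("line ", idx[bad_neg[1L]], " of ", path, ": negative start")
  }
  bad_len <- which(end <= start)
  if (length(bad_len)) {
    stop("line ", idx[bad_len[1L]], " of ", path,
      ": end <= start (zero- or negative-length interval)")
  }

  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[4L] %||% NA_character_,
    character(1L)), NA_character_)
  score <- suppressWarnings(as.numeric(
    ifelse(nf >= 5L, vapply(fields, function(f) f[5L] %||% NA_character_,
      character(1L)), NA_character_)
  ))
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[6L] %||% ".",
    character(1L)), ".")
  strand[!strand %in% c("+", "-")] <- "*"

  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand,
    name = name,
    score = score
  )
  gr <- sort_track(gr)
  S4Vectors::metadata(gr)$track_id <- track_id
  S4Vectors::metadata(gr)$empty <- FALSE
  gr
}

#' Read several BED tracks at once
#'
#' @param paths Character vector of BED paths.
#' @param track_ids Optional ids, recycled from file basenames.
#' @return Named list of `GRanges`, one per file.
#' @export
read_tracks <- function(paths, track_ids = NULL) {
  if (is.null(track_ids)) {
    track_ids <- sub("\\.bed(\\.gz)?$", "", basename(paths))
  }
  stopifnot(length(track_ids) == length(paths))
  tracks <- Map(read_bed, paths, track_ids)
  names(tracks) <- track_ids
  tracks
}

# Sort by (chrom, start, end), chromosomes in lexicographic order,
# ignoring strand.
sort_track <- function(gr) {
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  sort(gr, ignore.strand = TRUE)
}

#' Write intervals to a BED file
#'
#' Writes 0-based half-open coordinates. With `name`/`score` supplied (or
#' present as metadata columns) a BED6 file is produced, otherwise BED3.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param name,score Optional per-interval name and score vectors; default
#'   to the `name`/`score` metadata columns when present.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path, name = NULL, score = NULL) {
  mc <- S4Vectors::mcols(gr)
  name <- name %||% if ("name" %in% colnames(mc)) mc$name else NULL
  score <- score %||% if ("score" %in% colnames(mc)) mc$score else NULL
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(name) || !is.null(score)) {
    df$name <- if (is.null(name)) "." else ifelse(is.na(name), ".", name)
    df$score <- if (is.null(score)) 0 else ifelse(is.na(score), 0, score)
    st <- as.character(GenomicRanges::strand(gr))
    df$strand <- ifelse(st == "*", ".", st)
  }
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Merge tracks into a union set of regions of interest
#'
#' Returns the maximal merged intervals of all inputs: intervals that
#' overlap or abut (share a boundary coordinate under the half-open
#' convention) are fused into one region. The result covers exactly the
#' base pairs covered by the inputs and is the default choice of regions
#' of interest when the user does not supply one. Strand is ignored.
#'
#' @param tracks A `GRanges` or list of `GRanges`.
#' @return A sorted, disjoint `GRanges` with
#'   `metadata(x)$source == "union_of_tracks"`.
#' @export
merge_union <- function(tracks) {
  if (methods::is(tracks, "GRanges")) {
    tracks <- list(tracks)
  }
  if (length(tracks) < 1L) {
    stop("at least one track is required")
  }
  grl <- lapply(unname(tracks), function(g) {
    g <- GenomicRanges::granges(g)
    GenomicRanges::strand(g) <- "*"
    g
  })
  all <- suppressWarnings(do.call(c, grl))
  if (length(all) == 0L) {
    stop("no intervals to union")
  }
  out <- GenomicRanges::reduce(sort_track(all), ignore.strand = TRUE)
  out <- sort_track(out)
  S4Vectors::metadata(out)$source <- "union_of_tracks"
  out
}

#' Binary track-by-region overlap matrix
#'
#' Computes the N x D matrix `Y` with `Y[i, d] = 1` iff region `i` shares
#' at least one base pair with some interval of track `d`. Overlap uses
#' the half-open convention: BED intervals `[100, 200)` and `[200, 300)`
#' do not overlap. Strand is ignored. This matrix is the input to
#' [fit_em()].
#'
#' @param regions `GRanges` of regions of interest (row order is kept).
#' @param tracks `GRanges` or list of `GRanges`, one per track.
#' @return Integer matrix of 0/1 with regions as rows (labelled
#'   `chrom:start-end` in BED coordinates) and tracks as columns.
#' @export
overlap_matrix <- function(regions, tracks) {
  if (methods::is(tracks, "GRanges")) {
    tracks <- list(tracks)
  }
  N <- length(regions)
  D <- length(tracks)
  if (N < 1L || D < 1L) {
    stop("need at least one region and one track")
  }
  ids <- track_ids(tracks)
  region_chroms <- unique(as.character(GenomeInfoDb::seqnames(regions)))

  Y <- matrix(0L, nrow = N, ncol = D,
    dimnames = list(region_labels(regions), ids))
  unmatched <- character(0L)
  for (d in seq_len(D)) {
    tr <- tracks[[d]]
    if (length(tr) == 0L) next
    tr_chroms <- unique(as.character(GenomeInfoDb::seqnames(tr)))
    unmatched <- union(unmatched, setdiff(tr_chroms, region_chroms))
    hit <- suppressWarnings(
      IRanges::overlapsAny(regions, tr, ignore.strand = TRUE)
    )
    Y[, d] <- as.integer(hit)
  }
  if (length(unmatched)) {
    warning("track chromosome name(s) absent from the regions of ",
      "interest: ", paste(sort(unmatched), collapse = ", "))
  }
  Y
}

track_ids <- function(tracks) {
  ids <- names(tracks)
  meta_ids <- vapply(tracks, function(g) {
    S4Vectors::metadata(g)$track_id %||% NA_character_
  }, character(1L))
  if (is.null(ids)) ids <- meta_ids
  ids[is.na(ids) | !nzchar(ids)] <-
    meta_ids[is.na(ids) | !nzchar(ids)]
  missing <- is.na(ids) | !nzchar(ids)
  ids[missing] <- sprintf("track_%d", which(missing))
  make.unique(ids)
}

region_labels <- function(regions) {
  sprintf(
    "%s:%d-%d",
    as.character(GenomeInfoDb::seqnames(regions)),
    GenomicRanges::start(regions) - 1L,
    GenomicRanges::end(regions)
  )
}

#' Read a chromosome-sizes file
#'
#' Two whitespace-separated columns: chromosome name and length in bp.
#'
#' @param path Path to the file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path,
    header = FALSE, col.names = c("chrom", "length"),
    colClasses = c("character", "numeric")
  )
  if (any(df$length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  stats::setNames(df$length, df$chrom)
}
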