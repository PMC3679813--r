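#' Joint occurrence probability from fitted parameters
#'
#' The fitted mixture parameters act as sufficient statistics for
#' co-occurrence: because tracks are independent within a cluster, the
#' probability of any presence/absence pattern over a subset of tracks is
#' `sum_k pi_k prod_{d in subset} q_kd^{v_d} (1 - q_kd)^{1 - v_d}`.
#' Unconstrained tracks marginalize out exactly, so no enumeration over
#' all 2^D patterns (and no raw data) is needed.
#'
#' @param params A [mixture_params()] object (or a `bernmix_fit`).
#' @param constraints Named vector of required values in \{0, 1\}; names
#'   are track ids (or, when `q` has no informative colnames, integer
#'   indices as names). E.g. `c(Nanog = 1, Oct4 = 0)`.
#' @return Probability in `[0, 1]`; exact, no sampling.
#' @examples
#' p <- mixture_params(c(0.5, 0.5), rbind(c(0.9, 0.1), c(0.1, 0.9)),
#'   track_ids = c("A", "B"))
#' joint_probability(p, c(A = 1, B = 0))
#' @export
joint_probability <- function(params, constraints) {
  if (inherits(params, "bernmix_fit")) params <- params$params
  stopifnot(inherits(params, "mixture_params"))
  cs <- check_constraints(params, constraints)
  comp <- rep(1, params$K)
  for (j in seq_along(cs$idx)) {
    qd <- params$q[, cs$idx[j]]
    comp <- comp * if (cs$val[j] == 1) qd else 1 - qd
  }
  sum(params$pi * comp)
}

#' Conditional occurrence probability from fitted parameters
#'
#' `P(constraints | given)` computed as the ratio of two joint
#' probabilities. Answers questions such as "what fraction of regions
#' bound by both A and B are also bound by C":
#' `conditional_probability(p, c(C = 1), c(A = 1, B = 1))`.
#'
#' @inheritParams joint_probability
#' @param given Named vector of conditioning values in \{0, 1\}; track
#'   sets of `constraints` and `given` must be disjoint.
#' @return Probability in `[0, 1]`.
#' @export
conditional_probability <- function(params, constraints, given) {
  if (inherits(params, "bernmix_fit")) params <- params$params
  cs <- check_constraints(params, constraints)
  gv <- check_constraints(params, given)
  common <- intersect(names(cs$named), names(gv$named))
  conflict <- common[cs$named[common] != gv$named[common]]
  if (length(conflict)) {
    stop("track(s) constrained and conditioned on with different ",
      "values: ", paste(conflict, collapse = ", "))
  }
  p_given <- joint_probability(params, given)
  if (p_given <= .Q_EPS) {
    stop("conditioning event has probability <= ", .Q_EPS,
      "; conditional probability is undefined")
  }
  both <- c(cs$named, gv$named[setdiff(names(gv$named), names(cs$named))])
  joint_probability(params, both) / p_given
}

# Resolve a constraint vector against the parameter track ids.
check_constraints <- function(params, constraints) {
  if (length(constraints) < 1L) {
    stop("at least one constrained track is required")
  }
  vals <- as.numeric(constraints)
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    stop("constraint values must be 0 or 1")
  }
  ids <- colnames(params$q)
  nm <- names(constraints)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("constraints must be a named vector (track ids as names)")
  }
  idx <- match(nm, ids)
  as_int <- suppressWarnings(as.integer(nm))
  use_int <- is.na(idx) & !is.na(as_int)
  idx[use_int] <- as_int[use_int]
  if (anyNA(idx) || any(idx < 1L | idx > params$D)) {
    stop("unknown track(s): ",
      paste(nm[is.na(idx) | idx < 1L | idx > params$D], collapse = ", "),
      "; valid tracks: ", paste(ids, collapse = ", "))
  }
  if (anyDuplicated(idx)) {
    stop("duplicate constraints on track(s): ",
      paste(nm[duplicated(idx)], collapse = ", "))
  }
  named <- stats::setNames(vals, ids[idx])
  list(idx = idx, val = vals, named = named)
}

#' Parse a textual occurrence query
#'
#' Accepts strings like `"TrackA=1,TrackB=0"` (joint) or
#' `"TrackA=1,TrackB=0 | TrackC=1"` (conditional). Whitespace around
#' tokens is ignored.
#'
#' @param text Query string.
#' @return List with `constraints` and (possibly `NULL`) `given`, both
#'   named 0/1 vectors suitable for [joint_probability()] /
#'   [conditional_probability()].
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  halves <- strsplit(text, "|", fixed = TRUE)[[1L]]
  if (length(halves) > 2L) {
    stop("query may contain at most one '|'")
  }
  parse_side <- function(side) {
    toks <- strsplit(side, ",", fixed = TRUE)[[1L]]
    toks <- trimws(toks)
    toks <- toks[nzchar(toks)]
    if (!length(toks)) stop("empty constraint list in query")
    kv <- regmatches(toks, regexec("^(.+?)\\s*=\\s*([01])$", toks))
    bad <- lengths(kv) != 3L
    if (any(bad)) {
      stop("cannot parse query term(s): ",
        paste(toks[bad], collapse = ", "),
        " (expected 'Track=0' or 'Track=1')")
    }
    stats::setNames(
      as.numeric(vapply(kv, `[`, character(1L), 3L)),
      trimws(vapply(kv, `[`, character(1L), 2L))
    )
  }
  list(
    constraints = parse_side(halves[1L]),
    given = if (length(halves) == 2L) parse_side(halves[2L]) else NULL
  )
}

#' Evaluate a textual query against fitted parameters
#'
#' @inheritParams joint_probability
#' @param text Query string, see [parse_query()].
#' @return Probability in `[0, 1]`.
#' @examples
#' p <- mixture_params(c(0.5, 0.5), rbind(c(0.9, 0.1), c(0.1, 0.9)),
#'   track_ids = c("A", "B"))
#' query_probability(p, "A=1 | B=0")
#' @export
query_probability <- function(params, text) {
  q <- parse_query(text)
  if (is.null(q$given)) {
    joint_probability(params, q$constraints)
  } else {
    conditional_probability(params, q$constraints, q$given)
  }
}
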