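# Internal numerical helpers shared across modules.

# Probability clamp applied wherever Bernoulli parameters are *estimated*
# or fed into a log; keeps log q and log(1 - q) finite when estimates hit
# the boundary (boundary estimates are common with well-separated data).
.Q_EPS <- 1e-6

clamp_q <- function(q, eps = .Q_EPS) {
  pmin(pmax(q, eps), 1 - eps)
}

# Row-wise log(sum(exp(x))) without overflow; rows that are all -Inf
# stay -Inf rather than becoming NaN.
row_log_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  finite <- is.finite(mx)
  out <- mx
  if (any(finite)) {
    mf <- m[finite, , drop = FALSE]
    out[finite] <- mx[finite] + log(rowSums(exp(mf - mx[finite])))
  }
  out
}

# Validate / coerce a binary overlap matrix: integer storage, entries in
# {0, 1}, labelled rows and columns.
as_overlap_matrix <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 1L || ncol(Y) < 1L) {
    stop("overlap matrix must have at least one row and one column")
  }
  if (anyNA(Y) || !all(Y %in% c(0, 1))) {
    stop("overlap matrix entries must all be 0 or 1")
  }
  storage.mode(Y) <- "integer"
  if (is.null(rownames(Y))) {
    rownames(Y) <- sprintf("region_%d", seq_len(nrow(Y)))
  }
  if (is.null(colnames(Y))) {
    colnames(Y) <- sprintf("track_%d", seq_len(ncol(Y)))
  }
  Y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
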