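test_that("mixture_params validates its invariants", {
  p <- mixture_params(c(0.6, 0.4), rbind(c(0.9, 0.1), c(0, 1)))
  expect_equal(sum(p$pi), 1)
  expect_equal(p$K, 2L)
  expect_equal(p$D, 2L)
  expect_error(mixture_params(c(0.6, 0.5), matrix(0.5, 2, 2)), "sum to 1")
  expect_error(mixture_params(c(-0.1, 1.1), matrix(0.5, 2, 2)), ">= 0")
  expect_error(mixture_params(1, matrix(1.5, 1, 1)), "\\[0, 1\\]")
  clamped <- mixture_params(1, matrix(c(0, 1), 1, 2), clamp = TRUE)
  expect_true(all(clamped$q >= 1e-6 & clamped$q <= 1 - 1e-6))
})

test_that("observed_loglik handles trivial closed forms", {
  # single Bernoulli
  p <- mixture_params(1, matrix(0.5, 1, 1))
  expect_equal(observed_loglik(matrix(1, 1, 1), p), log(0.5))
  # two near-deterministic opposite components: one explains the row
  eps <- 1e-6
  p2 <- mixture_params(c(0.5, 0.5), rbind(c(1 - eps, eps), c(eps, 1 - eps)))
  expect_equal(observed_loglik(matrix(c(1, 0), 1, 2), p2), log(0.5),
    tolerance = 1e-5)
})

test_that("observed_loglik and e_step match brute-force arithmetic", {
  for (seed in 1:10) {
    p <- random_params(K = 2 + seed %% 2, D = 3, seed = 100 + seed)
    Y <- withr::with_seed(seed, matrix(rbinom(6 * 3, 1, 0.5), 6, 3))
    expect_equal(observed_loglik(Y, p),
      oracle_loglik_direct(Y, p$pi, p$q), tolerance = 1e-12)
    expect_equal(unname(e_step(Y, p)), oracle_estep(Y, p$pi, p$q),
      tolerance = 1e-12)
  }
})

test_that("e_step degenerate cases: single component and symmetry", {
  Y <- withr::with_seed(5, matrix(rbinom(15, 1, 0.5), 5, 3))
  p1 <- mixture_params(1, matrix(0.3, 1, 3))
  expect_equal(unname(e_step(Y, p1)), matrix(1, 5, 1))
  p2 <- mixture_params(c(0.5, 0.5), rbind(rep(0.3, 3), rep(0.3, 3)))
  expect_equal(unname(e_step(Y, p2)), matrix(0.5, 5, 2))
  # extreme parameters must not produce NaN
  pex <- mixture_params(c(0.5, 0.5),
    rbind(rep(1e-6, 3), rep(1 - 1e-6, 3)))
  mu <- e_step(matrix(1, 2, 3), pex)
  expect_false(anyNA(mu))
  expect_equal(unname(rowSums(mu)), c(1, 1))
})

test_that("m_step reduces to per-cluster frequencies for hard and uniform mu", {
  Y <- withr::with_seed(3, matrix(rbinom(40, 1, 0.4), 10, 4))
  # one-hot assignments
  z <- rep(1:2, each = 5)
  mu <- matrix(0, 10, 2)
  mu[cbind(1:10, z)] <- 1
  p <- m_step(Y, mu)
  expect_equal(p$pi, c(0.5, 0.5))
  expect_equal(unname(p$q),
    clamp_fix <- pmin(pmax(rbind(colMeans(Y[1:5, ]), colMeans(Y[6:10, ])),
      1e-6), 1 - 1e-6))
  # uniform responsibilities -> global column means everywhere
  pu <- m_step(Y, matrix(1 / 3, 10, 3))
  expect_equal(pu$pi, rep(1 / 3, 3))
  for (k in 1:3) {
    expect_equal(unname(pu$q[k, ]),
      pmin(pmax(colMeans(Y), 1e-6), 1 - 1e-6))
  }
})

test_that("m_step maximizes the expected complete-data log-likelihood", {
  withr::with_seed(17, {
    Y <- matrix(rbinom(60, 1, 0.5), 15, 4)
    mu <- matrix(runif(15 * 3), 15, 3)
    mu <- mu / rowSums(mu)
  })
  p <- m_step(Y, mu)
  q0 <- oracle_qfun(Y, mu, p$pi, p$q)
  for (k in 1:3) {
    for (d in 1:4) {
      for (delta in c(-1e-3, 1e-3)) {
        q2 <- p$q
        q2[k, d] <- min(max(q2[k, d] + delta, 1e-9), 1 - 1e-9)
        expect_lte(oracle_qfun(Y, mu, p$pi, q2), q0 + 1e-10)
      }
    }
    for (delta in c(-1e-3, 1e-3)) {
      pi2 <- p$pi
      pi2[k] <- max(pi2[k] + delta, 1e-9)
      pi2 <- pi2 / sum(pi2)
      expect_lte(oracle_qfun(Y, mu, pi2, p$q), q0 + 1e-10)
    }
  }
})

test_that("m_step flags emptied components instead of dividing by zero", {
  Y <- matrix(c(1, 0, 1, 0), 2, 2)
  mu <- cbind(c(1, 1), c(0, 0))
  expect_warning(p <- m_step(Y, mu), "empty mixture component")
  expect_true(attr(p, "degenerate"))
  expect_equal(unname(p$q[2, ]), c(0.5, 0.5))
  expect_error(m_step(Y, matrix(0.7, 2, 2)), "sum to 1")
})

test_that("kmeans_init recovers separable patterns and is deterministic", {
  Y <- rbind(
    matrix(rep(c(1L, 0L), 6), 6, 2, byrow = TRUE),
    matrix(rep(c(0L, 1L), 4), 4, 2, byrow = TRUE)
  )
  p <- kmeans_init(Y, 2, seed = 1)
  ord <- order(p$pi, decreasing = TRUE)
  expect_equal(sort(p$pi, decreasing = TRUE), c(0.6, 0.4))
  expect_equal(unname(round(p$q[ord, ])), rbind(c(1, 0), c(0, 1)))
  # clamped centers stay inside (0, 1)
  expect_true(all(p$q > 0 & p$q < 1))
  # K = 1 collapses to column means
  p1 <- kmeans_init(Y, 1, seed = 1)
  expect_equal(unname(p1$q[1, ]), c(0.6, 0.4))
  expect_equal(p1$pi, 1)
  # determinism
  Yr <- withr::with_seed(2, matrix(rbinom(200, 1, 0.5), 50, 4))
  expect_identical(kmeans_init(Yr, 3, seed = 9), kmeans_init(Yr, 3, seed = 9))
})

test_that("kmeans_init reduces K when there are too few distinct rows", {
  Y <- matrix(rep(c(1L, 0L, 0L, 1L), 5), 10, 2, byrow = TRUE)
  expect_warning(p <- kmeans_init(Y, 4, seed = 1), "distinct rows")
  expect_equal(p$K, 2L)
  expect_true(attr(p, "k_reduced"))
  expect_error(kmeans_init(Y, 0), "K must be >= 1")
})

test_that("fit_em with K = 1 equals the independent-Bernoulli closed form", {
  Y <- withr::with_seed(8, matrix(rbinom(300, 1, 0.3), 100, 3))
  fit <- fit_em(Y, 1, seed = 1)
  phat <- colMeans(Y)
  expect_equal(unname(fit$params$q[1, ]), phat, tolerance = 1e-9)
  closed <- sum(colSums(Y) * log(phat) + (100 - colSums(Y)) * log(1 - phat))
  expect_equal(fit$loglik, closed, tolerance = 1e-6)
})

test_that("fit_em recovers known two-component parameters", {
  truth <- mixture_params(c(0.5, 0.5),
    rbind(c(0.9, 0.9, 0.1), c(0.1, 0.1, 0.9)))
  sim <- simulate_matrix(truth, 2000, seed = 31)
  fit <- fit_em(sim$Y, 2, seed = 31)
  m <- match_components(fit, truth)
  expect_lt(max(abs(truth$q - fit$params$q[m$perm, ])), 0.05)
  expect_lt(max(abs(truth$pi - fit$params$pi[m$perm])), 0.05)
})

test_that("fit results satisfy their structural invariants", {
  sim <- simulate_matrix(sim_params(K = 3, D = 6), 400, seed = 4)
  fit <- fit_em(sim$Y, 3, seed = 4)
  # monotone trace
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  # assignments are the argmax of the responsibilities
  expect_equal(fit$assignments, max.col(fit$responsibilities,
    ties.method = "first"))
  # clusters sorted by decreasing size
  expect_true(all(diff(fit$params$pi) <= 1e-12))
  # responsibilities are a proper stochastic matrix
  expect_equal(unname(rowSums(fit$responsibilities)), rep(1, 400),
    tolerance = 1e-10)
  expect_equal(fit$bic, bic(fit$loglik, fit$K, fit$D, fit$N))
  expect_error(fit_em(sim$Y, 0), "K must satisfy")
  expect_error(fit_em(sim$Y, 401), "K must satisfy")
})

test_that("converged fits are EM fixpoints and permutation invariant", {
  sim <- simulate_matrix(sim_params(K = 2, D = 4), 500, seed = 12)
  tol <- 1e-8
  fit <- fit_em(sim$Y, 2, tol = tol, seed = 12)
  expect_true(fit$converged)
  extra <- m_step(sim$Y, e_step(sim$Y, fit$params))
  expect_lt(max(abs(extra$q - fit$params$q)), 10 * tol * abs(fit$loglik))
  expect_lt(max(abs(extra$pi - fit$params$pi)), 10 * tol * abs(fit$loglik))
  # relabelling components leaves the likelihood unchanged
  perm <- c(2, 1)
  pp <- mixture_params(fit$params$pi[perm], fit$params$q[perm, ])
  expect_equal(observed_loglik(sim$Y, pp),
    observed_loglik(sim$Y, fit$params), tolerance = 1e-12)
})

test_that("parameter tables round-trip through TSV", {
  p <- random_params(3, 4, seed = 77)
  f <- tempfile(fileext = ".tsv")
  write_params(p, f)
  back <- read_params(f)
  expect_equal(back$pi, p$pi, tolerance = 1e-12)
  expect_equal(back$q, p$q, tolerance = 1e-9)
  expect_error(
    read_params(write_bed_lines("param\tc1\nNanog\t0.5\nOct4\t0.2")),
    "must be 'pi'"
  )
})

test_that("the shipped mouse ES parameter table loads coherently", {
  f <- system.file("extdata", "mouse_es15_params.tsv",
    package = "intervalmix")
  es <- read_params(f)
  expect_equal(es$K, 8L)
  expect_equal(es$D, 15L)
  expect_equal(sum(es$pi), 1)
  expect_true(all(c("Nanog", "Oct4", "Ctcf", "p300") %in% colnames(es$q)))
})
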