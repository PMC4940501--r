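test_that("patefield_sample honors forced tables and marginals", {
  expect_equal(patefield_sample(1, 1, seed = 1), matrix(1L, 1, 1))
  draw <- patefield_sample(c(2, 0), c(1, 1), seed = 2)
  expect_equal(draw[2L, ], c(0L, 0L))
  expect_error(patefield_sample(c(2, 1), c(1, 1)), "agree")
  set.seed(33)
  for (k in 1:50) {
    r <- rpois(4, 5) + 1L; s <- as.vector(stats::rmultinom(1, sum(r), rep(1, 5)))
    m <- patefield_sample(r, s)
    expect_equal(rowSums(m), r)
    expect_equal(colSums(m), as.numeric(s))
  }
})

test_that("patefield draws match exact 2x2 table probabilities", {
  # every nondegenerate 2x2 margin with total <= 6, 2000 draws each, 3 SE
  set.seed(77)
  for (N in 2:6) {
    for (r1 in 1:(N - 1)) {
      for (c1 in 1:(N - 1)) {
        r <- c(r1, N - r1); s <- c(c1, N - c1)
        probs <- exact_2x2_probs(r, s)
        draws <- stats::r2dtable(2000, r, s)
        a11 <- vapply(draws, function(m) m[1, 1], numeric(1))
        emp <- table(factor(a11, levels = names(probs))) / 2000
        se <- sqrt(probs * (1 - probs) / 2000)
        expect_true(all(abs(as.numeric(emp) - probs) <= 3 * se + 1e-12),
                    info = sprintf("margins r=(%d,%d) c=(%d,%d)",
                                   r[1], r[2], s[1], s[2]))
      }
    }
  }
})

test_that("null_distribution evaluates the statistic over conserving draws", {
  w <- bipartite_web(matrix(c(4, 1, 2, 3, 0, 5), 2, 3))
  # a constant statistic (the grand total) is conserved on every draw
  ens <- null_distribution(w, function(m) sum(m), n = 50, seed = 4)
  expect_equal(ens$null, rep(sum(w), 50))
  # n = 0 keeps the observed value with an empty ensemble
  e0 <- null_distribution(w, wnodf, n = 0, seed = 1)
  expect_equal(length(e0$null), 0L)
  expect_equal(e0$observed, wnodf(w))
  # failing statistics are excluded and counted
  flaky <- local({
    i <- 0L
    function(m) {
      i <<- i + 1L
      if (i %% 3L == 0L) stop("undefined")
      sum(m > 0)
    }
  })
  ef <- null_distribution(w, flaky, n = 30, seed = 5)
  expect_equal(ef$n_failed, 10L)
  expect_equal(length(ef$null), 20L)
})

test_that("zscore_and_p matches hand computation and flags degeneracy", {
  ens <- structure(list(statistic = "x", observed = 3, null = c(1, 2, 3),
                        n = 3L, n_failed = 0L, seed = NULL),
                   class = "null_ensemble")
  zp <- zscore_and_p(ens)
  expect_equal(zp$z, 1.0)
  expect_equal(zp$p, 2 / 4)
  ens$observed <- 2
  expect_equal(zscore_and_p(ens)$z, 0)
  ens$null <- c(2, 2, 2)
  expect_error(zscore_and_p(ens), "degenerate")
})

test_that("empirical p is calibrated under the null", {
  # observed webs drawn from the null itself: rejection at 0.05 near nominal
  set.seed(2024)
  r <- c(10, 8, 6, 4); s <- c(9, 8, 6, 5)
  n_rep <- 2000
  rej <- 0L
  for (i in seq_len(n_rep)) {
    obs <- stats::r2dtable(1, r, s)[[1L]]
    nulls <- stats::r2dtable(99, r, s)
    stat_obs <- wnodf(obs)
    stat_null <- vapply(nulls, wnodf, numeric(1))
    p <- (1 + sum(stat_null >= stat_obs)) / 100
    if (p <= 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})
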