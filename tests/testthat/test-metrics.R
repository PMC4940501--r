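test_that("connectance is the realized-link fraction", {
  expect_equal(connectance(matrix(1, 2, 2)), 1)
  expect_equal(connectance(matrix(c(1, 0, 2, 3), 2, 2)), 0.75)
  expect_equal(connectance(diag(5) * 2), 0.2)
})

test_that("interaction evenness matches the Shannon formula", {
  expect_equal(interaction_evenness(matrix(1, 2, 2)), 1)
  m <- matrix(c(2, 0, 1, 1), 2, 2)
  H <- -(0.5 * log(0.5) + 0.25 * log(0.25) * 2)
  expect_equal(interaction_evenness(m), H / log(3))
  # all weight in two equal cells is perfectly even
  expect_equal(interaction_evenness(matrix(c(4, 0, 0, 4), 2, 2)), 1)
  # under the all-cells convention the denominator grows
  expect_equal(interaction_evenness(m, links = "all"), H / log(4))
  expect_error(interaction_evenness(matrix(c(5, 0, 0, 0), 2, 2)), "links")
})

test_that("wnodf agrees with hand-built extremes", {
  expect_equal(wnodf(matrix(c(5, 0, 0, 5), 2, 2)), 0)     # compartmentalized
  expect_equal(wnodf(matrix(c(3, 1, 2, 0), 2, 2)), 100)   # [[3,2],[1,0]]
  expect_error(wnodf(matrix(5, 1, 1)), "undefined")
})

test_that("wnodf equals the brute-force pair oracle on random webs", {
  set.seed(42)
  for (k in 1:25) {
    m <- random_web(sample(2:7, 1), sample(2:7, 1))
    expect_equal(wnodf(m), wnodf_oracle(m))
  }
})

test_that("h2prime hits the specialization extremes", {
  expect_equal(h2prime(matrix(c(5, 0, 0, 5), 2, 2)), 1)
  expect_equal(h2prime(matrix(1, 2, 2)), 0)
  expect_error(h2prime(matrix(c(1, 2), 1, 2)), "H2'")
})

test_that("planted specialized webs outscore marginal-matched random webs", {
  diag_web <- diag(4) * 10
  set.seed(8)
  nulls <- stats::r2dtable(100, rowSums(diag_web), colSums(diag_web))
  h_obs <- h2prime(diag_web)
  h_null <- vapply(nulls, h2prime, numeric(1))
  expect_gt(h_obs, max(h_null) - 1e-9)
  expect_gt(mean(h_obs > h_null), 0.95)
})

test_that("generality is the marginal-weighted effective partner number", {
  expect_equal(generality(matrix(1, 2, 2), "plants"), 2)
  expect_equal(generality(matrix(1, 2, 2), "bacteria"), 2)
  m <- matrix(c(3, 0, 1, 2), 2, 2)  # rows (3,1), (0,2)
  H1 <- log(4) - 0.75 * log(3)
  expect_equal(generality(m, "plants"), (4 / 6) * exp(H1) + (2 / 6) * 1)
  # every bacterium on one plant -> Gb = 1
  expect_equal(generality(diag(3) * 2, "bacteria"), 1)
})

test_that("species metrics: degree, effective partners, d-prime", {
  m <- matrix(c(1, 0, 2, 3), 2, 2,
              dimnames = list(c("pA", "pB"), c("t1", "t2")))
  sm <- species_metrics(m)
  expect_equal(sm$degree[sm$species == "pA"], 2L)
  expect_equal(sm$degree[sm$species == "pB"], 1L)
  expect_equal(sm$degree[sm$species == "t1"], 1L)
  expect_equal(sm$degree[sm$species == "t2"], 2L)
  # row (3,1): exp(H) with H = ln4 - 0.75 ln3
  row31 <- matrix(c(3, 0, 1, 2), 2, 2)
  sm2 <- species_metrics(row31)
  expect_equal(sm2$effective_partners[[1L]], exp(log(4) - 0.75 * log(3)))
  # uniform row (2,2) -> 2 effective partners; single partner -> 1
  sm3 <- species_metrics(matrix(c(2, 0, 2, 5), 2, 2))
  expect_equal(sm3$effective_partners[[1L]], 2)
  expect_equal(sm3$effective_partners[[2L]], 1)
})

test_that("effective partners never exceed degree (equality iff uniform)", {
  set.seed(13)
  for (k in 1:50) {
    m <- random_web(sample(2:6, 1), sample(2:6, 1))
    sm <- species_metrics(m)
    expect_true(all(sm$effective_partners <= sm$degree + 1e-9))
  }
})

test_that("d-prime: availability-matched use scores 0, monopolies score 1", {
  # species whose partner distribution equals overall availability
  m <- rbind(c(6, 3), c(2, 1))  # both rows proportional to column totals
  sm <- species_metrics(m)
  expect_equal(sm$d[sm$side == "plant"], c(0, 0), tolerance = 1e-12)
  expect_equal(sm$dprime[sm$side == "plant"], c(0, 0))
  # monopolized exclusive partner with A_i = D_j reaches d_max
  m2 <- rbind(c(5, 0, 0), c(0, 3, 2), c(0, 1, 4))
  sm2 <- species_metrics(m2)
  expect_equal(sm2$d[[1L]], log(sum(m2) / 5))
  expect_equal(sm2$dprime[[1L]], 1)
})

test_that("metric ranges hold over random fixed-marginal webs", {
  set.seed(99)
  webs <- stats::r2dtable(200, c(12, 9, 7, 5), c(10, 9, 8, 6))
  for (m in webs) {
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
    if (nrow(m) < 2 || ncol(m) < 2) next
    expect_gte(connectance(m), 0); expect_lte(connectance(m), 1)
    ie <- interaction_evenness(m)
    expect_gte(ie, 0); expect_lte(ie, 1)
    wn <- wnodf(m)
    expect_gte(wn, 0); expect_lte(wn, 100)
    h2 <- h2prime(m)
    expect_gte(h2, 0); expect_lte(h2, 1)
    sm <- species_metrics(m)
    expect_true(all(sm$dprime >= 0 & sm$dprime <= 1))
  }
})

test_that("metrics are invariant to uniform count scaling", {
  set.seed(5)
  m <- random_web(4, 5)
  for (k in c(2L, 7L)) {
    expect_equal(connectance(k * m), connectance(m))
    expect_equal(interaction_evenness(k * m), interaction_evenness(m))
    expect_equal(wnodf(k * m), wnodf(m))
    expect_equal(generality(k * m, "plants"), generality(m, "plants"))
    expect_equal(generality(k * m, "bacteria"), generality(m, "bacteria"))
    expect_equal(h2prime(k * m), h2prime(m), tolerance = 0.02)
    sm1 <- species_metrics(m); smk <- species_metrics(k * m)
    expect_equal(smk$effective_partners, sm1$effective_partners)
    expect_equal(smk$d, sm1$d)
  }
})

test_that("network_metrics assembles the one-row summary", {
  w <- bipartite_web(matrix(c(3, 1, 0, 2), 2, 2))
  nm <- network_metrics(w)
  expect_equal(nm$plants, 2L)
  expect_equal(nm$links, 3L)
  expect_equal(nm$connectance, 0.75)
  expect_equal(nm$wnodf, wnodf_oracle(unclass(w)))
})
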