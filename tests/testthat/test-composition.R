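test_that("g_test matches closed forms and the cell-by-cell oracle", {
  even <- matrix(10, 2, 2)
  res <- g_test(even)
  expect_equal(res$G, 0)
  expect_equal(res$p, 1)
  diag2 <- matrix(c(10, 0, 0, 10), 2, 2)
  res2 <- g_test(diag2)
  expect_equal(res2$G, 40 * log(2))
  expect_equal(res2$df, 1L)
  set.seed(17)
  for (k in 1:30) {
    ct <- matrix(rpois(6, 8) + 1L, 2, 3)
    expect_equal(g_test(ct)$G, g_oracle(ct), tolerance = 1e-10)
  }
})

test_that("g_test rejects invalid tables and supports Williams correction", {
  expect_error(g_test(matrix(0, 2, 2)), "empty")
  expect_error(g_test(matrix(c(1, 0, 2, 0), 2, 2, byrow = TRUE), ), "all-zero")
  ct <- matrix(c(12, 5, 7, 9), 2, 2)
  expect_lt(g_test(ct, williams = TRUE)$G, g_test(ct)$G)
})

test_that("G-test type-I error is near nominal under multinomial independence", {
  set.seed(555)
  probs <- as.vector(outer(c(0.5, 0.5), c(0.3, 0.4, 0.3)))
  n_rep <- 2000
  rej <- 0L
  for (i in seq_len(n_rep)) {
    ct <- matrix(stats::rmultinom(1, 200, probs), 2, 3)
    if (any(rowSums(ct) == 0) || any(colSums(ct) == 0)) next
    if (g_test(ct)$p <= 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})

test_that("clade_table builds the status and gradient contrasts", {
  tab <- tibble::tibble(
    sequence_id = sprintf("q%03d", 1:60),
    site = rep(c("u", "s", "h"), each = 20),
    invasion_status = rep(c("uninvaded", "semi", "heavy"), each = 20),
    plant_species = rep(rep(c("nat1", "inv1"), each = 10), 3),
    plant_status = rep(rep(c("native", "invasive"), each = 10), 3),
    clade = rep(c("beta-Burkholderia", "alpha-Bradyrhizobium"), 30))
  ct <- clade_table(tab, "status_at_invaded")
  expect_equal(sum(ct), 40L)  # only the two invaded sites
  expect_equal(sort(rownames(ct)), c("invasive", "native"))
  ct2 <- clade_table(tab, "gradient_for_shared_natives")
  expect_equal(sort(rownames(ct2)), c("invaded", "uninvaded"))
  expect_equal(sum(ct2), 30L)  # nat1 occurs on both sides: 10 + 20 records
  # no invaded records -> error
  uninv <- tab[tab$invasion_status == "uninvaded", ]
  expect_error(clade_table(uninv, "status_at_invaded"), "no records")
})

test_that("planted clade contrasts produce off-diagonal zeros", {
  sc <- scenario_design("co-introduction", seed = 31)
  survey <- gen_survey(sc$design, sc$community, sc$community_truth, seed = 32)
  ct <- clade_table(survey$table, "status_at_invaded")
  # invasives carry only Bradyrhizobium in this scenario
  expect_equal(sum(ct["invasive", setdiff(colnames(ct),
                                          "alpha-Bradyrhizobium")]), 0L)
  expect_equal(sum(ct["native", "alpha-Bradyrhizobium"]), 0L)
  expect_equal(sum(ct), sum(survey$table$invasion_status %in% c("semi", "heavy")))
})

test_that("species-metric comparison picks its branch and reports groups", {
  df <- tibble::tibble(
    species = rep(letters[1:8], each = 2),
    site = rep(c("s1", "s2"), 8),
    group = rep(c("native", "invasive"), each = 8),
    val = c(rnorm(8, 4, 0.5), rnorm(8, 2, 0.5)))
  set.seed(1)
  res <- compare_species_metrics(df, "val", "group")
  expect_true(res$test %in% c("anova", "kruskal"))
  expect_equal(res$df1, 1)
  summ <- res$group_summary[[1L]]
  expect_equal(nrow(summ), 2L)
  expect_equal(sum(summ$n), 8L)  # one value per species after averaging
  # identical groups: no difference to find
  df2 <- df; df2$val <- rep(c(1, 2, 3, 4), 4)
  res2 <- compare_species_metrics(df2, "val", "group")
  expect_gt(res2$p, 0.9)
  # constant metric short-circuits
  df3 <- df; df3$val <- 1
  expect_equal(compare_species_metrics(df3, "val", "group")$test, "degenerate")
})

test_that("kruskal branch matches a hand-ranked oracle", {
  df <- tibble::tibble(
    species = paste0("sp", 1:18), site = "s1",
    group = rep(c("g1", "g2", "g3"), each = 6),
    # a gross outlier per group fails the Shapiro screen
    val = c(1, 1, 2, 2, 3, 100, 4, 5, 5, 6, 6, 200, 7, 8, 8, 9, 9, 300))
  res <- compare_species_metrics(df, "val", "group")
  expect_equal(res$test, "kruskal")
  kt <- stats::kruskal.test(df$val, factor(df$group))
  expect_equal(res$statistic, unname(kt$statistic))
  expect_equal(res$p, kt$p.value)
})

test_that("clade occupancy percentages sum to 100 within groups", {
  sc <- scenario_design("random", seed = 41)
  survey <- gen_survey(sc$design, sc$community, sc$community_truth, seed = 42)
  occ <- clade_occupancy(survey$table)
  sums <- occ |>
    dplyr::group_by(.data$invasion_status, .data$plant_species) |>
    dplyr::summarise(tot = sum(.data$percent), .groups = "drop")
  expect_true(all(abs(sums$tot - 100) < 1e-9))
  expect_equal(sum(occ$n), nrow(survey$table))
})
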