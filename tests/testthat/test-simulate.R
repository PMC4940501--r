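test_that("sequence community hits its identity bands exactly", {
  sim <- gen_sequence_community(2, 1, 100, 1, 0.90, seed = 1)
  idm <- pairwise_identity(sim$seqs)
  expect_equal(nrow(idm), 2L)
  expect_equal(unclass(idm)[1, 2], 0.90)
  asg <- cluster_at_threshold(idm, 0.95)
  expect_equal(n_taxa(asg), 2L)

  sim2 <- gen_sequence_community(3, 4, 300, 0.99, 0.94, seed = 2)
  expect_equal(nrow(sim2$seqs), 12L)
  idm2 <- unclass(pairwise_identity(sim2$seqs))
  same <- outer(sim2$truth$taxon, sim2$truth$taxon, "==")
  diag(same) <- NA
  expect_true(all(idm2[which(same)] >= 0.99))
  expect_true(all(idm2[which(!same)] <= 0.94))
  expect_equal(n_taxa(cluster_at_threshold(pairwise_identity(sim2$seqs),
                                           0.98)), 3L)
  # genotype level resolves every sequence (within-identity < 1)
  expect_equal(n_taxa(collapse_genotypes(sim2$seqs)), 12L)
})

test_that("single-sequence community is the trivial identity case", {
  sim <- gen_sequence_community(1, 1, 100, 1, 0.9, seed = 1)
  expect_equal(nrow(sim$seqs), 1L)
  expect_equal(unname(unclass(pairwise_identity(sim$seqs))[1, 1]), 1.0)
})

test_that("infeasible identity targets are rejected", {
  expect_error(gen_sequence_community(50, 10, 100, 0.9, 0.5, seed = 1),
               "infeasible")
  expect_error(gen_sequence_community(2, 2, 100, 0.9999, 0.5, seed = 1),
               "close to 1")
  expect_error(gen_sequence_community(2, 1, 100, 0.9, 0.95, seed = 1),
               "strictly below")
})

test_that("generators are deterministic given a seed", {
  a <- gen_sequence_community(3, 2, 200, 0.99, 0.9, seed = 5)
  b <- gen_sequence_community(3, 2, 200, 0.99, 0.9, seed = 5)
  expect_identical(a$seqs$sequence, b$seqs$sequence)
  w1 <- gen_modular_web(5, 8, 3, 4, 0.2, seed = 6)
  w2 <- gen_modular_web(5, 8, 3, 4, 0.2, seed = 6)
  expect_identical(unclass(w1$web), unclass(w2$web))
  n1 <- gen_nested_web(6, 10, seed = 7)
  n2 <- gen_nested_web(6, 10, seed = 7)
  expect_identical(unclass(n1), unclass(n2))
})

test_that("modular generator plants the requested block structure", {
  mw <- gen_modular_web(5, 5, 5, lambda_in = 5, lambda_out = 0, seed = 9)
  m <- unclass(mw$web)
  rmod <- mw$truth$module[mw$truth$side == "plant"]
  cmod <- mw$truth$module[mw$truth$side == "bacterium"]
  expect_true(all(m[outer(rmod, cmod, "!=")] == 0))
  expect_true(all(rowSums(m) > 0) && all(colSums(m) > 0))
  expect_error(gen_modular_web(5, 5, 6, 5, 0, seed = 1), "n_modules")
  expect_error(gen_modular_web(5, 5, 2, 1, 1, seed = 1), "lambda")
})

test_that("modular generator rates are honored on average", {
  ins <- c(); outs <- c()
  for (s in 1:40) {
    mw <- gen_modular_web(6, 12, 3, lambda_in = 5, lambda_out = 0.2, seed = s)
    m <- unclass(mw$web)
    rmod <- mw$truth$module[mw$truth$side == "plant"]
    cmod <- mw$truth$module[mw$truth$side == "bacterium"]
    within <- outer(rmod, cmod, "==")
    ins <- c(ins, m[within]); outs <- c(outs, m[!within])
  }
  expect_gt(mean(ins), mean(outs))
  expect_equal(mean(ins), 5, tolerance = 0.1)
  expect_lt(mean(outs), 0.5)  # margin repair inflates 0.2 slightly
})

test_that("nested generator spans full fill to triangular fill", {
  full <- gen_nested_web(4, 6, fill_decay = 0, total_count = 500, seed = 1)
  expect_equal(connectance(full), 1)
  tri <- gen_nested_web(8, 12, fill_decay = 4, total_count = 200, seed = 2)
  m <- unclass(tri)
  expect_lt(connectance(tri), 0.6)
  # marginal totals decay along the ranks (modulo multinomial noise)
  expect_gt(mean(rowSums(m)[1:4]), 2 * mean(rowSums(m)[5:8]))
  expect_gt(mean(colSums(m)[1:6]), 2 * mean(colSums(m)[7:12]))
  expect_gt(wnodf(tri), 60)
})

test_that("survey respects the design and records round-trip into webs", {
  sc <- scenario_design("co-introduction", seed = 13)
  survey <- gen_survey(sc$design, sc$community, sc$community_truth, seed = 14)
  counts <- dplyr::count(survey$table, .data$site, .data$plant_species)
  planned <- sc$design$plants
  merged <- dplyr::inner_join(counts, planned,
                              by = c("site", "plant_species"))
  expect_equal(merged$n, merged$nodules)
  expect_equal(nrow(survey$table), 296L)
  # every record's sequence is a copy of its planted genotype
  expect_identical(survey$table$sequence_id, survey$seqs$id)
  # round-trip: web from records equals tabulated sampled counts
  asg <- survey$truth[c("sequence_id", "taxon")]
  names(asg)[2] <- "taxon_id"
  w <- build_web(survey$table, asg)
  expect_equal(sum(w), 296)
  direct <- table(dplyr::inner_join(survey$table, survey$truth,
                                    by = "sequence_id")[
                                      c("plant_species", "taxon")])
  expect_equal(sum(unclass(w) > 0), sum(direct > 0))
})

test_that("surveys are deterministic and designs validated", {
  sc <- scenario_design("infiltration", seed = 15)
  s1 <- gen_survey(sc$design, sc$community, sc$community_truth, seed = 16)
  s2 <- gen_survey(sc$design, sc$community, sc$community_truth, seed = 16)
  expect_identical(s1$table, s2$table)
  bad_truth <- sc$community_truth
  bad_truth$taxon <- paste0("other_", bad_truth$taxon)
  expect_error(gen_survey(sc$design, sc$community, bad_truth, seed = 1),
               "absent from the community")
})
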