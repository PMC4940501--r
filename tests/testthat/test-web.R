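make_records <- function(n, plant, taxon, site = "s1", status = "native",
                         clade = "beta-Burkholderia", offset = 0L) {
  tibble::tibble(
    sequence_id = sprintf("q%04d", offset + seq_len(n)),
    site = site, invasion_status = "uninvaded",
    plant_species = plant, plant_status = status, clade = clade,
    taxon_id = taxon)
}

test_that("build_web cross-tabulates records and conserves totals", {
  recs <- dplyr::bind_rows(
    make_records(3, "pA", "t1"),
    make_records(2, "pA", "t2", offset = 10L),
    make_records(4, "pB", "t2", offset = 20L))
  asg <- recs[c("sequence_id", "taxon_id")]
  w <- build_web(recs, asg)
  expect_s3_class(w, "bipartite_web")
  expect_equal(sum(w), 9)
  expect_equal(unclass(w)["pA", "t1"], 3)
  expect_equal(unclass(w)["pB", "t2"], 4)
  expect_equal(sum(rowSums(w)), sum(colSums(w)))
  # single record -> 1x1 web with connectance 1
  one <- make_records(1, "pX", "tX")
  w1 <- build_web(one, one[c("sequence_id", "taxon_id")])
  expect_equal(dim(w1), c(1L, 1L))
  expect_equal(connectance(w1), 1)
})

test_that("build_web errors on empty selections and missing assignments", {
  recs <- make_records(2, "pA", "t1")
  asg <- recs[c("sequence_id", "taxon_id")]
  expect_error(build_web(recs, asg, sites = "nowhere"), "no nodule records")
  expect_error(build_web(recs, asg[1L, ]), "without a taxon assignment")
})

test_that("records from the disjoint-module generator rebuild block-diagonally", {
  sc <- scenario_design("co-introduction", seed = 5)
  survey <- gen_survey(sc$design, sc$community, sc$community_truth, seed = 6)
  asg <- survey$truth[c("sequence_id", "taxon")]
  names(asg)[2] <- "taxon_id"
  w <- build_web(survey$table, asg, sites = "site_U")
  # each plant's taxa are private: no taxon column has two nonzero plants
  expect_true(all(colSums(unclass(w) > 0) == 1))
  expect_equal(sum(w), 100)  # the uninvaded site's nodule total
})

test_that("combine_webs pools counts over the union of labels", {
  w1 <- bipartite_web(matrix(c(2, 0, 1, 3), 2, 2,
                             dimnames = list(c("pA", "pB"), c("t1", "t2"))))
  w2 <- bipartite_web(matrix(c(1, 4), 1, 2,
                             dimnames = list("pA", c("t2", "t3"))))
  cw <- combine_webs(list(w1, w2))
  expect_equal(sum(cw), sum(w1) + sum(w2))
  expect_equal(rownames(cw), c("pA", "pB"))
  expect_equal(colnames(cw), c("t1", "t2", "t3"))
  expect_equal(unclass(cw)["pA", "t2"], 1 + 1)
  # disjoint label sets give a block-diagonal combined web
  w3 <- bipartite_web(matrix(5, 1, 1, dimnames = list("pZ", "t9")))
  cw2 <- combine_webs(list(w1, w3))
  expect_equal(unclass(cw2)["pZ", "t1"], 0)
  expect_equal(unclass(cw2)["pA", "t9"], 0)
})

test_that("combining site webs matches pooling the records directly", {
  sc <- scenario_design("random", seed = 9)
  survey <- gen_survey(sc$design, sc$community, sc$community_truth, seed = 10)
  asg <- survey$truth[c("sequence_id", "taxon")]
  names(asg)[2] <- "taxon_id"
  sites <- unique(survey$table$site)
  per_site <- lapply(sites, function(s) build_web(survey$table, asg, sites = s))
  combined <- combine_webs(per_site)
  pooled <- build_web(survey$table, asg)
  cm <- unclass(combined)[rownames(pooled), colnames(pooled)]
  expect_equal(dim(cm), dim(pooled))
  expect_true(all(cm == unclass(pooled)))
  expect_equal(sum(combined), 296)  # 100 + 97 + 99
})

test_that("conflicting plant-status metadata across webs errors", {
  w1 <- bipartite_web(matrix(2, 1, 1, dimnames = list("pA", "t1")),
                      plant_status = c(pA = "native"))
  w2 <- bipartite_web(matrix(2, 1, 1, dimnames = list("pA", "t2")),
                      plant_status = c(pA = "invasive"))
  expect_error(combine_webs(list(w1, w2)), "conflicting plant_status")
})
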