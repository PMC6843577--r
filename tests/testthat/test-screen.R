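# Three-channel screening and the case-study fixture.

test_that("the case-study fixture reproduces the published subgroup sets", {
  fx <- make_pmt_fixture()
  s2 <- screen_subgroup2(fx$ingredients, fx$hili)
  s3 <- screen_subgroup3("He Shou Wu", fx$network)
  expect_equal(s2, fx$expected$s2)
  expect_equal(s3, fx$expected$s3)
  expect_length(fx$expected$s1, 21)
  expect_length(s2, 6)
  expect_length(s3, 7)
  expect_setequal(s3, c("emodin", "chrysophanol", "chrysarobin", "rhein",
                        "danthron", "polygonumnolide c2",
                        "emodin dianthrone"))
  # luteolin is a HILI-only hit
  expect_true("luteolin" %in% s2)
  expect_false("luteolin" %in% fx$expected$s1)
})

test_that("integration yields the published union and unique contributions", {
  fx <- make_pmt_fixture()
  res <- integrate_subgroups(fx$expected$s1,
                             screen_subgroup2(fx$ingredients, fx$hili),
                             screen_subgroup3("He Shou Wu", fx$network))
  expect_length(res$union, 25)
  expect_equal(unname(res$subgroup_sizes), c(21, 6, 7))
  expect_equal(unname(res$unique_counts), c(15, 1, 3))
  expect_setequal(res$union, fx$expected$union)
  # provenance bookkeeping: set sizes add up across channels
  expect_equal(sum(res$table$in_s1) + sum(res$table$in_s2) +
                 sum(res$table$in_s3), 21 + 6 + 7)
})

test_that("network and HILI lookups are normalization-insensitive", {
  fx <- make_pmt_fixture()
  expect_equal(screen_subgroup3("he shou wu", fx$network),
               screen_subgroup3("He Shou Wu", fx$network))
  shouty <- fx$ingredients
  shouty$name <- toupper(shouty$name)
  expect_equal(screen_subgroup2(shouty, fx$hili),
               screen_subgroup2(fx$ingredients, fx$hili))
  expect_message(out <- screen_subgroup3("unknown herb", fx$network),
                 "not found")
  expect_length(out, 0)
})

test_that("integration is commutative and idempotent with faithful provenance", {
  s1 <- c("a", "b", "c"); s2 <- c("b", "d"); s3 <- c("c", "d", "e")
  r1 <- integrate_subgroups(s1, s2, s3)
  r2 <- integrate_subgroups(s1, rev(s2), unique(c(s3, s3)))
  expect_equal(r1$table, r2$table)
  expect_setequal(r1$union, c("a", "b", "c", "d", "e"))
  expect_equal(r1$table$provenance[r1$table$ingredient == "d"],
               "hili+network")
  # every union member has non-empty provenance consistent with membership
  expect_true(all(nchar(r1$table$provenance) > 0))
  # no invented names
  expect_true(all(r1$union %in% c(s1, s2, s3)))
  empty <- integrate_subgroups(character(0), character(0), character(0))
  expect_length(empty$union, 0)
})

test_that("classifier screening applies the strict probability threshold", {
  ids <- c("i1", "i2", "i3")
  ingredients <- as_compounds(tibble::tibble(
    compound_id = ids, name = c("Alpha", "Beta", "Gamma")))
  fm <- fm_from_matrix(matrix(rnorm(3), ncol = 1,
                              dimnames = list(NULL, "f1")),
                       ids = ids, family = "toy")
  # a one-base stack whose meta model passes the base call through
  base <- make_stub_bases(matrix(c(1, 1, 0), ncol = 1), ids,
                          family = "toy")[[1]]
  st <- fit_stacked(list(base), list(toy = fm),
                    c("pos", "pos", "neg"), mode = "resubstitution")
  s1 <- screen_subgroup1(ingredients, st, list(toy = fm))
  expect_setequal(as.character(s1), c("alpha", "beta"))

  # all-negative model: empty subgroup
  neg <- make_stub_bases(matrix(0, 3, 1), ids, family = "toy")[[1]]
  st0 <- fit_stacked(list(neg, neg), list(toy = fm),
                     c("pos", "neg", "neg"), mode = "resubstitution")
  expect_length(screen_subgroup1(ingredients, st0, list(toy = fm)), 0)

  # probability exactly at the threshold is excluded: a base that always
  # votes positive on balanced labels yields a posterior of exactly 0.5
  two <- as_compounds(tibble::tibble(compound_id = c("i1", "i2"),
                                     name = c("Alpha", "Beta")))
  fm2 <- fm_from_matrix(matrix(rnorm(2), ncol = 1,
                               dimnames = list(NULL, "f1")),
                        ids = c("i1", "i2"), family = "toy")
  always <- make_stub_bases(matrix(1, 2, 1), c("i1", "i2"),
                            family = "toy")[[1]]
  st_half <- fit_stacked(list(always), list(toy = fm2), c("pos", "neg"),
                         mode = "resubstitution")
  pr_half <- predict_stacked(st_half, list(toy = fm2))
  expect_equal(pr_half$probability, c(0.5, 0.5))
  expect_length(screen_subgroup1(two, st_half, list(toy = fm2)), 0)
})

test_that("hierarchical ingredient clustering behaves at its extremes", {
  x <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10.5, 10), c(0.2, 0.1))
  colnames(x) <- c("d1", "d2")
  fm <- fm_from_matrix(x, ids = paste0("g", 1:5))
  cl <- cluster_ingredients(fm, n_groups = 2)
  # two identical rows merge first, at height 0
  expect_equal(cl$tree$height[1], 0)
  expect_equal(cl$groups[["g1"]], cl$groups[["g2"]])
  # well-separated blobs are recovered perfectly
  expect_equal(cl$groups[["g3"]], cl$groups[["g4"]])
  expect_false(cl$groups[["g1"]] == cl$groups[["g3"]])
  # n_groups = n gives singletons; n_groups > n errors
  expect_length(unique(cluster_ingredients(fm, 5)$groups), 5)
  expect_error(cluster_ingredients(fm, 6), class = "hepascreen_data_error")
})

test_that("run_screen integrates channels and writes its reports", {
  fx <- make_pmt_fixture()
  out_dir <- withr::local_tempdir()
  res <- run_screen(fx$ingredients, "He Shou Wu", fx$network, fx$hili,
                    s1_override = fx$expected$s1, out_dir = out_dir)
  expect_length(res$union, 25)
  expect_true(file.exists(file.path(out_dir, "screening.csv")))
  expect_true(file.exists(file.path(out_dir, "screening.json")))
  rep <- jsonlite::read_json(file.path(out_dir, "screening.json"))
  expect_equal(rep$unique_counts$s1, 15)

  # without the classifier channel the union is s2 U s3
  res0 <- run_screen(fx$ingredients, "He Shou Wu", fx$network, fx$hili,
                     no_classifier = TRUE)
  expect_setequal(res0$union,
                  union(screen_subgroup2(fx$ingredients, fx$hili),
                        screen_subgroup3("He Shou Wu", fx$network)))
  expect_error(run_screen(fx$ingredients, "x", fx$network, fx$hili),
               class = "hepascreen_config_error")
})
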