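test_that("co-expression screen keeps exact and affine partners, excludes anticorrelation", {
  m <- rbind(q = c(1, 2, 3, 4, 5),
             double = c(2, 4, 6, 8, 10),
             rev = c(5, 4, 3, 2, 1),
             flat = c(7, 7, 7, 7, 7))
  expect_warning(rec <- coexpressed_set("q", m), "zero-variance")
  expect_identical(rec$partner_id, "double")
  expect_equal(rec$r, 1, tolerance = 1e-12)
  expect_error(coexpressed_set("nope", m), "absent")
  expect_error(coexpressed_set("q", m[, 1:2]), "3 samples")
})

test_that("Pearson screen agrees with the textbook two-pass oracle to 1e-12", {
  set.seed(500)
  m <- matrix(rnorm(100 * 20), 100, dimnames = list(sprintf("g%03d", 1:100), NULL))
  rec <- coexpressed_set("g001", m, r_min = -1)
  for (i in seq_len(nrow(rec))) {
    expect_equal(rec$r[i], oracle_pearson(m["g001", ], m[rec$partner_id[i], ]),
                 tolerance = 1e-12)
  }
  # symmetry of the correlation
  expect_equal(rec$r[rec$partner_id == "g050"],
               coexpressed_set("g050", m, r_min = -1)$r[
                 coexpressed_set("g050", m, r_min = -1)$partner_id == "g001"],
               tolerance = 1e-12)
  # random Gaussian rows essentially never reach 0.85
  expect_lte(nrow(coexpressed_set("g001", m, r_min = 0.85)), 1)
})

test_that("category counting fills from the annotation and aggregates flags", {
  fx <- coexpression_partner_fixture()
  ann <- fixture_annotation()
  r74 <- fx[fx$query == "SvMYB74", ]
  rec74 <- data.frame(query_id = "SvMYB74", partner_id = r74$partner_id,
                      r = r74$r, category = NA_character_)
  cc <- count_target_categories(rec74, ann)
  expect_equal(cc$counts[["lignin_biosynthesis"]], 7)
  expect_equal(cc$total_targets, 32)
  expect_true(cc$flags[["has_toolbox"]])
  expect_true(cc$flags[["has_laccase"]])
  empty <- count_target_categories(rec74[0, ], ann)
  expect_true(all(empty$counts == 0))
  # unannotated partners default to "other"
  stray <- data.frame(query_id = "q", partner_id = "UNKNOWN.1", r = 0.9,
                      category = NA_character_)
  expect_equal(count_target_categories(stray, ann)$counts[["other"]], 1)
})

test_that("shortlisting applies the minimum-target rule and ranks by count", {
  genes <- sprintf("g%03d", 1:80)
  e <- gen_expression_data(genes, 39, 4, 3, genes[1:20], genes[21:23],
                           r_within = 0.95, r_background = 0.2, seed = 19)
  ann <- category_annotation(data.frame(gene_id = genes[1:20],
                                        category = "lignin_biosynthesis"))
  sl <- shortlist_candidates(genes[21:23], e$atlas, ann, min_targets = 11)
  expect_true(all(sl$pass))
  expect_true(!is.unsorted(rev(sl$total_targets)))
  sl_hi <- shortlist_candidates(genes[21:23], e$atlas, ann, min_targets = 100)
  expect_false(any(sl_hi$pass))
  # boundary: exactly min_targets passes
  n0 <- sl$total_targets[1]
  expect_true(shortlist_candidates(sl$gene_id[1], e$atlas, ann,
                                   min_targets = n0)$pass)
  expect_false(shortlist_candidates(sl$gene_id[1], e$atlas, ann,
                                    min_targets = n0 + 1)$pass)
})

test_that("shortlist size is monotone in r_min and min_targets", {
  set.seed(71)
  genes <- sprintf("g%03d", 1:50)
  e <- gen_expression_data(genes, 20, 4, 3, genes[1:15], genes[16:20],
                           r_within = 0.9, r_background = 0.3, seed = 72)
  ann <- category_annotation(data.frame(gene_id = genes[1:15],
                                        category = "lignin_related"))
  cands <- genes[16:20]
  for (i in 1:5) {
    r1 <- runif(1, 0.3, 0.9); r2 <- runif(1, r1, 0.99)
    t1 <- sample(1:8, 1); t2 <- t1 + sample(1:8, 1)
    n_r1 <- sum(shortlist_candidates(cands, e$atlas, ann, r_min = r1, min_targets = t1)$pass)
    n_r2 <- sum(shortlist_candidates(cands, e$atlas, ann, r_min = r2, min_targets = t1)$pass)
    n_t2 <- sum(shortlist_candidates(cands, e$atlas, ann, r_min = r1, min_targets = t2)$pass)
    expect_lte(n_r2, n_r1)
    expect_lte(n_t2, n_r1)
  }
})
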