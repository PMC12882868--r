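test_that("funnel flags are monotone and the final verdict is their conjunction", {
  fam <- c("m1", "m2", "m3", "m4")
  sl <- data.frame(gene_id = c("m1", "m2"), pass = c(TRUE, FALSE))
  pref <- data.frame(gene = "m1", verdict = TRUE)
  rep1 <- run_funnel(fam, atlas_candidates = c("m1", "m2", "m3"),
                     internode_candidates = c("m1", "m2"),
                     shortlist = sl, preferential = pref)
  tab <- rep1$table
  expect_identical(tab$gene_id[tab$final_candidate], "m1")
  expect_true(all(diff(unname(rep1$summary[c("in_family", "atlas_cocluster",
                                             "internode_pass", "shortlist_pass",
                                             "preferential_pass")])) <= 0))
  # a gene that passed internode but skipped atlas cannot pass downstream
  rep2 <- run_funnel(fam, atlas_candidates = "m1",
                     internode_candidates = c("m1", "m4"),
                     shortlist = sl, preferential = pref)
  expect_false(rep2$table$internode_pass[rep2$table$gene_id == "m4"])
  # skipped stages are marked not evaluated, earlier counts unchanged
  rep3 <- run_funnel(fam, atlas_candidates = c("m1", "m2"),
                     internode_candidates = "m1",
                     shortlist = NULL, preferential = NULL)
  expect_true(is.na(rep3$summary[["shortlist_pass"]]))
  expect_true("shortlist" %in% rep3$diagnostics$not_evaluated)
  expect_equal(rep3$summary[["internode_pass"]], 1)
  # empty shortlist: zero final candidates, earlier counts unchanged
  rep4 <- run_funnel(fam, atlas_candidates = c("m1", "m2"),
                     internode_candidates = c("m1", "m2"),
                     shortlist = sl[0, ], preferential = NULL)
  expect_equal(rep4$summary[["final_candidate"]], 0)
  expect_equal(rep4$summary[["atlas_cocluster"]], 2)
  expect_error(run_funnel(c("m1", "m1"), atlas_candidates = "m1",
                          internode_candidates = "m1"), "collision")
})

test_that("a gene absent from the internode matrix fails that stage and is reported", {
  m <- rbind(tb = c(1, 2, 8, 10), m1 = c(1, 2, 9, 10))
  colnames(m) <- c("MsZ", "CEZ", "TZ", "MZ")
  sel <- internode_stage(m, "tb", c("m1", "m_gone"), mode = "peak_zone")
  rep <- run_funnel(c("m1", "m_gone"), atlas_candidates = c("m1", "m_gone"),
                    internode_candidates = sel$candidates,
                    internode_missing = sel$missing)
  expect_false(rep$table$internode_pass[rep$table$gene_id == "m_gone"])
  expect_identical(rep$diagnostics$internode_missing, "m_gone")
})

test_that("configuration validates parameter ranges", {
  expect_error(funnel_config(r_min = 1.01), "r_min")
  expect_error(funnel_config(alpha = 0), "alpha")
  expect_error(funnel_config(gap_threshold = 0), "gap_threshold")
  cfg <- funnel_config()
  expect_equal(cfg$r_min, 0.85)
  expect_equal(cfg$tandem_gap_bp, 50000)
  expect_equal(cfg$min_targets, 11)
})

test_that("writers and readers round-trip every format losslessly", {
  dir <- withr::local_tempdir()
  set.seed(60)
  m <- matrix(round(rexp(20), 6), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  p <- file.path(dir, "m.tsv")
  write_expression_matrix(m, p)
  expect_equal(read_expression_matrix(p), m)
  models <- data.frame(gene_id = c("a", "b"), chromosome = c("chr1", "chr2"),
                       start = c(100, 1), end = c(400, 1), strand = c("+", "-"))
  gp <- file.path(dir, "g.gff3")
  write_gene_models_gff3(models, gp)
  back <- read_gene_models_gff3(gp)
  expect_equal(back[order(back$gene_id), ], models, ignore_attr = TRUE)
  # zero-length gene (start == end) accepted as 1 bp
  expect_equal(back$start[back$gene_id == "b"], back$end[back$gene_id == "b"])
  # non-numeric matrix cell errors with row/column named
  writeLines(c("gene_id\ts1\ts2", "g1\t1.5\toops"), file.path(dir, "bad.tsv"))
  expect_error(read_expression_matrix(file.path(dir, "bad.tsv")),
               "row 'g1', column 's2'")
})

test_that("the file-level pipeline reproduces the planted truth and reruns byte-identically", {
  dir <- withr::local_tempdir()
  g <- gen_family_genome(17, 6, 2, 25, list(list("chr2", 3, 30000)), seed = 42,
                         dir = file.path(dir, "genome"))
  fam_truth <- g$truth$entity_id[g$truth$role == "r2r3_family"]
  regulators <- fam_truth[1:5]
  toolbox <- sprintf("TOOLBOX_%02d", 1:14)
  decoys <- sprintf("LACPRX_%02d", 1:20)
  e <- gen_expression_data(c(g$truth$entity_id, toolbox, decoys), 39, 4, 5,
                           toolbox, regulators, 0.9, 0.3, seed = 43,
                           dir = file.path(dir, "expr"), decoy_ids = decoys)
  v <- gen_validation_fixtures(regulators, effect_fold = 8, n_reps = 4, seed = 44,
                               dir = file.path(dir, "valid"))
  ann_path <- file.path(dir, "annotation.tsv")
  write.table(data.frame(
    gene_id = c(toolbox, decoys, regulators),
    category = c(rep("lignin_biosynthesis", 14), rep("lignin_related", 25)),
    is_toolbox = c(rep(TRUE, 14), rep(FALSE, 25))),
    ann_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- funnel_config(log2p1 = TRUE, inputs = list(
    proteome_fasta = g$proteome_fasta, gene_models_gff3 = g$gene_models_gff3,
    atlas_tsv = e$atlas_tsv, internode_tsv = e$internode_tsv,
    annotation_tsv = ann_path, toolbox_ids = toolbox,
    ct_tsv = v$ct_tsv, reference_genes = v$reference_genes,
    target_tissue = v$target_tissue, luciferase_tsv = v$luc_tsv,
    control_effector = v$control_effector))
  out1 <- file.path(dir, "run1"); out2 <- file.path(dir, "run2")
  res <- run_pipeline(cfg, out_dir = out1)
  expect_setequal(res$report$stages$final_candidate, regulators)
  expect_setequal(res$family$protein_id, fam_truth)
  expect_equal(res$tandem$n_tandem, 3)
  expect_true(file.exists(file.path(out1, "funnel_report.json")))
  expect_true(all(c("inputs", "config", "tool_version") %in%
                    names(unclass(res$manifest))))
  res2 <- run_pipeline(cfg, out_dir = out2)
  expect_identical(readLines(file.path(out1, "funnel_report.json")),
                   readLines(file.path(out2, "funnel_report.json")))
  expect_identical(readLines(file.path(out1, "candidates.tsv")),
                   readLines(file.path(out2, "candidates.tsv")))
  # config errors surface before computation
  expect_error(run_pipeline(funnel_config(inputs = list())), "missing mandatory")
})

test_that("yaml configs drive the pipeline and bad thresholds fail fast", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("r_min: 1.01"), yml)
  expect_error(run_pipeline(yml), "r_min")
})
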