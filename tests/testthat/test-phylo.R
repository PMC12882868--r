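test_that("center-star alignment handles the textbook cases and round-trips", {
  a <- build_msa(c(x = "ACD", y = "AD"))
  expect_identical(unclass(a)[["x"]], "ACD")
  expect_identical(unclass(a)[["y"]], "A-D")
  same <- build_msa(c(p = "MKV", q = "MKV", r = "MKV"))
  expect_false(any(grepl("-", unclass(same))))
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    seqs <- setNames(vapply(seq_len(n), function(i) rand_protein(sample(20:60, 1)), ""),
                     paste0("s", seq_len(n)))
    aln <- build_msa(seqs)
    expect_length(unique(nchar(unclass(aln))), 1)
    expect_identical(gsub("-", "", unclass(aln))[names(seqs)], seqs)
  }
  expect_error(build_msa(c(a = "ACD")), "at least 2")
})

test_that("gap-threshold trimming drops majority-gap columns with a 10% floor", {
  aln <- structure(c(a = "AC-D", b = "A--D", c = "AC-D", d = "A-CD"),
                   n_columns = 4L, class = "protein_msa")
  tr <- trim_alignment(aln)            # col3 gap frac 0.75 dropped; col2 0.5 kept
  expect_identical(attr(tr, "n_columns"), 3L)
  expect_identical(unclass(tr)[["b"]], "A-D")
  nogap <- build_msa(c(x = "MKVI", y = "MKVI"))
  expect_identical(unclass(trim_alignment(nogap)), unclass(nogap))
  # 10 columns all at gap fraction 0.6: the floor retains exactly one column
  rows <- c(r1 = paste(rep("A", 10), collapse = ""),
            r2 = paste(rep("A", 10), collapse = ""),
            r3 = paste(rep("-", 10), collapse = ""),
            r4 = paste(rep("-", 10), collapse = ""),
            r5 = paste(rep("-", 10), collapse = ""))
  aln60 <- structure(rows, n_columns = 10L, class = "protein_msa")
  expect_identical(attr(trim_alignment(aln60), "n_columns"), 1L)
  # idempotent when the floor is not triggered; never grows
  tr2 <- trim_alignment(tr)
  expect_identical(unclass(tr2), unclass(tr))
  expect_lte(attr(tr, "n_columns"), attr(aln, "n_columns"))
})

test_that("neighbor joining reproduces the 3-taxon closed form and star degeneracy", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_from_dist(d)
  lens <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                   tr$tip.label[tr$edge[, 2][tr$edge[, 2] <= 3]])
  expect_equal(lens[c("a", "b", "c")], c(a = 1, b = 1, c = 3))
  ident <- build_msa(c(u = "MKVI", v = "MKVI", w = "MKVI"))
  star <- nj_tree(ident)
  expect_equal(sum(star$edge.length), 0)
  expect_error(nj_from_dist(d[1:2, 1:2]), "at least 3")
  gappy <- structure(c(a = "AC--", b = "AC--", c = "--GT"),
                     n_columns = 4L, class = "protein_msa")
  expect_error(nj_tree(gappy), "incomparable")
})

test_that("neighbor joining recovers the generating topology of additive matrices", {
  set.seed(202)
  for (i in 1:50) {
    t0 <- ape::rtree(sample(5:12, 1))
    d0 <- stats::cophenetic(t0)
    tr <- nj_from_dist(d0)
    expect_equal(phangorn::RF.dist(ape::unroot(t0), tr), 0)
  }
})

test_that("bootstrap supports are deterministic and degenerate correctly at one replicate", {
  set.seed(33)
  base1 <- rand_protein(60); base2 <- rand_protein(60)
  seqs <- c(a = mutate_string(base1, 0.05), b = mutate_string(base1, 0.05),
            c = mutate_string(base2, 0.05), d = mutate_string(base2, 0.05))
  aln <- build_msa(seqs)
  b1 <- bootstrap_support(aln, n_replicates = 100, seed = 4)
  b2 <- bootstrap_support(aln, n_replicates = 100, seed = 4)
  expect_identical(b1$node.label, b2$node.label)
  sup <- suppressWarnings(as.numeric(b1$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95)  # long internal branch: near-full support
  one <- bootstrap_support(aln, n_replicates = 1, seed = 4)
  sup1 <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))
})

test_that("subgroup assignment follows majority labels in the smallest supported clade", {
  # query sister to one reference
  tr <- ape::read.tree(text = "((q1:0.1,r1:0.1)100:0.5,(r2:0.1,r3:0.1)100:0.5);")
  asg <- assign_subgroups(tr, c(r1 = "S3", r2 = "S14", r3 = "S14"))
  expect_identical(asg$subgroup[asg$query_id == "q1"], "S3")
  # majority wins
  tr2 <- ape::read.tree(
    text = "((((q1:0.1,r1:0.1):0.1,r2:0.1):0.1,r3:0.1):0.4,(r4:0.1,r5:0.1):0.4);")
  asg2 <- assign_subgroups(tr2, c(r1 = "S3", r2 = "S3", r3 = "S21",
                                  r4 = "X", r5 = "X"))
  expect_identical(asg2$subgroup, "S3")
  # low support pushes the walk outward
  tr3 <- ape::read.tree(text = "((q1:0.1,r1:0.1)10:0.5,(r2:0.1,r3:0.1)100:0.5);")
  asg3 <- assign_subgroups(tr3, c(r1 = "S3", r2 = "S3", r3 = "S3"),
                           min_support = 50)
  expect_identical(asg3$subgroup, "S3")
  expect_gt(asg3$clade_size, 2)
  expect_error(assign_subgroups(tr, c(zz = "S1")), "no labeled reference")
})

test_that("simulated subgroup families are classified correctly at 10% mutation", {
  n_correct <- 0; n_total <- 0
  for (seed in 1:20) {
    set.seed(seed)
    founders <- replicate(4, rand_protein(80))
    seqs <- character(0)
    labels <- character(0)
    for (sg in 1:4) {
      for (k in 1:2) {
        seqs[paste0("ref", sg, "_", k)] <- mutate_string(founders[sg], 0.10)
        labels[paste0("ref", sg, "_", k)] <- paste0("S", sg)
      }
      seqs[paste0("query", sg)] <- mutate_string(founders[sg], 0.10)
    }
    aln <- trim_alignment(build_msa(seqs))
    tree <- nj_tree(aln)
    asg <- assign_subgroups(tree, labels)
    truth <- paste0("S", sub("query", "", asg$query_id))
    n_correct <- n_correct + sum(asg$subgroup == truth)
    n_total <- n_total + nrow(asg)
  }
  expect_gte(n_correct / n_total, 0.90)
})

test_that("subgroup assignment is invariant under leaf-order permutation", {
  set.seed(55)
  founders <- replicate(3, rand_protein(60))
  seqs <- c(r1 = mutate_string(founders[1], 0.1), r2 = mutate_string(founders[1], 0.1),
            q1 = mutate_string(founders[1], 0.1),
            r3 = mutate_string(founders[2], 0.1), q2 = mutate_string(founders[2], 0.1),
            r4 = mutate_string(founders[3], 0.1), q3 = mutate_string(founders[3], 0.1))
  labels <- c(r1 = "A", r2 = "A", r3 = "B", r4 = "C")
  ref <- assign_subgroups(nj_tree(build_msa(seqs)), labels)
  ref <- ref[order(ref$query_id), ]
  for (i in 1:3) {
    perm <- sample(seqs)
    got <- assign_subgroups(nj_tree(build_msa(perm)), labels)
    got <- got[order(got$query_id), ]
    expect_identical(got$subgroup, ref$subgroup)
  }
})
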