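# Independent oracles and small fixture builders shared across tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

mutate_string <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  for (p in which(runif(length(ch)) < rate)) {
    ch[p] <- sample(setdiff(AA20, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# Plain double-loop window scorer + greedy overlap resolution, written
# independently of the package's vectorized scanner.
oracle_scan <- function(sequence, pssm) {
  ch <- strsplit(sequence, "")[[1]]
  w <- pssm$width
  if (length(ch) < w) return(data.frame(start = integer(0), end = integer(0),
                                        score = numeric(0)))
  n_win <- length(ch) - w + 1L
  sc <- numeric(n_win)
  for (p in seq_len(n_win)) {
    s <- 0
    for (j in seq_len(w)) {
      a <- ch[p + j - 1L]
      if (a %in% rownames(pssm$scores)) s <- s + pssm$scores[a, j]
    }
    sc[p] <- s
  }
  cand <- which(sc >= pssm$threshold)
  cand <- cand[order(-sc[cand], cand)]
  occupied <- rep(FALSE, length(ch))
  keep <- integer(0)
  for (p in cand) {
    if (!any(occupied[p:(p + w - 1L)])) {
      occupied[p:(p + w - 1L)] <- TRUE
      keep <- c(keep, p)
    }
  }
  keep <- sort(keep)
  data.frame(start = keep - 1L, end = keep - 1L + w, score = sc[keep])
}

# All-pairs tandem linkage + transitive closure, independent of the sweep.
oracle_tandem <- function(models, max_gap_bp) {
  n <- nrow(models)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (models$chromosome[i] != models$chromosome[j]) next
    up <- if (models$start[i] <= models$start[j]) i else j
    dn <- if (up == i) j else i
    gap <- max(0, models$start[dn] - models$end[up])
    if (gap <= max_gap_bp) adj[i, j] <- TRUE
  }
  # transitive closure
  repeat {
    new <- adj | (adj %*% adj > 0)
    if (identical(new, adj)) break
    adj <- new
  }
  comp <- rep(NA_integer_, n)
  cc <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cc <- cc + 1L
    members <- unique(c(i, which(adj[i, ])))
    comp[members] <- cc
  }
  split(models$gene_id, comp)
}

# Textbook two-pass Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Random family gene layout on a couple of chromosomes.
random_layout <- function(n) {
  data.frame(
    gene_id = sprintf("g%02d", seq_len(n)),
    chromosome = sample(c("chr1", "chr2", "chr3"), n, replace = TRUE),
    start = s <- sample.int(500000, n),
    end = s + sample.int(5000, n),
    strand = "+")
}

tandem_sets <- function(res) {
  lapply(res$clusters, function(cl) sort(cl$members))
}

# Shared end-to-end synthetic funnel run; returns truth and the report.
run_synthetic_funnel <- function(seed, with_validation = TRUE) {
  g <- gen_family_genome(17, 6, 2, 25, list(list("chr2", 3, 30000)), seed = seed)
  proteome <- read_proteome_fasta(g$proteome_fasta)
  fam_truth <- g$truth$entity_id[g$truth$role == "r2r3_family"]
  regulators <- fam_truth[1:5]
  toolbox <- sprintf("TOOLBOX_%02d", 1:14)
  decoys <- sprintf("LACPRX_%02d", 1:20)  # lignin-related non-family co-members
  genes <- c(g$truth$entity_id, toolbox, decoys)
  e <- gen_expression_data(genes, 39, 4, 5, toolbox, regulators,
                           r_within = 0.9, r_background = 0.3, seed = seed + 1,
                           decoy_ids = decoys)
  pssm <- build_repeat_pssm()
  family <- identify_family(proteome, pssm)
  fam_ids <- family$protein_id
  sc <- suppressWarnings(unit_variance_scale(e$atlas))
  cl <- cluster_rows(sc, k = 5)
  atlas_sel <- suppressWarnings(select_cocluster_candidates(cl, toolbox, fam_ids))
  inter_sel <- internode_stage(e$internode, toolbox, fam_ids)
  ann <- category_annotation(data.frame(
    gene_id = c(toolbox, decoys, regulators),
    category = c(rep("lignin_biosynthesis", length(toolbox)),
                 rep("lignin_related", length(decoys) + length(regulators))),
    is_toolbox = c(rep(TRUE, length(toolbox)),
                   rep(FALSE, length(decoys) + length(regulators)))))
  # screen on the log2 scale: the generator plants its correlations there
  shortlist <- shortlist_candidates(
    intersect(atlas_sel$candidates, inter_sel$candidates), e$atlas, ann,
    log2p1 = TRUE)
  preferential <- NULL
  if (with_validation) {
    v <- gen_validation_fixtures(shortlist$gene_id[shortlist$pass],
                                 effect_fold = 8, n_reps = 4, seed = seed + 2)
    re <- relative_expression(v$ct, v$reference_genes)
    preferential <- preferential_call(re, v$target_tissue)
  }
  report <- run_funnel(fam_ids,
                       atlas_candidates = atlas_sel$candidates,
                       internode_candidates = inter_sel$candidates,
                       internode_missing = inter_sel$missing,
                       shortlist = shortlist, preferential = preferential)
  list(report = report, regulators = regulators, family_truth = fam_truth,
       toolbox = toolbox, truth = g$truth, expr = e)
}
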