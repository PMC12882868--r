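# Synthetic-data generators: every pipeline input with known planted truth.
# The generators sample MYB repeats from the same bundled seed alignment as
# the scanner's PSSM, but through an independent mutation path, so recovery
# tests are not circular at nonzero noise.

SYNTH_CHROMOSOMES <- paste0("chr", 1:9)

mutate_seq <- function(chars, rate, protected = integer(0)) {
  n <- length(chars)
  mut <- which(stats::runif(n) < rate)
  mut <- setdiff(mut, protected)
  for (p in mut) chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
  chars
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

plant_repeats <- function(len, n_repeats, seed_rows, noise, gap_range = c(2, 10),
                          first_start_range = c(6, 40)) {
  chars <- strsplit(random_protein(len), "")[[1]]
  w <- nchar(seed_rows[1])
  start <- sample(first_start_range[1]:first_start_range[2], 1)
  starts <- integer(0)
  for (k in seq_len(n_repeats)) {
    rep_chars <- strsplit(sample(seed_rows, 1), "")[[1]]
    rep_chars <- mutate_seq(rep_chars, noise)
    chars[start:(start + w - 1L)] <- rep_chars
    starts <- c(starts, start)
    start <- start + w + sample(gap_range[1]:gap_range[2], 1)
  }
  list(sequence = paste(chars, collapse = ""), starts = starts - 1L)
}

#' Generate a synthetic proteome and genome with planted family structure
#'
#' Produces a proteome FASTA, a gene-model GFF3 and a truth table in which
#' `n_r2r3` proteins carry exactly two MYB repeats in the N-terminal window,
#' `n_single` carry one, `n_triple` carry three, and `n_background` carry
#' none. Repeats are sampled from the bundled seed alignment with
#' per-position substitution noise. Gene coordinates realize the requested
#' tandem arrays (family genes with exact intra-array gaps); all other genes
#' are spaced 200 kb apart across the nine chromosomes. Identical arguments
#' and seed give byte-identical files.
#'
#' @param n_r2r3,n_single,n_triple,n_background Entity counts (>= 0).
#' @param tandem_spec List of `list(chromosome, array_size, intra_gap_bp)`
#'   tandem arrays of family genes; chromosomes must be chr1..chr9.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param noise Per-position substitution rate inside planted repeats.
#' @return List with paths `proteome_fasta`, `gene_models_gff3`, `truth_json`
#'   and the `truth` data.frame (entity_id, role, planted_cluster,
#'   planted_params).
#' @export
gen_family_genome <- function(n_r2r3, n_single, n_triple, n_background,
                              tandem_spec = list(), seed, dir = tempfile("synthgenome"),
                              noise = 0.05) {
  counts <- c(n_r2r3, n_single, n_triple, n_background)
  if (any(counts < 0)) stop("negative counts")
  for (ts in tandem_spec) {
    if (!ts[[1]] %in% SYNTH_CHROMOSOMES) {
      stop("tandem array on an undeclared chromosome: ", ts[[1]])
    }
    if (ts[[3]] <= 0) stop("intra_gap_bp must be > 0")
  }
  n_in_arrays <- sum(vapply(tandem_spec, function(ts) as.integer(ts[[2]]), integer(1)))
  if (n_in_arrays > n_r2r3) stop("tandem arrays require more family genes than n_r2r3")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  seed_rows <- unname(myb_seed_alignment())

  ids <- c(if (n_r2r3 > 0) sprintf("SYNR2R3_%03d", seq_len(n_r2r3)),
           if (n_single > 0) sprintf("SYN1R_%03d", seq_len(n_single)),
           if (n_triple > 0) sprintf("SYN3R_%03d", seq_len(n_triple)),
           if (n_background > 0) sprintf("SYNBG_%03d", seq_len(n_background)))
  roles <- rep(c("r2r3_family", "single_repeat", "triple_repeat", "background"),
               counts)
  n_rep <- c(r2r3_family = 2L, single_repeat = 1L, triple_repeat = 3L,
             background = 0L)[roles]
  seqs <- character(length(ids))
  starts <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    len <- sample(250:350, 1)
    if (n_rep[i] == 0L) {
      seqs[i] <- random_protein(len)
      starts[[i]] <- integer(0)
    } else {
      pr <- plant_repeats(len, n_rep[i], seed_rows, noise)
      seqs[i] <- pr$sequence
      starts[[i]] <- pr$starts
    }
  }

  # genomic layout: tandem arrays take the first family genes, in spec order
  chrom <- character(length(ids))
  gstart <- numeric(length(ids))
  gend <- numeric(length(ids))
  gene_len <- 3000
  next_family <- 1L
  array_of <- rep(NA_integer_, length(ids))
  array_offset <- stats::setNames(rep(100000, 9), SYNTH_CHROMOSOMES)
  for (ai in seq_along(tandem_spec)) {
    ts <- tandem_spec[[ai]]
    pos <- array_offset[[ts[[1]]]]
    array_offset[[ts[[1]]]] <- pos + 1e6
    for (k in seq_len(as.integer(ts[[2]]))) {
      i <- next_family
      chrom[i] <- ts[[1]]
      gstart[i] <- pos
      gend[i] <- pos + gene_len - 1
      pos <- gend[i] + as.numeric(ts[[3]])  # so start_next - end = intra_gap_bp
      array_of[i] <- ai
      next_family <- next_family + 1L
    }
  }
  loose <- which(chrom == "")
  # spread remaining genes 200 kb apart, round-robin over chromosomes,
  # starting far from any tandem array
  offset <- stats::setNames(rep(5e6, 9), SYNTH_CHROMOSOMES)
  for (i in loose) {
    cc <- SYNTH_CHROMOSOMES[(i %% 9) + 1]
    chrom[i] <- cc
    gstart[i] <- offset[cc]
    gend[i] <- offset[cc] + gene_len - 1
    offset[cc] <- offset[cc] + 200000
  }

  truth <- data.frame(
    entity_id = ids, role = roles,
    planted_cluster = rep(NA_integer_, length(ids)),
    n_planted_repeats = n_rep,
    repeat_starts = vapply(starts, paste, character(1), collapse = ","),
    tandem_array = array_of,
    chromosome = chrom, start = gstart, end = gend)
  truth$role[!is.na(array_of)] <- "r2r3_family"  # tandem members stay family

  fasta <- file.path(dir, "proteome.fasta")
  gff3 <- file.path(dir, "genes.gff3")
  tj <- file.path(dir, "truth.json")
  if (length(ids)) {
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(stats::setNames(seqs, ids)), fasta)
    write_gene_models_gff3(
      data.frame(gene_id = ids, chromosome = chrom, start = gstart,
                 end = gend, strand = "+"), gff3)
  } else {
    writeLines(character(0), fasta)
    writeLines("##gff-version 3", gff3)
  }
  jsonlite::write_json(truth, tj, dataframe = "rows", na = "null", digits = NA)
  list(proteome_fasta = fasta, gene_models_gff3 = gff3, truth_json = tj,
       truth = truth)
}

#' Generate synthetic atlas and internode expression matrices
#'
#' Plants `k_planted` co-expression clusters in an atlas matrix via nested
#' latent factors: per sample, `x_g = sqrt(r_bg) g0 + sqrt(r_w - r_bg) f_c +
#' sqrt(1 - r_w) eps_g`, so two genes sharing a cluster have expected Pearson
#' correlation `r_within` on the log scale while any cross-cluster pair sits
#' at the `r_background` baseline. Cluster 1 holds all toolbox genes and
#' planted regulators; the remaining genes fill clusters 2..k round-robin.
#' Values are exponentiated
#' as `2^(x/2 + offset)` into positive TPM-like units; the mild dynamic range
#' keeps the raw-scale Pearson correlation of planted pairs close to the
#' latent value. The internode matrix has the four zone columns (MsZ, CEZ,
#' TZ, MZ); cluster-1 genes rise bottom-to-top and peak in TZ or MZ, all
#' others fall.
#'
#' @param genes Character vector of gene ids.
#' @param n_samples_atlas Number of atlas samples (>= 3; the study-scale
#'   default is 39).
#' @param n_zones Number of internode zones (must be 4).
#' @param k_planted Number of planted clusters (>= 2).
#' @param toolbox_ids,regulator_ids Subsets of `genes` planted into cluster 1.
#' @param decoy_ids Further genes planted into cluster 1 (e.g. non-family
#'   lignin-related genes such as laccases and peroxidases that co-express
#'   with the toolbox in real atlases); disjoint from the other planted sets.
#' @param r_within,r_background Latent within-cluster correlations,
#'   `0 <= r_background < r_within <= 1`.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return List with paths `atlas_tsv`, `internode_tsv`, `truth_json`, the
#'   matrices `atlas` and `internode`, and the `truth` data.frame.
#' @export
gen_expression_data <- function(genes, n_samples_atlas = 39, n_zones = 4,
                                k_planted = 5, toolbox_ids, regulator_ids,
                                r_within = 0.9, r_background = 0.3, seed,
                                dir = tempfile("synthexpr"), decoy_ids = NULL) {
  if (!(r_background >= 0 && r_background < r_within && r_within <= 1)) {
    stop("require 0 <= r_background < r_within <= 1")
  }
  if (n_samples_atlas < 3) stop("n_samples_atlas must be >= 3")
  if (n_zones != 4) stop("n_zones must be 4 (MsZ, CEZ, TZ, MZ)")
  if (k_planted < 2) stop("k_planted must be >= 2")
  if (!all(toolbox_ids %in% genes) || !all(regulator_ids %in% genes)) {
    stop("toolbox and regulator ids must be a subset of genes")
  }
  if (length(intersect(toolbox_ids, regulator_ids))) {
    stop("regulator ids overlap toolbox ids")
  }
  if (!all(decoy_ids %in% genes) ||
      length(intersect(decoy_ids, c(toolbox_ids, regulator_ids)))) {
    stop("decoy ids must be genes outside the toolbox and regulator sets")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  planted <- c(toolbox_ids, regulator_ids, decoy_ids)
  rest <- setdiff(genes, planted)
  cluster <- stats::setNames(integer(length(genes)), genes)
  cluster[planted] <- 1L
  if (length(rest)) {
    pool <- if (k_planted > 1) 2:k_planted else 1
    cluster[rest] <- rep(pool, length.out = length(rest))
  }

  n <- n_samples_atlas
  global <- stats::rnorm(n)
  factors <- matrix(stats::rnorm(k_planted * n), k_planted, n)
  x <- matrix(0, length(genes), n, dimnames = list(genes, NULL))
  for (g in genes) {
    cl <- cluster[[g]]
    x[g, ] <- sqrt(r_background) * global +
      sqrt(r_within - r_background) * factors[cl, ] +
      sqrt(1 - r_within) * stats::rnorm(n)
  }
  offsets <- stats::runif(length(genes), 3, 7)
  atlas <- 2^(x / 2 + offsets)
  colnames(atlas) <- sprintf("sample_%02d", seq_len(n))

  up <- c(0, 0.5, 3, 3.5); down <- rev(up)
  mu <- matrix(0, length(genes), 4, dimnames = list(genes, INTERNODE_ZONES))
  for (g in genes) {
    base <- if (cluster[[g]] == 1L) up else down
    if (cluster[[g]] == 1L && stats::runif(1) < 0.5) base <- c(0, 0.5, 3.5, 3)
    mu[g, ] <- base + stats::rnorm(4, sd = 0.2)
  }
  internode <- 2^(mu + stats::runif(length(genes), 1, 3))

  truth <- data.frame(
    entity_id = genes,
    role = ifelse(genes %in% regulator_ids, "planted_regulator",
                  ifelse(genes %in% toolbox_ids, "toolbox", "background")),
    is_decoy = genes %in% decoy_ids,
    planted_cluster = as.integer(cluster[genes]),
    r_within = r_within, r_background = r_background)

  atlas_tsv <- file.path(dir, "atlas.tsv")
  internode_tsv <- file.path(dir, "internode.tsv")
  tj <- file.path(dir, "truth.json")
  write_expression_matrix(atlas, atlas_tsv)
  write_expression_matrix(internode, internode_tsv)
  jsonlite::write_json(truth, tj, dataframe = "rows", na = "null", digits = NA)
  list(atlas_tsv = atlas_tsv, internode_tsv = internode_tsv, truth_json = tj,
       atlas = atlas, internode = internode, truth = truth)
}

#' Generate synthetic qPCR and luciferase validation fixtures
#'
#' Ct table: 4 tissues x `n_reps` replicates x (candidates + 2 reference
#' genes). Reference genes sit near Ct 20 in every tissue; candidate targets
#' sit near Ct 26 except in the top internode, where their Ct is lowered by
#' log2(`effect_fold`) so their relative expression is `effect_fold`-times
#' higher. Luciferase table: fLUC and rLUC per replicate for each candidate
#' effector and a GUS control, with candidate fLUC/rLUC ratios
#' `effect_fold`-times the control's.
#'
#' @param candidate_ids Candidate gene/effector ids.
#' @param effect_fold Planted fold change (> 0; 1 = null).
#' @param n_reps Biological replicates (>= 2).
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param ct_noise_sd,luc_noise_sd Gaussian noise on Ct cycles / log2 ratios.
#' @return List with paths `ct_tsv`, `luc_tsv`, `truth_json`, tables `ct` and
#'   `luciferase`, `reference_genes`, `control_effector`, `target_tissue`.
#' @export
gen_validation_fixtures <- function(candidate_ids, effect_fold = 8, n_reps = 4,
                                    seed, dir = tempfile("synthvalid"),
                                    ct_noise_sd = 0.15, luc_noise_sd = 0.2) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (effect_fold <= 0) stop("effect_fold must be > 0")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  tissues <- c("young_root", "young_leaf", "internode_bottom", "internode_top")
  refs <- c("CUL", "EF1a")
  grid <- expand.grid(gene = c(candidate_ids, refs), tissue = tissues,
                      replicate = seq_len(n_reps), stringsAsFactors = FALSE)
  base <- ifelse(grid$gene %in% refs, 20, 26)
  shift <- ifelse(!grid$gene %in% refs & grid$tissue == "internode_top",
                  log2(effect_fold), 0)
  grid$ct <- base - shift + stats::rnorm(nrow(grid), sd = ct_noise_sd)
  ct <- grid[order(grid$gene, grid$tissue, grid$replicate), ]
  rownames(ct) <- NULL

  effectors <- c(candidate_ids, "GUS")
  lgrid <- expand.grid(effector = effectors, replicate = seq_len(n_reps),
                       stringsAsFactors = FALSE)
  lgrid$rluc <- 2^(stats::rnorm(nrow(lgrid), mean = 10, sd = 0.3))
  base_ratio <- ifelse(lgrid$effector == "GUS", 1, effect_fold)
  lgrid$fluc <- lgrid$rluc * base_ratio *
    2^(stats::rnorm(nrow(lgrid), sd = luc_noise_sd))
  luc <- lgrid[order(lgrid$effector, lgrid$replicate), ]
  rownames(luc) <- NULL

  truth <- data.frame(entity_id = candidate_ids, role = "planted_regulator",
                      planted_cluster = NA_integer_, effect_fold = effect_fold)
  ct_tsv <- file.path(dir, "ct.tsv")
  luc_tsv <- file.path(dir, "luciferase.tsv")
  tj <- file.path(dir, "truth.json")
  utils::write.table(ct, ct_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(luc, luc_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truth, tj, dataframe = "rows", na = "null", digits = NA)
  list(ct_tsv = ct_tsv, luc_tsv = luc_tsv, truth_json = tj,
       ct = ct, luciferase = luc, reference_genes = refs,
       control_effector = "GUS", target_tissue = "internode_top")
}
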