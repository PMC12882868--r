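# Readers and writers for the standard formats, plus the run manifest and the
# end-to-end pipeline driver. External coordinates are GFF3 1-based inclusive;
# repeat-hit coordinates inside the package are 0-based half-open and are
# converted at this boundary only.

#' Read a proteome FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector of sequences.
#' @export
read_proteome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aln <- Biostrings::readAAStringSet(path)
  if (length(aln) && (is.null(names(aln)) || any(names(aln) == ""))) {
    stop("malformed FASTA record: missing id")
  }
  # keep only the first whitespace-delimited token of each header
  stats::setNames(as.character(aln), sub("\\s.*$", "", names(aln)))
}

#' Read gene models from GFF3
#'
#' Keeps `type == "gene"` records and requires an `ID` attribute. A
#' zero-length gene (start == end) is accepted as a 1-bp feature.
#'
#' @param path GFF3 file.
#' @return data.frame with `gene_id`, `chromosome`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates).
#' @export
read_gene_models_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gff <- as.data.frame(rtracklayer::readGFF(path))
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) {
    return(data.frame(gene_id = character(0), chromosome = character(0),
                      start = numeric(0), end = numeric(0), strand = character(0)))
  }
  if (is.null(genes$ID) || anyNA(genes$ID)) stop("GFF3 gene record without ID attribute")
  data.frame(gene_id = as.character(genes$ID),
             chromosome = as.character(genes$seqid),
             start = as.numeric(genes$start),
             end = as.numeric(genes$end),
             strand = as.character(genes$strand))
}

#' Write gene models as GFF3
#'
#' @param models data.frame with `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$chromosome,
    ranges = IRanges::IRanges(start = models$start, end = models$end),
    strand = models$strand)
  gr$ID <- models$gene_id
  gr$type <- "gene"
  gr$source <- "mybfunnel"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' First column = gene ids, header row = sample ids. Non-numeric cells are an
#' error naming the offending row and column; duplicate gene ids are an
#' error.
#'
#' @param path TSV file.
#' @return Numeric matrix, genes in rows.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (anyDuplicated(df[[1]])) stop("duplicate gene ids in matrix")
  ids <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) & vals[[j]] != "NA")
    if (length(bad)) {
      stop("non-numeric cell at row '", ids[bad[1]], "', column '",
           colnames(vals)[j], "': ", vals[[j]][bad[1]])
    }
    m[, j] <- v
  }
  m
}

#' Write an expression matrix TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_column Header for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df) <- c(id_column, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene -> functional-category annotation TSV
#'
#' @param path TSV with columns `gene_id`, `category` and optional flag
#'   columns.
#' @return A [category_annotation()].
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (fl in NOTE_FLAGS) if (!is.null(df[[fl]])) df[[fl]] <- as.logical(df[[fl]])
  category_annotation(df)
}

#' Write a tree with support values as newick
#'
#' @param tree `ape::phylo` (internal-node labels carry supports).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Build a run manifest
#'
#' Records input paths with md5 checksums, the configuration snapshot, the
#' package version, a timestamp and accumulated warnings, so every report can
#' be traced to the exact inputs and settings that produced it.
#'
#' @param inputs Named character vector of input file paths.
#' @param config A [funnel_config()].
#' @param warnings Character vector of warnings raised during the run.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(inputs, config, warnings = character(0)) {
  files <- data.frame(
    name = names(inputs), path = unname(unlist(inputs)),
    md5 = unname(tools::md5sum(unlist(inputs))))
  structure(list(inputs = files, config = unclass(config),
                 tool_version = as.character(utils::packageVersion("mybfunnel")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 warnings = warnings),
            class = "run_manifest")
}

#' Run the full candidate funnel from files
#'
#' Executes identify -> map -> atlas co-clustering -> internode stage ->
#' co-expression shortlist -> (optional) validation -> funnel over the input
#' files named in `config$inputs`, writes the per-stage TSV/JSON reports and
#' the run manifest under `out_dir`, and returns the funnel report. Subgroup
#' assignment runs when a reference-label TSV is supplied.
#'
#' @param config A [funnel_config()] whose `inputs` list names
#'   `proteome_fasta`, `gene_models_gff3`, `atlas_tsv`, `internode_tsv`,
#'   `annotation_tsv`, `toolbox_ids` (character vector) and optionally
#'   `reference_labels_tsv`, `ct_tsv`, `luciferase_tsv`,
#'   `reference_genes`, `control_effector`, `target_tissue`. Alternatively a
#'   path to a YAML file with the same structure.
#' @param out_dir Output directory for reports.
#' @return List with `report` (the [run_funnel()] result), `family`,
#'   `names`, `tandem`, `manifest`, and the output paths.
#' @export
run_pipeline <- function(config, out_dir = tempfile("mybfunnel_run")) {
  if (is.character(config) && length(config) == 1L) {
    config <- do.call(funnel_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "funnel_config"))
  inputs <- config$inputs
  required <- c("proteome_fasta", "gene_models_gff3", "atlas_tsv",
                "internode_tsv", "annotation_tsv", "toolbox_ids")
  miss <- setdiff(required, names(inputs))
  if (length(miss)) stop("missing mandatory inputs: ", paste(miss, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warns <- character(0)
  wcollect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  proteome <- read_proteome_fasta(inputs$proteome_fasta)
  models <- read_gene_models_gff3(inputs$gene_models_gff3)
  atlas <- read_expression_matrix(inputs$atlas_tsv)
  internode <- read_expression_matrix(inputs$internode_tsv)
  ann <- read_annotation_tsv(inputs$annotation_tsv)
  toolbox <- inputs$toolbox_ids

  pssm <- build_repeat_pssm(threshold_fraction = config$pssm_threshold_fraction)
  family <- identify_family(proteome, pssm, nterm_limit = config$nterm_limit,
                            max_inter_repeat_gap = config$max_inter_repeat_gap)
  fam_ids <- family$protein_id
  if (length(setdiff(fam_ids, models$gene_id))) {
    stop("family ids lacking gene models: ",
         paste(utils::head(setdiff(fam_ids, models$gene_id)), collapse = ", "))
  }
  naming <- assign_family_names(fam_ids, models, prefix = config$name_prefix)
  tandem <- detect_tandem_clusters(models[models$gene_id %in% fam_ids, , drop = FALSE],
                                   max_gap_bp = config$tandem_gap_bp)

  subgroups <- NULL
  if (!is.null(inputs$reference_labels_tsv) && !is.null(inputs$reference_fasta)) {
    lab <- utils::read.delim(inputs$reference_labels_tsv, stringsAsFactors = FALSE)
    ref_seqs <- read_proteome_fasta(inputs$reference_fasta)
    seqs <- c(ref_seqs, proteome[fam_ids])
    aln <- trim_alignment(build_msa(seqs), config$gap_threshold, config$min_conserve)
    tree <- bootstrap_support(aln, n_replicates = config$n_bootstrap,
                              seed = config$seed)
    write_tree_newick(tree, file.path(out_dir, "family_tree.nwk"))
    subgroups <- assign_subgroups(tree, stats::setNames(lab$subgroup, lab$gene_id),
                                  min_support = config$min_support)
  }

  scaled <- wcollect(unit_variance_scale(atlas))
  cl <- cluster_rows(scaled, k = config$k_atlas, distance = config$distance,
                     linkage = config$linkage)
  atlas_sel <- wcollect(select_cocluster_candidates(cl, toolbox, fam_ids))
  inter_sel <- wcollect(internode_stage(internode, toolbox, fam_ids,
                                        mode = config$internode_mode))
  shortlist <- wcollect(shortlist_candidates(
    intersect(atlas_sel$candidates, inter_sel$candidates), atlas, ann,
    r_min = config$r_min, min_targets = config$min_targets,
    log2p1 = config$log2p1))

  preferential <- NULL
  if (!is.null(inputs$ct_tsv)) {
    ct <- utils::read.delim(inputs$ct_tsv, stringsAsFactors = FALSE)
    re <- relative_expression(ct, inputs$reference_genes)
    preferential <- preferential_call(re, inputs$target_tissue,
                                      alpha = config$alpha)
  }
  transact <- NULL
  if (!is.null(inputs$luciferase_tsv)) {
    luc <- utils::read.delim(inputs$luciferase_tsv, stringsAsFactors = FALSE)
    transact <- transactivation_fold(luc, inputs$control_effector)
  }

  report <- run_funnel(
    family_ids = fam_ids, family_names = naming$names,
    atlas_candidates = atlas_sel$candidates,
    internode_candidates = inter_sel$candidates,
    internode_missing = inter_sel$missing,
    shortlist = shortlist, preferential = preferential,
    subgroups = subgroups, config = config)

  manifest <- run_manifest(
    inputs[vapply(inputs, function(x) is.character(x) && length(x) == 1 && file.exists(x),
                  logical(1))],
    config, warnings = warns)
  cfg_echo <- unclass(config)
  cfg_echo$inputs <- NULL
  jsonlite::write_json(
    list(config = cfg_echo, summary = as.list(report$summary),
         stages = report$stages, diagnostics = report$diagnostics),
    file.path(out_dir, "funnel_report.json"),
    dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(report$table, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(cl$labels), cluster = as.integer(cl$labels)),
    file.path(out_dir, "atlas_clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  list(report = report, family = family, names = naming, tandem = tandem,
       subgroups = subgroups, preferential = preferential,
       transactivation = transact, manifest = manifest, out_dir = out_dir)
}
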