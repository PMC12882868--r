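# Chromosome natural sort: "chr2" before "chr10"; names without a trailing
# number (scaffolds/contigs) sort after numbered chromosomes, alphabetically.
natural_chrom_order <- function(chroms) {
  num <- suppressWarnings(as.numeric(sub("^\\D*", "", chroms)))
  is_scaffold <- is.na(num) | grepl("scaffold|contig", chroms, ignore.case = TRUE)
  order(is_scaffold, num, chroms)
}

#' Name family members by chromosomal order
#'
#' Assigns sequential family names (`prefix1`, `prefix2`, ...) by walking the
#' chromosomes in natural-sort order (chr2 before chr10, scaffolds last) and
#' genes by ascending start within each chromosome, mirroring the convention
#' of numbering a plant TF family along its chromosomes.
#'
#' @param family_ids Character vector of family gene ids.
#' @param models data.frame of gene models with columns `gene_id`,
#'   `chromosome`, `start`, `end`, `strand`.
#' @param prefix Name prefix, e.g. `"SvMYB"`.
#' @return List with `names` (named character vector id -> family name) and
#'   `chromosome_counts` (named integer vector, natural-sort order).
#' @export
assign_family_names <- function(family_ids, models, prefix = "MYB") {
  if (anyDuplicated(family_ids)) stop("duplicate family ids")
  if (length(family_ids) == 0L) {
    return(list(names = stats::setNames(character(0), character(0)),
                chromosome_counts = stats::setNames(integer(0), character(0))))
  }
  m <- models[match(family_ids, models$gene_id), , drop = FALSE]
  if (anyNA(m$gene_id)) {
    stop("family ids lacking coordinates: ",
         paste(setdiff(family_ids, models$gene_id), collapse = ", "))
  }
  chrom_levels <- unique(m$chromosome)[natural_chrom_order(unique(m$chromosome))]
  ord <- order(match(m$chromosome, chrom_levels), m$start)
  m <- m[ord, , drop = FALSE]
  nm <- stats::setNames(paste0(prefix, seq_len(nrow(m))), m$gene_id)
  counts <- table(factor(m$chromosome, levels = chrom_levels))
  list(names = nm,
       chromosome_counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Detect tandem duplication clusters
#'
#' Two family genes are tandem-linked iff they lie on the same chromosome and
#' the gap between their closest edges, `max(0, start_downstream -
#' end_upstream)`, is at most `max_gap_bp` (inclusive). Clusters are connected
#' components of this relation (transitive chaining), computed by a sorted
#' sweep with a running maximum end coordinate; intervening non-family genes
#' are not considered.
#'
#' @param models data.frame of family gene models (`gene_id`, `chromosome`,
#'   `start`, `end`).
#' @param max_gap_bp Maximum edge-to-edge distance in bp (default 50 kb).
#' @return List with `clusters` (list of data.frames: `chromosome`, `members`,
#'   `gaps` between consecutive members), `tandem_genes` (character vector),
#'   `n_tandem`, and `fraction` (tandem genes / family size).
#' @export
detect_tandem_clusters <- function(models, max_gap_bp = 50000) {
  if (max_gap_bp <= 0) stop("max_gap_bp must be > 0")
  if (anyDuplicated(models$gene_id)) stop("duplicate coordinates for one id")
  clusters <- list()
  for (chrom in unique(models$chromosome)) {
    g <- models[models$chromosome == chrom, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    if (nrow(g) < 2L) next
    run_end <- g$end[1]
    comp <- 1L
    comp_id <- integer(nrow(g))
    comp_id[1] <- comp
    for (i in 2:nrow(g)) {
      gap <- max(0, g$start[i] - run_end)
      if (gap <= max_gap_bp) {
        comp_id[i] <- comp
        run_end <- max(run_end, g$end[i])
      } else {
        comp <- comp + 1L
        comp_id[i] <- comp
        run_end <- g$end[i]
      }
    }
    for (cc in unique(comp_id)) {
      idx <- which(comp_id == cc)
      if (length(idx) < 2L) next
      gg <- g[idx, , drop = FALSE]
      gaps <- pmax(0, gg$start[-1] - gg$end[-nrow(gg)])
      clusters[[length(clusters) + 1L]] <- list(
        chromosome = chrom, members = gg$gene_id, gaps = gaps)
    }
  }
  tandem_genes <- unlist(lapply(clusters, `[[`, "members"))
  if (is.null(tandem_genes)) tandem_genes <- character(0)
  list(clusters = clusters,
       tandem_genes = tandem_genes,
       n_tandem = length(tandem_genes),
       fraction = if (nrow(models) > 0) length(tandem_genes) / nrow(models) else NA_real_)
}
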