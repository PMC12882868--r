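# Pipeline configuration and the candidate funnel.

#' Pipeline configuration
#'
#' Bundles every numeric parameter of the funnel with its default: the
#' co-expression threshold (r >= 0.85), the 50-kb tandem rule, the alignment
#' trimming rule (gap threshold 0.5, conserve at least 10% of columns),
#' cluster counts for the atlas (5) and internode (2) heatmaps, the shortlist
#' rule (>= 11 target partners), the significance level (0.05), and the
#' repeat-scanner limits (N-terminal 200 aa, inter-repeat gap 30 aa, PSSM
#' threshold fraction 0.45). The config is serialized into every report for
#' provenance.
#'
#' @param r_min Inclusive Pearson threshold, in (-1, 1].
#' @param tandem_gap_bp Maximum tandem edge-to-edge distance (bp).
#' @param gap_threshold,min_conserve Alignment trimming parameters.
#' @param k_atlas,k_internode Cluster counts for the two stages.
#' @param min_targets Shortlist minimum target-category partner count.
#' @param alpha Significance level for validation statistics.
#' @param nterm_limit,max_inter_repeat_gap,pssm_threshold_fraction Repeat
#'   scanner parameters (residues / fraction).
#' @param n_bootstrap Bootstrap replicates for the subgroup tree.
#' @param min_support Minimum clade support for subgroup assignment.
#' @param distance,linkage Clustering distance and linkage.
#' @param internode_mode `"cocluster_with_terminal"` or `"peak_zone"`.
#' @param log2p1 Correlate on log2(x+1) in the co-expression screen.
#' @param name_prefix Family-name prefix.
#' @param seed Integer seed for any stochastic step (bootstrap).
#' @param inputs Named list of input paths/values for [run_pipeline()].
#' @return Object of class `funnel_config`.
#' @export
funnel_config <- function(r_min = 0.85, tandem_gap_bp = 50000,
                          gap_threshold = 0.5, min_conserve = 0.10,
                          k_atlas = 5, k_internode = 2, min_targets = 11,
                          alpha = 0.05, nterm_limit = 200,
                          max_inter_repeat_gap = 30,
                          pssm_threshold_fraction = 0.45,
                          n_bootstrap = 100, min_support = 50,
                          distance = "correlation", linkage = "average",
                          internode_mode = "cocluster_with_terminal",
                          log2p1 = FALSE, name_prefix = "MYB",
                          seed = 1, inputs = list()) {
  if (!(r_min > -1 && r_min <= 1)) stop("r_min must be in (-1, 1]")
  if (tandem_gap_bp <= 0) stop("tandem_gap_bp must be > 0")
  if (!(gap_threshold > 0 && gap_threshold <= 1)) stop("gap_threshold in (0, 1]")
  if (!(min_conserve > 0 && min_conserve <= 1)) stop("min_conserve in (0, 1]")
  if (k_atlas < 2 || k_internode < 2) stop("cluster counts must be >= 2")
  if (!(alpha > 0 && alpha < 1)) stop("alpha in (0, 1)")
  if (min_targets < 0) stop("min_targets must be >= 0")
  if (!(pssm_threshold_fraction > 0 && pssm_threshold_fraction < 1)) {
    stop("pssm_threshold_fraction in (0, 1)")
  }
  structure(as.list(environment()), class = "funnel_config")
}

#' @export
print.funnel_config <- function(x, ...) {
  cat("Funnel configuration:\n")
  for (nm in setdiff(names(x), "inputs")) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Combine all stages into the candidate funnel
#'
#' Applies set intersection in pipeline order (family -> atlas co-cluster ->
#' internode -> co-expression shortlist -> preferential expression) and
#' reports, per family gene, monotone stage flags whose conjunction is the
#' final-candidate verdict. A gene lacking data at a stage fails that stage
#' and is listed in the diagnostics; a stage given as `NULL` is skipped and
#' marked "not evaluated" (it neither passes nor fails anyone).
#'
#' @param family_ids Family member ids (stage 1 survivors).
#' @param family_names Named vector id -> family name (optional).
#' @param atlas_candidates Ids surviving the atlas co-cluster stage.
#' @param internode_candidates Ids surviving the internode stage.
#' @param internode_missing Ids absent from the internode matrix.
#' @param shortlist data.frame from [shortlist_candidates()], or `NULL` to
#'   skip.
#' @param preferential data.frame from [preferential_call()], or `NULL` to
#'   skip.
#' @param subgroups data.frame from [assign_subgroups()], or `NULL`.
#' @param config A [funnel_config()].
#' @return List of class `funnel_report`: `table` (per-gene flags),
#'   `summary` (survivor counts per stage), `stages` (surviving id sets),
#'   `diagnostics`, and the echoed `config`.
#' @export
run_funnel <- function(family_ids, family_names = NULL,
                       atlas_candidates, internode_candidates,
                       internode_missing = character(0),
                       shortlist = NULL, preferential = NULL,
                       subgroups = NULL, config = funnel_config()) {
  if (anyDuplicated(family_ids)) stop("id collision in family table")
  flag <- function(ids) family_ids %in% ids
  in_family <- rep(TRUE, length(family_ids))
  atlas_f <- flag(atlas_candidates) & in_family
  inter_f <- flag(internode_candidates) & atlas_f

  short_eval <- !is.null(shortlist)
  short_f <- if (short_eval) flag(shortlist$gene_id[shortlist$pass]) & inter_f else inter_f
  pref_eval <- !is.null(preferential)
  pref_f <- if (pref_eval) flag(preferential$gene[preferential$verdict]) & short_f else short_f
  final <- pref_f

  sub_of <- function(ids) {
    if (is.null(subgroups)) return(rep(NA_character_, length(ids)))
    subgroups$subgroup[match(ids, subgroups$query_id)]
  }
  nm_of <- function(ids) {
    if (is.null(family_names)) return(ids)
    out <- unname(family_names[ids])
    ifelse(is.na(out), ids, out)
  }
  table <- data.frame(
    gene_id = family_ids,
    family_name = nm_of(family_ids),
    subgroup = sub_of(family_ids),
    in_family = in_family,
    atlas_cocluster = atlas_f,
    internode_pass = inter_f,
    shortlist_pass = if (short_eval) short_f else NA,
    preferential_pass = if (pref_eval) pref_f else NA,
    final_candidate = final)
  summary <- c(in_family = length(family_ids),
               atlas_cocluster = sum(atlas_f),
               internode_pass = sum(inter_f),
               shortlist_pass = if (short_eval) sum(short_f) else NA_integer_,
               preferential_pass = if (pref_eval) sum(pref_f) else NA_integer_,
               final_candidate = sum(final))
  stages <- list(in_family = family_ids,
                 atlas_cocluster = family_ids[atlas_f],
                 internode_pass = family_ids[inter_f],
                 shortlist_pass = if (short_eval) family_ids[short_f] else NULL,
                 preferential_pass = if (pref_eval) family_ids[pref_f] else NULL,
                 final_candidate = family_ids[final])
  diagnostics <- list(
    internode_missing = intersect(family_ids, internode_missing),
    not_evaluated = c(if (!short_eval) "shortlist",
                      if (!pref_eval) "preferential"))
  cfg <- unclass(config)
  cfg$inputs <- NULL
  structure(list(table = table, summary = summary, stages = stages,
                 diagnostics = diagnostics, config = cfg),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Candidate funnel:\n")
  for (nm in names(x$summary)) {
    cat(sprintf("  %-18s %s\n", nm,
                ifelse(is.na(x$summary[[nm]]), "not evaluated", x$summary[[nm]])))
  }
  fin <- x$stages$final_candidate
  if (length(fin)) cat("  final candidates:", paste(fin, collapse = ", "), "\n")
  invisible(x)
}
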