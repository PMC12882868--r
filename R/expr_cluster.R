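# Expression-atlas co-clustering with the toolbox set and internode-zone
# profiling against an artificial mean-toolbox terminal.

INTERNODE_ZONES <- c("MsZ", "CEZ", "TZ", "MZ")

#' Unit-variance scale the rows of an expression matrix
#'
#' Standardizes each gene row to mean 0 and (n-1)-denominator standard
#' deviation 1, the usual preprocessing before correlation-based heatmap
#' clustering. Constant rows cannot be scaled; they are dropped with a warning
#' and listed in the `"dropped"` attribute.
#'
#' @param m Numeric matrix, genes in rows, samples in columns.
#' @return Scaled matrix with attribute `dropped` (character vector of
#'   removed gene ids).
#' @export
unit_variance_scale <- function(m) {
  sds <- apply(m, 1, stats::sd)
  constant <- sds == 0 | is.na(sds)
  if (all(constant)) stop("all rows constant; nothing to scale")
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant row(s): ",
            paste(utils::head(rownames(m)[constant], 5), collapse = ", "))
  }
  kept <- m[!constant, , drop = FALSE]
  out <- (kept - rowMeans(kept)) / sds[!constant]
  attr(out, "dropped") <- rownames(m)[constant]
  out
}

#' Agglomerative clustering of expression rows
#'
#' Hierarchical clustering of (scaled) rows under correlation distance
#' (1 - Pearson) or Euclidean distance, with average, complete or Ward
#' linkage, cut into `k` clusters. Rows are processed in lexicographic gene-id
#' order so ties resolve deterministically.
#'
#' @param m Numeric matrix (typically the output of [unit_variance_scale()]).
#' @param k Number of clusters (2 <= k <= nrow).
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`.
#' @return List with `labels` (named integer vector gene -> 1..k), `k`, and
#'   the `hclust` object as `dendrogram`.
#' @export
cluster_rows <- function(m, k, distance = c("correlation", "euclidean"),
                         linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(m)) stop("k exceeds row count")
  m <- m[order(rownames(m)), , drop = FALSE]
  d <- if (distance == "correlation") {
    stats::as.dist(1 - stats::cor(t(m)))
  } else {
    stats::dist(m)
  }
  method <- c(average = "average", complete = "complete", ward = "ward.D2")[linkage]
  hc <- stats::hclust(d, method = method)
  labels <- stats::cutree(hc, k = k)
  list(labels = labels, k = k, dendrogram = hc)
}

#' Select candidates co-clustering with the toolbox genes
#'
#' Picks the cluster holding the most toolbox genes (ties: higher toolbox
#' fraction, then smaller cluster, then lower label) and returns the family
#' members of that cluster, toolbox genes excluded. A warning is raised when
#' the toolbox genes split across clusters.
#'
#' @param assignment Result of [cluster_rows()].
#' @param toolbox_ids Reference gene set (e.g. the lignin toolbox).
#' @param family_ids Family member ids.
#' @return List with `candidates`, `selected_cluster`, and `diagnostics`
#'   (toolbox coverage per cluster).
#' @export
select_cocluster_candidates <- function(assignment, toolbox_ids, family_ids) {
  labels <- assignment$labels
  present <- intersect(toolbox_ids, names(labels))
  if (length(present) == 0L) stop("no toolbox gene in the cluster assignment")
  tb <- table(factor(labels[present], levels = sort(unique(labels))))
  sizes <- table(factor(labels, levels = sort(unique(labels))))
  frac <- as.numeric(tb) / as.numeric(sizes)
  ord <- order(-as.numeric(tb), -frac, as.numeric(sizes), as.numeric(names(tb)))
  selected <- as.integer(names(tb)[ord[1]])
  if (sum(tb > 0) > 1L) {
    warning("toolbox genes split across ", sum(tb > 0), " clusters")
  }
  members <- names(labels)[labels == selected]
  candidates <- setdiff(intersect(members, family_ids), toolbox_ids)
  list(candidates = candidates,
       selected_cluster = selected,
       diagnostics = list(
         toolbox_per_cluster = stats::setNames(as.integer(tb), names(tb)),
         cluster_sizes = stats::setNames(as.integer(sizes), names(sizes)),
         toolbox_missing = setdiff(toolbox_ids, names(labels))))
}

#' Mean scaled toolbox expression profile
#'
#' The "artificial terminal": per-sample mean of the unit-variance-scaled
#' toolbox gene rows, used as a reference profile in the internode stage.
#'
#' @param m Raw expression matrix.
#' @param toolbox_ids Toolbox gene ids (must be rows of `m`).
#' @return List with `profile` (numeric, one value per sample) and
#'   `member_ids`.
#' @export
reference_profile <- function(m, toolbox_ids) {
  present <- intersect(toolbox_ids, rownames(m))
  if (length(present) == 0L) stop("no toolbox gene present in the matrix")
  scaled <- unit_variance_scale(m[present, , drop = FALSE])
  list(profile = colMeans(scaled), member_ids = present)
}

#' Internode developmental-zone stage
#'
#' Screens family genes against the four internode zones (MsZ, CEZ, TZ, MZ,
#' bottom to top). In `cocluster_with_terminal` mode the mean scaled toolbox
#' profile is appended as an artificial row, rows are clustered at k = 2, and
#' family genes sharing the terminal's cluster are returned. In `peak_zone`
#' mode family genes whose scaled profile peaks in TZ or MZ are returned.
#' Genes absent from the matrix are dropped (and reported).
#'
#' @param m 4-column expression matrix with columns named MsZ, CEZ, TZ, MZ.
#' @param toolbox_ids Toolbox gene ids (required for terminal mode).
#' @param family_ids Family member ids to screen.
#' @param mode `"cocluster_with_terminal"` or `"peak_zone"`.
#' @return List with `candidates`, `mode`, and `missing` (family genes absent
#'   from the matrix).
#' @export
internode_stage <- function(m, toolbox_ids, family_ids,
                            mode = c("cocluster_with_terminal", "peak_zone")) {
  mode <- match.arg(mode)
  if (ncol(m) != 4L || !identical(colnames(m), INTERNODE_ZONES)) {
    stop("matrix must have exactly the 4 zone columns MsZ, CEZ, TZ, MZ")
  }
  missing <- setdiff(family_ids, rownames(m))
  family_present <- intersect(family_ids, rownames(m))
  if (mode == "peak_zone") {
    scaled <- unit_variance_scale(m)
    fam <- intersect(family_present, rownames(scaled))
    peaks <- apply(scaled[fam, , drop = FALSE], 1, which.max)
    candidates <- fam[peaks >= 3]
  } else {
    term <- reference_profile(m, toolbox_ids)
    scaled <- unit_variance_scale(m)
    aug <- rbind(scaled, `.lignin_terminal.` = term$profile)
    cl <- cluster_rows(aug, k = 2)
    term_cluster <- cl$labels[[".lignin_terminal."]]
    members <- names(cl$labels)[cl$labels == term_cluster]
    candidates <- intersect(family_present, setdiff(members, ".lignin_terminal."))
  }
  list(candidates = candidates, mode = mode, missing = missing)
}
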