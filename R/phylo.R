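# Multiple alignment, trimming, neighbor joining, bootstrap supports and
# reference-based subgroup assignment.

# Pairwise global (Needleman-Wunsch) alignment with linear gap penalty,
# scored match/mismatch, delegated to Biostrings.
pairwise_global <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  alphabet <- c(AA_ALPHABET, "X")
  sm <- matrix(mismatch, length(alphabet), length(alphabet),
               dimnames = list(alphabet, alphabet))
  diag(sm) <- match
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sm, gapOpening = 0, gapExtension = -gap,
    type = "global")
  list(score = Biostrings::score(pa),
       a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

#' Center-star multiple sequence alignment
#'
#' Picks the center sequence maximizing the summed pairwise global-alignment
#' score, then merges the pairwise alignments of every other sequence against
#' the center under the "once a gap, always a gap" rule.
#'
#' @param sequences Named character vector of >= 2 amino-acid sequences.
#' @param match,mismatch,gap Linear alignment scores.
#' @return Object of class `protein_msa`: named character vector of gapped
#'   rows (all equal length), with attribute `n_columns`.
#' @export
build_msa <- function(sequences, match = 1, mismatch = -1, gap = -1) {
  n <- length(sequences)
  if (n < 2L) stop("need at least 2 sequences")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must have unique names")
  }
  # center = argmax of summed pairwise scores
  total <- numeric(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- pairwise_global(sequences[[i]], sequences[[j]], match, mismatch, gap)$score
      total[i] <- total[i] + s
      total[j] <- total[j] + s
    }
  }
  ci <- which.max(total)
  center <- sequences[[ci]]
  # master center row as character vector; rows merged so far
  master <- strsplit(center, "")[[1]]
  rows <- list()
  rows[[names(sequences)[ci]]] <- master
  for (i in seq_len(n)[-ci]) {
    al <- pairwise_global(center, sequences[[i]], match, mismatch, gap)
    ac <- strsplit(al$a, "")[[1]]  # center with new gaps
    ao <- strsplit(al$b, "")[[1]]
    # positions of center residues within this pairwise alignment
    res_pos_pair <- which(ac != "-")
    res_pos_master <- which(master != "-")
    stopifnot(length(res_pos_pair) == length(res_pos_master))
    # count gaps inserted after each center residue (and before the first)
    new_width <- length(master) + 0L
    # build merged rows by inserting pairwise-new gap columns into master
    gaps_before <- integer(length(res_pos_pair) + 1L)  # slot k: before residue k
    prev <- 0L
    for (k in seq_along(res_pos_pair)) {
      gaps_before[k] <- res_pos_pair[k] - prev - 1L
      prev <- res_pos_pair[k]
    }
    gaps_before[length(gaps_before)] <- length(ac) - prev
    master_gaps_before <- integer(length(res_pos_master) + 1L)
    prev <- 0L
    for (k in seq_along(res_pos_master)) {
      master_gaps_before[k] <- res_pos_master[k] - prev - 1L
      prev <- res_pos_master[k]
    }
    master_gaps_before[length(master_gaps_before)] <- length(master) - prev
    extra <- pmax(0L, gaps_before - master_gaps_before)
    if (any(extra > 0L)) {
      # insert `extra[k]` gap columns before center residue k in all rows
      insert_cols <- function(row_chars, residue_pos) {
        out <- character(0)
        prev <- 0L
        for (k in seq_along(residue_pos)) {
          seg <- row_chars[(prev + 1L):(residue_pos[k] - 1L)]
          if (residue_pos[k] - 1L < prev + 1L) seg <- character(0)
          out <- c(out, seg, rep("-", extra[k]), row_chars[residue_pos[k]])
          prev <- residue_pos[k]
        }
        tail_seg <- if (prev < length(row_chars)) row_chars[(prev + 1L):length(row_chars)] else character(0)
        c(out, tail_seg, rep("-", extra[length(extra)]))
      }
      for (nm in names(rows)) rows[[nm]] <- insert_cols(rows[[nm]], res_pos_master)
      master <- rows[[names(sequences)[ci]]]
      res_pos_master <- which(master != "-")
    }
    # place the new row: its residues fall at pairwise columns; map pairwise
    # columns to master columns via center residues
    new_row <- rep("-", length(master))
    # map: pairwise col -> master col
    # center residue k: pair col res_pos_pair[k] -> master col res_pos_master[k]
    # gap runs before residue k occupy the `gaps_before[k]` master gap columns
    # immediately preceding master residue k (rightmost-aligned).
    pair2master <- integer(length(ac))
    for (k in seq_along(res_pos_pair)) {
      pair2master[res_pos_pair[k]] <- res_pos_master[k]
      if (gaps_before[k] > 0L) {
        cols <- seq(res_pos_master[k] - gaps_before[k], res_pos_master[k] - 1L)
        pair2master[(res_pos_pair[k] - gaps_before[k]):(res_pos_pair[k] - 1L)] <- cols
      }
    }
    k_last <- length(res_pos_pair)
    if (gaps_before[k_last + 1L] > 0L) {
      cols <- seq(res_pos_master[k_last] + 1L,
                  res_pos_master[k_last] + gaps_before[k_last + 1L])
      pair2master[(res_pos_pair[k_last] + 1L):length(ac)] <- cols
    }
    new_row[pair2master[ao != "-"]] <- ao[ao != "-"]
    rows[[names(sequences)[i]]] <- new_row
  }
  out <- vapply(rows, paste, character(1), collapse = "")
  out <- out[names(sequences)]  # input order
  structure(out, n_columns = nchar(out[[1]]), class = "protein_msa")
}

msa_matrix <- function(aln) {
  do.call(rbind, strsplit(unclass(aln), ""))
}

as_msa <- function(rows) {
  out <- vapply(rows, paste, character(1), collapse = "")
  structure(out, n_columns = if (length(out)) nchar(out[[1]]) else 0L,
            class = "protein_msa")
}

#' Trim alignment columns by gap fraction
#'
#' Removes columns whose gap fraction exceeds `gap_threshold`. If fewer than
#' `min_conserve` of the original columns would remain, the
#' `ceiling(min_conserve * n_columns)` columns with the lowest gap fraction
#' are retained instead (ties resolved leftmost).
#'
#' @param aln A `protein_msa`.
#' @param gap_threshold Columns with gap fraction strictly above this are
#'   dropped (default 0.5).
#' @param min_conserve Minimum fraction of columns to conserve (default 0.10).
#' @return Trimmed `protein_msa`.
#' @export
trim_alignment <- function(aln, gap_threshold = 0.5, min_conserve = 0.10) {
  stopifnot(gap_threshold > 0, gap_threshold <= 1,
            min_conserve > 0, min_conserve <= 1)
  m <- msa_matrix(aln)
  if (length(m) == 0L) stop("empty alignment")
  gapfrac <- colMeans(m == "-")
  keep <- which(gapfrac <= gap_threshold)
  floor_n <- ceiling(min_conserve * ncol(m))
  if (length(keep) < floor_n) {
    keep <- sort(order(gapfrac)[seq_len(floor_n)])
  }
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  structure(stats::setNames(out, rownames(m) %||% names(aln)),
            n_columns = length(keep), class = "protein_msa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise p-distances from an alignment
#'
#' Mismatches divided by the number of columns where both rows carry a
#' residue; a pair with zero comparable columns is an error.
#'
#' @param aln A `protein_msa`.
#' @return Symmetric distance matrix.
#' @export
p_distance <- function(aln) {
  m <- msa_matrix(aln)
  nm <- names(unclass(aln))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  res <- m != "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- res[i, ] & res[j, ]
      if (!any(comp)) stop("incomparable pair: ", nm[i], " vs ", nm[j])
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
    }
  }
  d
}

#' Neighbor joining from a distance matrix
#'
#' Saitou-Nei neighbor joining with
#' \eqn{Q(i,j) = (n-2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)}, deterministic
#' tie-breaking (smallest row index, then column index) and negative branch
#' lengths clamped to 0. An all-zero matrix yields a star tree.
#'
#' @param d Symmetric distance matrix with >= 3 labeled tips.
#' @return `ape::phylo` (unrooted).
#' @export
nj_from_dist <- function(d) {
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (max(d) == 0) {
    return(ape::read.tree(text = paste0(
      "(", paste(paste0(labels, ":0"), collapse = ","), ");")))
  }
  nodes <- labels  # newick fragments for active nodes
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    i <- idx[1]; j <- idx[2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    bi <- max(0, bi); bj <- max(0, bj)
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[i], format(bi, digits = 15),
                        nodes[j], format(bj, digits = 15))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    nodes <- c(nodes[keep], new_node)
    dimnames(d2) <- list(seq_along(nodes), seq_along(nodes))
    d <- d2
  }
  b1 <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  b2 <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  b3 <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nodes[1], format(b1, digits = 15),
                 nodes[2], format(b2, digits = 15),
                 nodes[3], format(b3, digits = 15))
  ape::read.tree(text = txt)
}

#' Neighbor-joining tree from an alignment
#'
#' p-distances ([p_distance()]) followed by [nj_from_dist()].
#'
#' @param aln A `protein_msa` with >= 3 rows.
#' @return `ape::phylo`.
#' @export
nj_tree <- function(aln) {
  if (length(unclass(aln)) < 3L) stop("need at least 3 rows")
  nj_from_dist(p_distance(aln))
}

# Internal-edge bipartitions of an unrooted tree, canonicalized as the side
# not containing the alphabetically first tip, encoded "a|b|c".
tree_splits <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1]
  n_tip <- length(tips)
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, function(k) if (k <= n_tip) tips[k] else desc(k)))
  }
  internal <- setdiff(unique(tree$edge[, 1]), n_tip + 1L)  # non-root internal nodes
  sp <- vapply(internal, function(node) {
    side <- desc(node)
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > n_tip - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  stats::setNames(sp, internal)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and labels each internal node of the point-estimate tree with
#' the percentage of replicate trees containing its bipartition.
#'
#' @param aln A `protein_msa`.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed (column resampling only).
#' @return `ape::phylo` with `node.label` support percentages (root label
#'   empty).
#' @export
bootstrap_support <- function(aln, n_replicates = 100, seed = 1) {
  stopifnot(n_replicates >= 1)
  point <- nj_tree(aln)
  m <- msa_matrix(aln)
  sp_point <- tree_splits(point)
  counts <- stats::setNames(rep(0, length(sp_point)), names(sp_point))
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- as_msa(stats::setNames(
      lapply(seq_len(nrow(m)), function(i) m[i, cols]), rownames(m)))
    rep_splits <- tryCatch(tree_splits(nj_tree(rep_aln)), error = function(e) character(0))
    hit <- !is.na(sp_point) & sp_point %in% rep_splits
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / n_replicates)
  n_tip <- length(point$tip.label)
  labs <- character(point$Nnode)
  for (k in seq_along(sp_point)) {
    node <- as.integer(names(sp_point)[k])
    labs[node - n_tip] <- if (is.na(sp_point[k])) "" else as.character(support[k])
  }
  point$node.label <- labs
  point
}

#' Assign phylogenetic subgroups from reference-labeled leaves
#'
#' Midpoint-roots the tree, then for each unlabeled query leaf finds the
#' smallest clade containing the query and at least one reference leaf whose
#' support (internal-node label) is at least `min_support`; the majority
#' reference label in that clade is assigned (ties or no qualifying clade give
#' `"unclassified"`). Unlabeled internal nodes are treated as fully supported.
#'
#' @param tree `ape::phylo`, optionally with bootstrap `node.label`s.
#' @param reference_labels Named character vector: reference leaf id ->
#'   subgroup label.
#' @param min_support Minimum clade support percentage (default 50).
#' @return data.frame with `query_id`, `subgroup`, `support`, `clade_size`.
#' @export
assign_subgroups <- function(tree, reference_labels, min_support = 50) {
  refs <- names(reference_labels)
  if (!any(refs %in% tree$tip.label)) stop("no labeled reference leaf on the tree")
  rooted <- phangorn::midpoint(tree, node.labels = "label")
  queries <- setdiff(tree$tip.label, refs)
  if (length(setdiff(queries, rooted$tip.label)) > 0L) stop("query id absent from tree")
  n_tip <- length(rooted$tip.label)
  parent <- integer(max(rooted$edge))
  parent[rooted$edge[, 2]] <- rooted$edge[, 1]
  node_support <- function(node) {
    if (is.null(rooted$node.label)) return(100)
    lab <- rooted$node.label[node - n_tip]
    if (is.na(lab) || lab == "") 100 else as.numeric(lab)
  }
  clade_tips <- function(node) {
    if (node <= n_tip) return(rooted$tip.label[node])
    kids <- rooted$edge[rooted$edge[, 1] == node, 2]
    unlist(lapply(kids, clade_tips))
  }
  out <- lapply(queries, function(q) {
    node <- parent[match(q, rooted$tip.label)]
    repeat {
      tips <- clade_tips(node)
      in_refs <- intersect(tips, refs)
      sup <- node_support(node)
      if (length(in_refs) > 0L && sup >= min_support) {
        tab <- sort(table(reference_labels[in_refs]), decreasing = TRUE)
        subgroup <- if (length(tab) > 1L && tab[1] == tab[2]) "unclassified" else names(tab)[1]
        return(data.frame(query_id = q, subgroup = subgroup,
                          support = sup, clade_size = length(tips)))
      }
      if (parent[node] == 0L) {
        return(data.frame(query_id = q, subgroup = "unclassified",
                          support = NA_real_, clade_size = NA_integer_))
      }
      node <- parent[node]
    }
  })
  do.call(rbind, out)
}
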