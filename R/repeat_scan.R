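AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Bundled MYB-repeat seed alignment
#'
#' Returns the 52-column, 12-row seed alignment bundled with the package: a
#' synthetic block modeled on the plant MYB repeat consensus (helix-turn-helix
#' with the conserved tryptophan triad at columns 6, 26 and 46). It drives both
#' the repeat scanner (via [build_repeat_pssm()]) and the synthetic-data
#' generator, which samples rows through an independent mutation path.
#'
#' @return Named character vector of equal-length amino-acid strings.
#' @export
myb_seed_alignment <- function() {
  path <- system.file("extdata", "myb_repeat_seed_alignment.fasta",
                      package = "mybfunnel", mustWork = TRUE)
  aln <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aln), names(aln))
}

#' Build a position-specific scoring matrix for the MYB repeat
#'
#' Column scores are log-odds in bits against a background residue
#' distribution, with additive pseudocounts:
#' \deqn{s(c, a) = \log_2\frac{(n_{c,a} + \lambda b_a)/(N + \lambda)}{b_a}}
#' where \eqn{n_{c,a}} counts residue \eqn{a} in column \eqn{c} of the seed
#' alignment, \eqn{N} is the number of rows and \eqn{\lambda} the pseudocount.
#' The hit threshold defaults to `threshold_fraction` times the maximum
#' achievable window score (sum of per-column maxima).
#'
#' @param seed_alignment Character vector of equal-length ungapped amino-acid
#'   strings (defaults to the bundled MYB seed alignment).
#' @param pseudocount Positive pseudocount \eqn{\lambda}.
#' @param background Named numeric vector of residue frequencies summing to 1;
#'   default uniform (0.05 each).
#' @param threshold_fraction Fraction of the maximum achievable score used as
#'   the hit threshold.
#' @return Object of class `repeat_pssm`: list with `width`, `scores`
#'   (residue-by-column matrix, bits), `threshold` and `max_score`.
#' @export
build_repeat_pssm <- function(seed_alignment = myb_seed_alignment(),
                              pseudocount = 1,
                              background = NULL,
                              threshold_fraction = 0.45) {
  if (length(seed_alignment) < 1) stop("empty seed alignment")
  widths <- nchar(seed_alignment)
  if (length(unique(widths)) != 1L) stop("ragged alignment: rows differ in length")
  if (!is.numeric(pseudocount) || pseudocount <= 0) stop("pseudocount must be > 0")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  if (!all(AA_ALPHABET %in% names(background))) {
    stop("background must cover the 20-letter amino-acid alphabet")
  }
  background <- background[AA_ALPHABET]
  if (any(background <= 0)) stop("zero background frequency")
  if (abs(sum(background) - 1) > 1e-8) stop("background frequencies must sum to 1")

  width <- widths[1]
  chars <- do.call(rbind, strsplit(seed_alignment, ""))
  if (!all(chars %in% AA_ALPHABET)) {
    stop("seed alignment contains characters outside the 20-letter alphabet")
  }
  n <- nrow(chars)
  scores <- matrix(0, nrow = 20, ncol = width,
                   dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_len(width)) {
    cnt <- table(factor(chars[, j], levels = AA_ALPHABET))
    scores[, j] <- log2(((as.numeric(cnt) + pseudocount * background) /
                           (n + pseudocount)) / background)
  }
  max_score <- sum(apply(scores, 2, max))
  structure(
    list(width = width, scores = scores,
         threshold = threshold_fraction * max_score,
         max_score = max_score),
    class = "repeat_pssm"
  )
}

#' @export
print.repeat_pssm <- function(x, ...) {
  cat("Repeat PSSM:", x$width, "columns; threshold",
      sprintf("%.1f", x$threshold), "of max", sprintf("%.1f", x$max_score),
      "bits\n")
  invisible(x)
}

# Window scores for one sequence; positions outside the alphabet (X etc.)
# contribute 0 bits. Returns numeric vector over 0-based window starts.
window_scores <- function(sequence, pssm) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  w <- pssm$width
  if (L < w) return(numeric(0))
  idx <- match(chars, AA_ALPHABET)
  n_win <- L - w + 1L
  ws <- numeric(n_win)
  for (j in seq_len(w)) {
    col <- pssm$scores[, j]
    contrib <- ifelse(is.na(idx[j:(j + n_win - 1L)]), 0, col[idx[j:(j + n_win - 1L)]])
    ws <- ws + contrib
  }
  ws
}

#' Scan a protein for MYB repeats
#'
#' Scores every window of the sequence against the PSSM, keeps windows at or
#' above the threshold, and resolves overlaps greedily in descending score
#' order (ties broken by the leftmost start). Coordinates are 0-based
#' half-open residue indices, so `end - start` equals the PSSM width.
#'
#' @param sequence Amino-acid string (unknown residues as `X` score 0).
#' @param pssm A `repeat_pssm`.
#' @return data.frame with columns `start`, `end`, `score`, sorted by `start`;
#'   zero rows when the sequence is shorter than the PSSM.
#' @export
scan_repeats <- function(sequence, pssm) {
  stopifnot(inherits(pssm, "repeat_pssm"))
  ws <- window_scores(sequence, pssm)
  hit <- which(ws >= pssm$threshold)
  if (length(hit) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), score = numeric(0)))
  }
  ord <- hit[order(-ws[hit], hit)]
  taken <- logical(nchar(sequence))
  starts <- integer(0)
  for (p in ord) {
    span <- p:(p + pssm$width - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      starts <- c(starts, p)
    }
  }
  starts <- sort(starts)
  data.frame(start = starts - 1L, end = starts - 1L + pssm$width,
             score = ws[starts])
}

#' Classify repeat architecture
#'
#' A protein is `R2R3` iff it carries exactly two repeat hits, both starting
#' before `nterm_limit`, separated by at most `max_inter_repeat_gap` residues
#' (gap = start of the second hit minus end of the first). One hit gives
#' `ONE_R`, three or more give `THREE_R_PLUS`, none gives `NONE`; only `R2R3`
#' proteins are retained as family members downstream.
#'
#' @param hits data.frame of hits as returned by [scan_repeats()] (sorted,
#'   non-overlapping, 0-based half-open).
#' @param protein_length Sequence length (residues).
#' @param nterm_limit Both hits must start before this residue index.
#' @param max_inter_repeat_gap Maximum residues between the two repeats.
#' @return List with `label` (one of NONE, ONE_R, R2R3, THREE_R_PLUS) and the
#'   `hits` table.
#' @export
classify_architecture <- function(hits, protein_length,
                                  nterm_limit = 200,
                                  max_inter_repeat_gap = 30) {
  n <- nrow(hits)
  if (n > 1L) {
    if (is.unsorted(hits$start, strictly = TRUE)) stop("hits must be sorted by start")
    if (any(hits$start[-1] < hits$end[-n])) stop("hits must not overlap")
  }
  label <- if (n == 0L) {
    "NONE"
  } else if (n == 1L) {
    "ONE_R"
  } else if (n >= 3L) {
    "THREE_R_PLUS"
  } else {
    gap <- hits$start[2] - hits$end[1]
    if (all(hits$start < nterm_limit) && gap <= max_inter_repeat_gap) "R2R3" else "NONE"
  }
  list(label = label, hits = hits)
}

#' Identify R2R3-MYB family members in a proteome
#'
#' Scans every protein, classifies its repeat architecture, and returns the
#' table of proteins with the canonical R2R3 architecture, in input order.
#'
#' @param proteome Named character vector of amino-acid sequences (primary
#'   transcripts only), or a data.frame with columns `id` and `sequence`.
#' @param pssm A `repeat_pssm`; defaults to the bundled seed alignment PSSM.
#' @param nterm_limit,max_inter_repeat_gap Passed to
#'   [classify_architecture()].
#' @return data.frame with columns `protein_id`, `n_hits`, `hit1_start`,
#'   `hit1_end`, `hit2_start`, `hit2_end`, `label` (all rows `R2R3`). The full
#'   per-protein architecture labels are attached as attribute
#'   `"architectures"`.
#' @export
identify_family <- function(proteome, pssm = build_repeat_pssm(),
                            nterm_limit = 200, max_inter_repeat_gap = 30) {
  if (is.data.frame(proteome)) {
    proteome <- stats::setNames(proteome$sequence, proteome$id)
  }
  if (length(proteome) == 0L) stop("empty proteome")
  if (is.null(names(proteome)) || any(names(proteome) == "")) {
    stop("every protein needs an id")
  }
  if (anyDuplicated(names(proteome))) {
    stop("duplicate protein ids: ",
         paste(unique(names(proteome)[duplicated(names(proteome))]), collapse = ", "))
  }
  rows <- vector("list", length(proteome))
  labels <- character(length(proteome))
  for (i in seq_along(proteome)) {
    hits <- scan_repeats(proteome[[i]], pssm)
    arch <- classify_architecture(hits, nchar(proteome[[i]]),
                                  nterm_limit, max_inter_repeat_gap)
    labels[i] <- arch$label
    if (arch$label == "R2R3") {
      rows[[i]] <- data.frame(
        protein_id = names(proteome)[i],
        n_hits = nrow(hits),
        hit1_start = hits$start[1], hit1_end = hits$end[1],
        hit2_start = hits$start[2], hit2_end = hits$end[2],
        label = "R2R3"
      )
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), n_hits = integer(0),
                      hit1_start = integer(0), hit1_end = integer(0),
                      hit2_start = integer(0), hit2_end = integer(0),
                      label = character(0))
  }
  rownames(out) <- NULL
  attr(out, "architectures") <- stats::setNames(labels, names(proteome))
  out
}
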