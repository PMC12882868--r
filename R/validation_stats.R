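# qPCR relative expression with preferential-expression calls, and
# dual-luciferase transactivation fold changes.

#' Relative expression from Ct values
#'
#' Computes RE = 2^(-dCt) with dCt = Ct_target - mean(Ct of the two reference
#' genes) per (tissue, replicate). Amplification efficiency is fixed at 2
#' (100%); the arithmetic mean of the two reference Cts is equivalent to
#' geometric-mean normalization on the linear scale.
#'
#' @param ct data.frame with columns `gene`, `tissue`, `replicate`, `ct`.
#' @param reference_genes Character vector of exactly two reference gene ids
#'   (e.g. CUL and EF1a homologues).
#' @return data.frame with `gene`, `tissue`, `replicate`, `re` for all
#'   non-reference genes.
#' @export
relative_expression <- function(ct, reference_genes) {
  stopifnot(all(c("gene", "tissue", "replicate", "ct") %in% names(ct)))
  if (length(reference_genes) != 2L) stop("exactly two reference genes required")
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  refs <- ct[ct$gene %in% reference_genes, ]
  key <- function(d) paste(d$tissue, d$replicate, sep = "\r")
  ref_n <- tapply(refs$gene, key(refs), function(g) length(unique(g)))
  targets <- ct[!ct$gene %in% reference_genes, ]
  miss <- setdiff(unique(key(targets)), names(ref_n)[ref_n == 2])
  if (length(miss)) {
    stop("missing reference Ct for (tissue, replicate): ",
         paste(gsub("\r", "/", miss), collapse = ", "))
  }
  ref_mean <- tapply(refs$ct, key(refs), mean)
  dct <- targets$ct - as.numeric(ref_mean[key(targets)])
  data.frame(gene = targets$gene, tissue = targets$tissue,
             replicate = targets$replicate, re = 2^(-dct))
}

#' Preferential-expression call per gene
#'
#' One-way ANOVA of relative expression across tissues followed by Tukey's
#' HSD. The verdict is `TRUE` iff the target tissue has the highest group
#' mean and its Tukey-adjusted p-value is below `alpha` against every other
#' tissue. The omnibus ANOVA F statistic and p-value are also returned: the
#' compound verdict is conservative by construction (its null rate is well
#' below `alpha`), while the omnibus test is the alpha-calibrated component.
#'
#' @param re data.frame from [relative_expression()].
#' @param target_tissue Tissue whose preferential expression is being tested.
#' @param alpha Significance level (default 0.05).
#' @return data.frame per gene: `gene`, `verdict`, `f`, `anova_p`,
#'   `max_tukey_p` (largest adjusted p against the target), with the full
#'   Tukey tables in attribute `"tukey"`.
#' @export
preferential_call <- function(re, target_tissue, alpha = 0.05) {
  stopifnot(target_tissue %in% re$tissue)
  if (any(grepl("-", unique(re$tissue), fixed = TRUE))) {
    stop("tissue names must not contain '-' (reserved for Tukey pair labels)")
  }
  tukeys <- list()
  rows <- lapply(split(re, re$gene), function(d) {
    if (length(unique(d$tissue)) < 2L) stop("need at least 2 tissues")
    if (any(table(d$tissue) < 2L)) stop("a tissue has a single replicate")
    d$tissue <- factor(d$tissue)
    fit <- stats::aov(re ~ tissue, data = d)
    an <- summary(fit)[[1]]
    f <- an[["F value"]][1]
    p <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$tissue
    pair_has_target <- grepl(paste0("(^|-)", target_tissue, "($|-)"),
                             rownames(tk))
    target_p <- tk[pair_has_target, "p adj"]
    means <- tapply(d$re, d$tissue, mean)
    verdict <- isTRUE(names(means)[which.max(means)] == target_tissue &&
                        all(target_p < alpha))
    tukeys[[d$gene[1]]] <<- tk
    data.frame(gene = d$gene[1], verdict = verdict, f = f, anova_p = p,
               max_tukey_p = max(target_p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tukey") <- tukeys
  out
}

#' Transactivation fold change from dual-luciferase readings
#'
#' Normalizes firefly by Renilla luciferase per replicate
#' (ratio = fLUC/rLUC), then reports each effector's fold change over the
#' control effector (ratio of means) with the ratio standard deviation and a
#' two-sided Student's t test of the effector ratios against the control
#' ratios (Welch available via `welch = TRUE`).
#'
#' @param luc data.frame with columns `effector`, `replicate`, `fluc`,
#'   `rluc`.
#' @param control Control effector id (e.g. a GUS effector).
#' @param welch Use Welch's unequal-variance t test instead of Student's.
#' @return data.frame per non-control effector: `effector`, `n`, `fold`,
#'   `sd_ratio`, `p`, `over_20fold`.
#' @export
transactivation_fold <- function(luc, control, welch = FALSE) {
  stopifnot(all(c("effector", "replicate", "fluc", "rluc") %in% names(luc)))
  if (any(luc$rluc <= 0)) stop("rLUC must be > 0 for every replicate")
  if (!control %in% luc$effector) stop("control effector missing: ", control)
  luc$ratio <- luc$fluc / luc$rluc
  ctl <- luc$ratio[luc$effector == control]
  if (length(ctl) < 2L) stop("need >= 2 control replicates")
  rows <- lapply(setdiff(unique(luc$effector), control), function(e) {
    x <- luc$ratio[luc$effector == e]
    if (length(x) < 2L) stop("need >= 2 replicates for effector ", e)
    p <- if (stats::sd(x) == 0 && stats::sd(ctl) == 0) {
      # degenerate noise-free readings: identical means are indistinguishable
      if (isTRUE(all.equal(mean(x), mean(ctl)))) 1 else 0
    } else {
      stats::t.test(x, ctl, var.equal = !welch)$p.value
    }
    fold <- mean(x) / mean(ctl)
    data.frame(effector = e, n = length(x), fold = fold,
               sd_ratio = stats::sd(x), p = p,
               over_20fold = fold > 20)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
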