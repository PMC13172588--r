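#' Paired RNA/RPF counts experiment
#'
#' A light container for gene x sample integer count matrices covering two
#' assays (`rna` = transcript abundance, `rpf` = ribosome footprints) across
#' conditions and replicates.  Every (condition, replicate) pair must have
#' exactly one `rna` and one `rpf` library.
#'
#' @param counts non-negative integer matrix with unique gene rownames and
#'   sample colnames.
#' @param samples data.frame with columns `sample`, `assay` (one of
#'   `"rna"`, `"rpf"`), `condition`, `replicate`; rows must match the count
#'   columns one-to-one.
#' @return object of class `counts_experiment`.
#' @export
counts_experiment <- function(counts, samples) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts))
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts must have unique gene rownames", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts are not allowed", call. = FALSE)
  stopifnot(all(c("sample", "assay", "condition", "replicate") %in% names(samples)))
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  if (anyNA(samples$sample)) {
    stop("every count column needs a matching row in the sample table", call. = FALSE)
  }
  if (!all(samples$assay %in% c("rna", "rpf"))) {
    stop("assay must be 'rna' or 'rpf'", call. = FALSE)
  }
  key <- interaction(samples$condition, samples$replicate, drop = TRUE)
  for (k in levels(key)) {
    a <- samples$assay[key == k]
    if (sum(a == "rna") != 1L || sum(a == "rpf") != 1L) {
      stop(sprintf("condition/replicate '%s' lacks a matched rna/rpf pair", k),
           call. = FALSE)
    }
  }
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples),
            class = "counts_experiment")
}

#' @export
print.counts_experiment <- function(x, ...) {
  cat(sprintf("counts_experiment: %d genes x %d libraries (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}

#' Per-replicate translation efficiency
#'
#' TE of gene g in (condition, replicate) is `CPM_rpf(g) / CPM_rna(g)` where
#' CPM is computed on pseudocount-adjusted counts against the library total
#' of adjusted counts, making TE strictly positive and invariant to global
#' library-size rescaling.
#'
#' @param experiment a [counts_experiment()].
#' @param pseudocount positive count added to every raw count (default 1).
#' @return object of class `te_matrix`: list with `te` (gene x
#'   condition.replicate matrix), `condition`, `replicate`, and
#'   `mean_rna_count` (per-gene mean raw RNA count, used by the
#'   minimum-count filter of [differential_te()]).
#' @examples
#' # a gene with equal rna/rpf counts in libraries of identical composition has TE 1
#' @export
compute_te <- function(experiment, pseudocount = 1) {
  stopifnot(inherits(experiment, "counts_experiment"))
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be > 0", call. = FALSE)
  }
  cts <- experiment$counts
  smp <- experiment$samples
  adj <- cts + pseudocount
  cpm <- sweep(adj, 2L, colSums(adj), "/") * 1e6
  key <- paste(smp$condition, smp$replicate, sep = ".")
  pairs <- unique(key)
  te <- matrix(NA_real_, nrow = nrow(cts), ncol = length(pairs),
               dimnames = list(rownames(cts), pairs))
  for (k in pairs) {
    j_rna <- which(key == k & smp$assay == "rna")
    j_rpf <- which(key == k & smp$assay == "rpf")
    if (length(j_rna) != 1L || length(j_rpf) != 1L) {
      stop(sprintf("missing assay partner for replicate '%s'", k), call. = FALSE)
    }
    te[, k] <- cpm[, j_rpf] / cpm[, j_rna]
  }
  structure(list(te = te,
                 condition = smp$condition[match(pairs, key)],
                 replicate = smp$replicate[match(pairs, key)],
                 mean_rna_count = rowMeans(cts[, smp$assay == "rna", drop = FALSE])),
            class = "te_matrix")
}

#' Differential translation efficiency
#'
#' For every gene, `log2fc` is the mean log2 TE in `treated` minus the mean
#' in `control`, and the p-value comes from a Welch two-sample t-test on the
#' per-replicate log2 TE values.  Genes are classified `up` if
#' `log2fc > lfc_threshold` and `p < alpha`, `down` if
#' `log2fc < -lfc_threshold` and `p < alpha`, otherwise `ns`.  Raw p-values
#' (not FDR-adjusted) are thresholded.  Genes whose mean raw RNA count falls
#' below `min_count` are flagged (`tested = FALSE`) and excluded from
#' testing; with a single replicate per condition the fold change is still
#' reported, but p is missing and the class forced to `ns` with a warning.
#'
#' @param te a `te_matrix` from [compute_te()].
#' @param control,treated condition labels.
#' @param lfc_threshold positive log2 fold-change threshold (default 1.5).
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param min_count minimum mean raw RNA count for a gene to be tested
#'   (default 5).
#' @param test `"welch"` (default) for the Welch two-sample t-test or
#'   `"student"` for the equal-variance t-test.  At very small replicate
#'   numbers (2-4 per condition) Welch is conservative because of the
#'   Satterthwaite degrees-of-freedom estimate; the equal-variance test is
#'   close to nominal when, as here, both conditions have similar spread.
#' @return data.frame with columns `gene`, `mean_log2_te_control`,
#'   `mean_log2_te_treated`, `log2fc`, `p_value`, `class`, `tested`.
#' @export
differential_te <- function(te, control, treated, lfc_threshold = 1.5,
                            alpha = 0.05, min_count = 5,
                            test = c("welch", "student")) {
  stopifnot(inherits(te, "te_matrix"))
  test <- match.arg(test)
  if (lfc_threshold <= 0 || alpha <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  jc <- which(te$condition == control)
  jt <- which(te$condition == treated)
  if (!length(jc) || !length(jt)) {
    stop("control/treated condition not found in the TE matrix", call. = FALSE)
  }
  l2 <- log2(te$te)
  mc <- rowMeans(l2[, jc, drop = FALSE])
  mt <- rowMeans(l2[, jt, drop = FALSE])
  lfc <- mt - mc
  tested <- te$mean_rna_count >= min_count
  single <- length(jc) < 2L || length(jt) < 2L
  p <- rep(NA_real_, nrow(l2))
  if (single) {
    warning("single replicate per condition: p-values unavailable, all classes ns",
            call. = FALSE)
  } else {
    for (i in which(tested)) {
      x <- l2[i, jt]
      y <- l2[i, jc]
      p[i] <- if (var(x) + var(y) == 0) {
        if (mean(x) == mean(y)) 1 else 0
      } else {
        t.test(x, y, var.equal = (test == "student"))$p.value
      }
    }
  }
  cls <- rep("ns", nrow(l2))
  ok <- tested & !is.na(p)
  cls[ok & lfc > lfc_threshold & p < alpha] <- "up"
  cls[ok & lfc < -lfc_threshold & p < alpha] <- "down"
  data.frame(gene = rownames(l2),
             mean_log2_te_control = mc,
             mean_log2_te_treated = mt,
             log2fc = lfc,
             p_value = p,
             class = cls,
             tested = tested,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Reporter translation efficiency
#'
#' TE of a dual-luciferase reporter: protein yield (firefly over renilla
#' activity) divided by the firefly/renilla mRNA-abundance ratio.
#'
#' @param fluc_activity,rluc_activity luminescence readings (> 0).
#' @param fluc_mrna,rluc_mrna relative mRNA abundances (> 0).
#' @return numeric TE value(s):
#'   `(fluc_activity/rluc_activity) / (fluc_mrna/rluc_mrna)`.
#' @export
reporter_te <- function(fluc_activity, rluc_activity, fluc_mrna, rluc_mrna) {
  vals <- c(fluc_activity, rluc_activity, fluc_mrna, rluc_mrna)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all reporter measurements must be strictly positive", call. = FALSE)
  }
  (fluc_activity / rluc_activity) / (fluc_mrna / rluc_mrna)
}

#' Polysome fraction mRNA distribution
#'
#' Converts per-fraction relative mRNA quantities into proportions summing
#' to 1, preserving fraction order.
#'
#' @param amounts non-negative numeric vector, at least one positive entry.
#' @return numeric vector of proportions (names preserved).
#' @export
polysome_distribution <- function(amounts) {
  if (!is.numeric(amounts) || any(!is.finite(amounts)) || any(amounts < 0)) {
    stop("amounts must be finite and non-negative", call. = FALSE)
  }
  tot <- sum(amounts)
  if (tot == 0) stop("all-zero fraction vector", call. = FALSE)
  amounts / tot
}
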