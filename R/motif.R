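#' @title Polyproline motif scanning
#' @description Count PP, PPG and PPP motifs in protein sequences and bin
#'   genes by PP-motif content.
#' @name motif_scan
NULL

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

PP_BIN_LEVELS <- c("0", "1", "2", "3", ">=4")

#' Bin a PP-dipeptide count
#'
#' Pure function mapping a PP count to the bins `0, 1, 2, 3, >=4` used for
#' motif-content summaries.
#'
#' @param pp_count non-negative integer vector of PP dipeptide counts.
#' @return factor with levels `c("0","1","2","3",">=4")`.
#' @export
pp_bin <- function(pp_count) {
  stopifnot(all(pp_count >= 0))
  lab <- ifelse(pp_count >= 4, ">=4", as.character(pp_count))
  factor(lab, levels = PP_BIN_LEVELS)
}

#' Scan a protein sequence for polyproline motifs
#'
#' Counts proline-proline (PP) dipeptides, Pro-Pro-Gly (PPG) tripeptides and
#' Pro-Pro-Pro (PPP) tripeptides, and the longest consecutive proline run.
#' Counting is case-insensitive and a trailing/internal stop character `*` is
#' stripped before scanning.  By default windows overlap, so a run of p
#' prolines contributes p-1 PP and max(p-2, 0) PPP motifs; with
#' `non_overlapping = TRUE` each residue is used by at most one motif
#' occurrence (floor(p/2) PP, floor(p/3) PPP per run).  PPG occurrences can
#' never overlap each other, so the flag does not affect them.
#'
#' @param sequence single amino-acid string over the 20-letter alphabet.
#' @param non_overlapping logical; count non-overlapping motifs instead of
#'   the default overlapping convention.
#' @return list with elements `length`, `pp_count`, `ppg_count`, `ppp_count`,
#'   `max_run`, `bin` (factor) and `contains_pp` (logical).
#' @examples
#' scan_motifs("PPP")    # pp_count 2, ppp_count 1, max_run 3
#' scan_motifs("APPGA")  # pp_count 1, ppg_count 1
#' @export
scan_motifs <- function(sequence, non_overlapping = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  s <- toupper(gsub("*", "", sequence, fixed = TRUE))
  ch <- strsplit(s, "")[[1]]
  bad <- which(!(ch %in% AA_ALPHABET20))
  if (length(bad)) {
    stop(sprintf("invalid amino-acid character '%s' at position %d",
                 ch[bad[1]], bad[1]), call. = FALSE)
  }
  n <- length(ch)
  if (n == 0L) {
    return(list(length = 0L, pp_count = 0L, ppg_count = 0L, ppp_count = 0L,
                max_run = 0L, bin = pp_bin(0L), contains_pp = FALSE))
  }
  isp <- ch == "P"
  # proline run lengths
  r <- rle(isp)
  runs <- r$lengths[r$values]
  max_run <- if (length(runs)) max(runs) else 0L
  if (non_overlapping) {
    pp <- sum(runs %/% 2L)
    ppp <- sum(runs %/% 3L)
  } else {
    pp <- sum(pmax(runs - 1L, 0L))
    ppp <- sum(pmax(runs - 2L, 0L))
  }
  ppg <- if (n >= 3L) {
    sum(isp[seq_len(n - 2L)] & isp[seq_len(n - 2L) + 1L] & ch[seq_len(n - 2L) + 2L] == "G")
  } else 0L
  list(length = n, pp_count = as.integer(pp), ppg_count = as.integer(ppg),
       ppp_count = as.integer(ppp), max_run = as.integer(max_run),
       bin = pp_bin(pp), contains_pp = pp >= 1L)
}

#' Motif-profile a whole proteome
#'
#' Scans every protein of a FASTA file (or `Biostrings::AAStringSet`) and
#' returns one motif profile per gene.  When an id mapping collapses several
#' records (isoforms) onto one gene, `isoform_policy` decides which sequence
#' is scanned: the longest isoform (default, mirroring common proteome-scale
#' practice), the first record, or an error.
#'
#' @param fasta path to a protein FASTA file or an `AAStringSet`.
#' @param gene_map optional data.frame with columns `id` (FASTA record name)
#'   and `gene`; records absent from the map keep their record name.
#' @param isoform_policy one of `"longest"`, `"first"`, `"error"`.
#' @param non_overlapping passed to [scan_motifs()].
#' @return data.frame with one row per gene: `gene`, `length`, `pp_count`,
#'   `ppg_count`, `ppp_count`, `max_run`, `bin`, `contains_pp`.
#' @export
profile_proteome <- function(fasta, gene_map = NULL,
                             isoform_policy = c("longest", "first", "error"),
                             non_overlapping = FALSE) {
  isoform_policy <- match.arg(isoform_policy)
  if (is.character(fasta)) {
    aa <- Biostrings::readAAStringSet(fasta)
  } else {
    aa <- Biostrings::AAStringSet(fasta)
  }
  seqs <- as.character(aa)
  ids <- sub("\\s.*$", "", names(aa))
  genes <- ids
  if (!is.null(gene_map)) {
    stopifnot(all(c("id", "gene") %in% names(gene_map)))
    hit <- match(ids, gene_map$id)
    genes[!is.na(hit)] <- gene_map$gene[hit[!is.na(hit)]]
  }
  if (anyDuplicated(genes)) {
    if (isoform_policy == "error") {
      stop("multiple records map to one gene and isoform_policy = 'error'",
           call. = FALSE)
    }
    keep <- if (isoform_policy == "longest") {
      # ties broken by first occurrence
      unlist(lapply(split(seq_along(genes), genes), function(i) {
        i[which.max(nchar(seqs[i]))]
      }), use.names = FALSE)
    } else {
      match(unique(genes), genes)
    }
    keep <- sort(keep)
    genes <- genes[keep]
    seqs <- seqs[keep]
  }
  prof <- lapply(seqs, scan_motifs, non_overlapping = non_overlapping)
  out <- data.frame(
    gene = genes,
    length = vapply(prof, `[[`, integer(1), "length"),
    pp_count = vapply(prof, `[[`, integer(1), "pp_count"),
    ppg_count = vapply(prof, `[[`, integer(1), "ppg_count"),
    ppp_count = vapply(prof, `[[`, integer(1), "ppp_count"),
    max_run = vapply(prof, `[[`, integer(1), "max_run"),
    stringsAsFactors = FALSE
  )
  out$bin <- pp_bin(out$pp_count)
  out$contains_pp <- out$pp_count >= 1L
  rownames(out) <- NULL
  out
}

#' Summarise motif bins
#'
#' @param profiles data.frame from [profile_proteome()].
#' @return data.frame with columns `bin` and `n_genes` (one row per bin; the
#'   counts partition the proteome).
#' @export
motif_bin_summary <- function(profiles) {
  tab <- table(factor(profiles$bin, levels = PP_BIN_LEVELS))
  data.frame(bin = names(tab), n_genes = as.integer(tab),
             stringsAsFactors = FALSE)
}
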