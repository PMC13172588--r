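# Plain-text readers/writers for the pipeline's file formats.
# Counts travel as genes x samples TSV, sample metadata as CSV, trajectory
# panels as metabolite x ordered-group CSV, gene sets as GMT.

#' Write a counts experiment to TSV + sample CSV
#'
#' @param experiment a [counts_experiment()].
#' @param counts_file TSV path; first column `gene`, then one column per
#'   sample id.
#' @param samples_file CSV path with columns sample, assay, condition,
#'   replicate.
#' @return invisibly, the two paths.
#' @export
write_counts <- function(experiment, counts_file, samples_file) {
  stopifnot(inherits(experiment, "counts_experiment"))
  df <- data.frame(gene = rownames(experiment$counts), experiment$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(experiment$samples[, c("sample", "assay", "condition", "replicate")],
            samples_file, row.names = FALSE, quote = FALSE)
  invisible(c(counts_file, samples_file))
}

#' Read a counts experiment from TSV + sample CSV
#'
#' @param counts_file,samples_file paths as written by [write_counts()].
#' @return a [counts_experiment()].
#' @export
read_counts <- function(counts_file, samples_file) {
  df <- read.delim(counts_file, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  samples <- read.csv(samples_file, stringsAsFactors = FALSE)
  counts_experiment(counts, samples)
}

#' Write a metabolite panel
#'
#' @param panel a `metabolite_panel` (see [simulate_panels()]).
#' @param means_file CSV path for the metabolite x ordered-group mean matrix
#'   (first column `metabolite`, remaining columns the ordered groups).
#' @param samples_file optional CSV path for replicate-level values (first
#'   column `sample`, second `group`, then one column per metabolite).
#' @return invisibly, the written paths.
#' @export
write_panel <- function(panel, means_file, samples_file = NULL) {
  df <- data.frame(metabolite = rownames(panel$abundance), panel$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, means_file, row.names = FALSE, quote = FALSE)
  if (!is.null(samples_file) && !is.null(panel$samples)) {
    sdf <- data.frame(sample = rownames(panel$samples),
                      group = as.character(panel$sample_group),
                      panel$samples, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.csv(sdf, samples_file, row.names = FALSE, quote = FALSE)
  }
  invisible(c(means_file, samples_file))
}

#' Read a metabolite panel
#'
#' @param means_file CSV as written by [write_panel()]; column order gives
#'   the group ordering.
#' @param samples_file optional replicate-level CSV.
#' @param cohort cohort id (defaults to the file name).
#' @param scale `"raw"` for concentration-scale panels (standardised by the
#'   pipeline before clustering) or `"zscore"` for panels whose values are
#'   already standardised trajectory profiles.
#' @return a `metabolite_panel` list.
#' @export
read_panel <- function(means_file, samples_file = NULL, cohort = NULL,
                       scale = c("raw", "zscore")) {
  scale <- match.arg(scale)
  df <- read.csv(means_file, check.names = FALSE, stringsAsFactors = FALSE)
  ab <- as.matrix(df[, -1, drop = FALSE])
  rownames(ab) <- df[[1]]
  panel <- list(cohort = cohort %||% sub("\\.csv$", "", basename(means_file)),
                groups = colnames(ab), abundance = ab, scale = scale,
                samples = NULL, sample_group = NULL, truth_shape = NULL)
  if (!is.null(samples_file)) {
    sdf <- read.csv(samples_file, check.names = FALSE, stringsAsFactors = FALSE)
    smat <- as.matrix(sdf[, -(1:2), drop = FALSE])
    rownames(smat) <- sdf[[1]]
    panel$samples <- smat
    panel$sample_group <- factor(sdf[[2]], levels = panel$groups)
  }
  class(panel) <- "metabolite_panel"
  panel
}

#' Write gene sets as GMT
#'
#' One tab-separated line per set: name, description, members.
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return invisibly, the path.
#' @export
write_gmt <- function(sets, path, description = "") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from GMT
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
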