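#' Default trajectory-panel designs
#'
#' Two cohorts mirroring a serum amino-acid study design: a clinical cohort
#' with ordered groups control < NM < EHM (71 metabolites, 42 of them on a
#' rising trajectory; group sizes 20/50/41) and an orthotopic mouse cohort
#' sampled weekly from week 2 to week 5 (72 metabolites, 27 rising; n = 6 per
#' week).  `shape_counts` gives the number of metabolites planted per
#' trajectory shape.
#'
#' @return list of per-cohort design lists with fields `cohort`, `groups`,
#'   `shape_counts` and `group_n` (replicates per group).
#' @export
default_panel_design <- function() {
  list(
    list(cohort = "cohort1",
         groups = c("control", "NM", "EHM"),
         shape_counts = c(increasing = 42L, decreasing = 10L,
                          flat = 10L, peaked = 9L),
         group_n = c(20L, 50L, 41L)),
    list(cohort = "mouse",
         groups = c("week2", "week3", "week4", "week5"),
         shape_counts = c(increasing = 27L, decreasing = 15L,
                          flat = 15L, peaked = 15L),
         group_n = c(6L, 6L, 6L, 6L))
  )
}

#' Default shared rising metabolites
#'
#' Sixteen amino acids planted with an increasing trajectory in every cohort,
#' so that the cross-cohort intersection has a known truth.
#'
#' @return character vector of 16 metabolite names.
#' @export
default_shared_metabolites <- function() {
  c("proline", "serine", "alanine", "histidine", "threonine", "methionine",
    "isoleucine", "glycine", "valine", "leucine", "lysine", "arginine",
    "phenylalanine", "tyrosine", "tryptophan", "glutamine")
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic study.  The count
#' model is negative binomial with mean mu and variance mu(1 + phi*mu)
#' (`dispersion` = phi); in the treated condition the ribosome-footprint mean
#' of a responsive gene is attenuated by `2^(-beta * pp_count)`, i.e. `beta`
#' is the translational repression per PP motif in log2 units.
#'
#' @param n_genes number of genes.
#' @param mean_length mean protein length in residues.
#' @param pp_bin_probs probability vector over the PP-count bins
#'   `0, 1, 2, 3, >=4`; must sum to 1.
#' @param n_reps replicates per condition (the treated/control ribosome
#'   profiling design uses 3 per group).
#' @param baseline_mu mean expression per gene in counts.
#' @param dispersion NB dispersion phi >= 0 (0 gives Poisson counts).
#' @param beta log2 translational repression per PP motif in responsive
#'   genes under treatment; negative values model activation.
#' @param frac_responsive fraction of PP-containing genes that respond.
#' @param lib_size target reads per library; defaults to
#'   `n_genes * baseline_mu`.
#' @param panels per-cohort trajectory designs, see [default_panel_design()].
#' @param shared_increasing metabolite names planted as increasing in every
#'   cohort, see [default_shared_metabolites()].
#' @param noise_sd Gaussian noise sd on the z-scale trajectory means.
#' @param n_pathways number of pathway gene sets (>= 3); exactly one is
#'   planted as enriched among truly TE-down genes.
#' @param pathway_size genes per pathway set.
#' @param metastasis_size size of the planted metastasis-associated set.
#' @param metastasis_or sampling odds ratio of metastasis-set membership for
#'   responsive PP-containing genes (1 = independence).
#' @param seed integer master seed; all sub-generators derive child seeds
#'   from it by fixed offsets.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L, mean_length = 400L,
                       pp_bin_probs = c("0" = 0.50, "1" = 0.20, "2" = 0.12,
                                        "3" = 0.08, ">=4" = 0.10),
                       n_reps = 3L, baseline_mu = 500, dispersion = 0.1,
                       beta = 1, frac_responsive = 0.3,
                       lib_size = NULL,
                       panels = default_panel_design(),
                       shared_increasing = default_shared_metabolites(),
                       noise_sd = 0.3,
                       n_pathways = 5L, pathway_size = 40L,
                       metastasis_size = 300L, metastasis_or = 4,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), mean_length = as.integer(mean_length),
              pp_bin_probs = pp_bin_probs, n_reps = as.integer(n_reps),
              baseline_mu = baseline_mu, dispersion = dispersion, beta = beta,
              frac_responsive = frac_responsive,
              lib_size = if (is.null(lib_size)) n_genes * baseline_mu else lib_size,
              panels = panels, shared_increasing = shared_increasing,
              noise_sd = noise_sd, n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              metastasis_size = as.integer(metastasis_size),
              metastasis_or = metastasis_or, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$pp_bin_probs) != 5L || any(cfg$pp_bin_probs < 0)) {
    stop("pp_bin_probs must be a non-negative vector over the 5 bins", call. = FALSE)
  }
  if (abs(sum(cfg$pp_bin_probs) - 1) > 1e-9) {
    stop("pp_bin_probs must sum to 1 (within 1e-9)", call. = FALSE)
  }
  pos <- c(n_genes = cfg$n_genes, mean_length = cfg$mean_length,
           n_reps = cfg$n_reps, baseline_mu = cfg$baseline_mu,
           lib_size = cfg$lib_size, n_pathways = cfg$n_pathways,
           pathway_size = cfg$pathway_size, metastasis_size = cfg$metastasis_size)
  if (any(pos <= 0)) {
    stop("counts and sizes must be strictly positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "), call. = FALSE)
  }
  if (cfg$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$frac_responsive < 0 || cfg$frac_responsive > 1) {
    stop("frac_responsive must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$metastasis_or <= 0) stop("metastasis_or must be > 0", call. = FALSE)
  if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  invisible(cfg)
}

# planted trajectory means on the z scale, in [-1.5, 1.5]
shape_means <- function(shape, n_groups) {
  pos <- seq(0, 1, length.out = n_groups)
  switch(shape,
         increasing = seq(-1.2, 1.2, length.out = n_groups),
         decreasing = seq(1.2, -1.2, length.out = n_groups),
         flat = rep(0, n_groups),
         peaked = 1.2 - 4.4 * abs(pos - 0.5),
         stop("unknown trajectory shape: ", shape, call. = FALSE))
}

#' Generate a synthetic proteome with planted PP-motif content
#'
#' Each gene is assigned a PP-count bin from `pp_bin_probs` (the `>=4` bin
#' draws a count in 4..6).  Sequences are uniform random over the 19
#' non-proline amino acids, with proline runs inserted at non-overlapping,
#' non-adjacent positions so that a rescan recovers exactly the planted PP
#' count.  PP-containing genes are flagged responsive with probability
#' `frac_responsive`.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `gene`, `length`, `pp_count`, `bin`,
#'   `responsive`, `sequence`.
#' @export
generate_proteome <- function(config) {
  validate_sim_config(config)
  if (config$n_genes < 1L) stop("zero-length proteome requested", call. = FALSE)
  set.seed(child_seed(config$seed, 11L))
  n <- config$n_genes
  bins <- sample(0:4, n, replace = TRUE, prob = config$pp_bin_probs)
  pp <- ifelse(bins == 4L, sample(4:6, n, replace = TRUE), bins)
  lens <- pmax(60L, as.integer(round(rnorm(n, config$mean_length,
                                           0.25 * config$mean_length))))
  bg <- setdiff(AA_ALPHABET20, "P")
  seqs <- character(n)
  for (i in seq_len(n)) {
    ci <- pp[i]
    if (ci == 0L) {
      seqs[i] <- paste(sample(bg, lens[i], replace = TRUE), collapse = "")
      next
    }
    # split the PP count over 1-3 proline runs; a run of length r yields r-1 PP
    npieces <- sample.int(min(ci, 3L), 1L)
    parts <- if (npieces == 1L) ci else {
      cuts <- sort(sample.int(ci - 1L, npieces - 1L))
      diff(c(0L, cuts, ci))
    }
    run_len <- parts + 1L
    n_bg <- max(lens[i] - sum(run_len), npieces + 1L)
    # background segment lengths, each >= 1, so runs never touch
    seg_cuts <- sort(sample.int(n_bg - 1L, npieces))
    seg_len <- diff(c(0L, seg_cuts, n_bg))
    segs <- split(sample(bg, n_bg, replace = TRUE),
                  rep(seq_along(seg_len), seg_len))
    pieces <- character(2L * npieces + 1L)
    pieces[seq(1L, length(pieces), by = 2L)] <-
      vapply(segs, paste, character(1), collapse = "")
    pieces[seq(2L, length(pieces) - 1L, by = 2L)] <-
      vapply(run_len, function(r) strrep("P", r), character(1))
    seqs[i] <- paste(pieces, collapse = "")
  }
  responsive <- pp > 0L & runif(n) < config$frac_responsive
  data.frame(gene = sprintf("G%05d", seq_len(n)),
             length = nchar(seqs),
             pp_count = as.integer(pp),
             bin = pp_bin(pp),
             responsive = responsive,
             sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Simulate paired RNA/RPF counts with motif-dependent repression
#'
#' Per-gene expected expression is drawn from a Gamma distribution with mean
#' `baseline_mu` and rescaled so that the expected library total equals
#' `lib_size`.  RNA counts are NB(mu, phi) identically distributed in both
#' conditions; ribosome-footprint (RPF) counts are NB(mu * t_g, phi) with
#' `t_g = 2^(-beta * pp_count)` for responsive genes in the treated
#' condition and `t_g = 1` otherwise.  Treated RPF library totals are
#' consequently attenuated by the planted global translational inhibition;
#' no renormalisation is applied.
#'
#' @param config a [sim_config()].
#' @param proteome data.frame from [generate_proteome()] (columns `gene`,
#'   `pp_count`, `responsive`).
#' @return a [counts_experiment()] with `2 * 2 * n_reps` libraries and a
#'   `"planted_log2fc"` attribute (per-gene planted log2 TE fold change).
#' @export
simulate_counts <- function(config, proteome) {
  validate_sim_config(config)
  stopifnot(all(c("gene", "pp_count", "responsive") %in% names(proteome)))
  set.seed(child_seed(config$seed, 23L))
  n <- nrow(proteome)
  lambda <- rgamma(n, shape = 2, rate = 2 / config$baseline_mu)
  mu <- lambda / sum(lambda) * config$lib_size
  tg <- ifelse(proteome$responsive, 2^(-config$beta * proteome$pp_count), 1)
  conds <- c("control", "treated")
  assays <- c("rna", "rpf")
  samples <- expand.grid(replicate = seq_len(config$n_reps),
                         condition = conds, assay = assays,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("assay", "condition", "replicate")]
  samples$sample <- sprintf("%s_%s_r%d", samples$assay, samples$condition,
                            samples$replicate)
  draw <- function(mu_vec) {
    if (config$dispersion > 0) {
      rnbinom(length(mu_vec), mu = mu_vec, size = 1 / config$dispersion)
    } else {
      rpois(length(mu_vec), mu_vec)
    }
  }
  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(proteome$gene, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu_j <- if (samples$assay[j] == "rpf" && samples$condition[j] == "treated") {
      mu * tg
    } else {
      mu
    }
    counts[, j] <- draw(mu_j)
  }
  ce <- counts_experiment(counts, samples)
  attr(ce, "planted_log2fc") <- stats::setNames(log2(tg), proteome$gene)
  ce
}

#' Simulate metabolite trajectory panels
#'
#' Each metabolite is assigned a true shape (increasing, decreasing, flat or
#' peaked); group means follow the shape on the z scale before Gaussian noise
#' of sd `noise_sd` is added.  Metabolites named in `shared_increasing` are
#' present in every cohort with the increasing shape; all other names are
#' cohort-specific.  Per-group replicate samples (shape mean + noise) are
#' generated alongside the mean panel for ordination and PERMANOVA.
#'
#' @param config a [sim_config()].
#' @return named list of `metabolite_panel` objects, one per cohort, each a
#'   list with `cohort`, `groups`, `abundance` (metabolite x group means),
#'   `samples` (replicate matrix), `sample_group`, and `truth_shape`.
#' @export
simulate_panels <- function(config) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, 37L))
  out <- list()
  for (design in config$panels) {
    g <- design$groups
    if (length(g) < 3L) {
      stop("fewer than 3 ordered groups: monotone selection undefined", call. = FALSE)
    }
    sc <- design$shape_counts
    shared <- config$shared_increasing
    if (length(shared) > sc[["increasing"]]) {
      stop("shared increasing subset larger than the cohort's increasing cluster",
           call. = FALSE)
    }
    shapes <- rep(names(sc), sc)
    n_met <- length(shapes)
    own <- sprintf("%s_met%03d", design$cohort, seq_len(n_met - length(shared)))
    names_all <- c(shared, own)
    # shared names take the first `length(shared)` increasing slots
    ord <- order(shapes != "increasing")
    shapes <- shapes[ord]
    centers <- t(vapply(shapes, shape_means, numeric(length(g)),
                        n_groups = length(g)))
    noise <- matrix(rnorm(n_met * length(g), 0, config$noise_sd),
                    nrow = n_met)
    abundance <- centers + noise
    dimnames(abundance) <- list(names_all, g)
    # replicate-level samples
    gn <- design$group_n
    sample_group <- factor(rep(g, gn), levels = g)
    smat <- matrix(0, nrow = sum(gn), ncol = n_met,
                   dimnames = list(sprintf("%s_s%03d", design$cohort, seq_len(sum(gn))),
                                   names_all))
    for (i in seq_len(sum(gn))) {
      gi <- match(as.character(sample_group[i]), g)
      smat[i, ] <- centers[, gi] + rnorm(n_met, 0, config$noise_sd)
    }
    panel <- list(cohort = design$cohort, groups = g, abundance = abundance,
                  scale = "zscore",
                  samples = smat, sample_group = sample_group,
                  truth_shape = stats::setNames(shapes, names_all))
    class(panel) <- "metabolite_panel"
    out[[design$cohort]] <- panel
  }
  out
}

#' Generate synthetic gene-set collections
#'
#' Builds (a) a metastasis-associated set whose membership is sampled with a
#' configurable odds ratio of over-representation among responsive
#' PP-containing genes, and (b) `n_pathways` pathway sets of which exactly
#' one is planted as enriched among truly TE-down genes (responsive genes
#' whose planted repression exceeds the 1.5 log2 classification threshold).
#'
#' @param config a [sim_config()].
#' @param proteome data.frame from [generate_proteome()].
#' @return list with `sets` (named list of gene-id vectors, the metastasis
#'   set first), `metastasis_name` and `planted_pathway`.
#' @export
generate_gene_sets <- function(config, proteome) {
  validate_sim_config(config)
  if (config$pathway_size < 1L) stop("empty pathway requested", call. = FALSE)
  if (config$n_pathways < 3L) stop("need at least 3 pathway sets", call. = FALSE)
  if (config$pathway_size > config$n_genes ||
      config$metastasis_size > config$n_genes) {
    stop("requested set size exceeds the number of genes", call. = FALSE)
  }
  set.seed(child_seed(config$seed, 53L))
  genes <- proteome$gene
  hot <- proteome$responsive & proteome$pp_count >= 1L
  w <- ifelse(hot, config$metastasis_or, 1)
  metastasis <- sort(sample(genes, config$metastasis_size, prob = w))
  # truth: genes whose planted TE log2FC is below -1.5
  truth_down <- genes[proteome$responsive &
                        config$beta * proteome$pp_count > 1.5]
  sets <- list(METASTASIS = metastasis)
  planted_idx <- 1L  # first pathway is the planted one; order is randomised below
  pw_names <- sprintf("PATHWAY_%02d", seq_len(config$n_pathways))
  for (i in seq_len(config$n_pathways)) {
    if (i == planted_idx && length(truth_down) > 0L) {
      k1 <- min(length(truth_down), round(0.7 * config$pathway_size))
      members <- sample(truth_down, k1)
      rest <- sample(setdiff(genes, members), config$pathway_size - k1)
      sets[[pw_names[i]]] <- sort(c(members, rest))
    } else {
      sets[[pw_names[i]]] <- sort(sample(genes, config$pathway_size))
    }
  }
  list(sets = sets, metastasis_name = "METASTASIS",
       planted_pathway = pw_names[planted_idx])
}

#' Simulate the full synthetic study
#'
#' Runs every generator with child seeds of `config$seed` and bundles the
#' results with the planted truth.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_study`: list with `proteome`, `counts`,
#'   `panels`, `gene_sets`, `truth` and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  proteome <- generate_proteome(config)
  counts <- simulate_counts(config, proteome)
  panels <- simulate_panels(config)
  gene_sets <- generate_gene_sets(config, proteome)
  truth <- list(
    seed = config$seed,
    beta = config$beta,
    genes = data.frame(gene = proteome$gene, pp_count = proteome$pp_count,
                       responsive = proteome$responsive,
                       planted_log2fc = as.numeric(attr(counts, "planted_log2fc")),
                       stringsAsFactors = FALSE),
    shared_increasing = config$shared_increasing,
    panel_shapes = lapply(panels, function(p) as.list(p$truth_shape)),
    metastasis_set = gene_sets$sets[[gene_sets$metastasis_name]],
    planted_pathway = gene_sets$planted_pathway
  )
  study <- list(proteome = proteome, counts = counts, panels = panels,
                gene_sets = gene_sets, truth = truth, config = config)
  class(study) <- "synthetic_study"
  study
}

#' Write a synthetic study to disk
#'
#' Emits the plain-text formats the pipeline consumes: proteome FASTA,
#' counts TSV (genes x samples), sample-metadata CSV, per-cohort panel CSVs
#' (group means) and replicate CSVs, a GMT file with the metastasis and
#' pathway sets, and a truth JSON with the planted parameters.
#'
#' @param study a `synthetic_study` from [simulate_study()].
#' @param dir output directory, created if needed.
#' @return invisibly, a named character vector of the written file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    proteome = file.path(dir, "proteome.fasta"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.csv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  aa <- Biostrings::AAStringSet(study$proteome$sequence)
  names(aa) <- study$proteome$gene
  Biostrings::writeXStringSet(aa, paths[["proteome"]])
  write_counts(study$counts, paths[["counts"]], paths[["samples"]])
  write_gmt(study$gene_sets$sets, paths[["gene_sets"]],
            description = "synthetic")
  jsonlite::write_json(study$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (p in study$panels) {
    f <- file.path(dir, sprintf("panel_%s.csv", p$cohort))
    fs <- file.path(dir, sprintf("panel_%s_samples.csv", p$cohort))
    write_panel(p, f, fs)
    paths[[paste0("panel_", p$cohort)]] <- f
    paths[[paste0("panel_", p$cohort, "_samples")]] <- fs
  }
  invisible(paths)
}
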