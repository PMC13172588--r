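#' Pipeline configuration
#'
#' Assembles (and validates) the configuration of the end-to-end synthetic
#' study replica: simulation parameters, analysis thresholds and the output
#' directory.  Can also be loaded from a YAML file whose top-level keys
#' match the arguments (`sim` holds [sim_config()] arguments).
#'
#' @param out_dir run directory (created by [run_pipeline()]).
#' @param seed master seed; overrides `sim$seed`.
#' @param sim list of [sim_config()] arguments.
#' @param lfc_threshold,alpha differential-TE classification thresholds.
#' @param pseudocount,min_count TE computation / filtering parameters.
#' @param k cluster number for trajectory clustering, or `"auto"` for the
#'   elbow method.
#' @param k_range candidate k values when `k = "auto"`.
#' @param m fuzzifier.
#' @param min_membership membership cutoff for cluster membership reports.
#' @param direction trajectory direction of interest.
#' @param n_permutations PERMANOVA permutations.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = list(),
                            lfc_threshold = 1.5, alpha = 0.05,
                            pseudocount = 1, min_count = 5,
                            k = "auto", k_range = 2:8, m = 2,
                            min_membership = 0.5,
                            direction = "increasing",
                            n_permutations = 999L) {
  if (missing(out_dir) || !nzchar(out_dir)) stop("out_dir is required", call. = FALSE)
  if (lfc_threshold <= 0 || alpha <= 0 || pseudocount <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  sim$seed <- as.integer(seed)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              sim = do.call(sim_config, sim),
              lfc_threshold = lfc_threshold, alpha = alpha,
              pseudocount = pseudocount, min_count = min_count,
              k = k, k_range = k_range, m = m,
              min_membership = min_membership, direction = direction,
              n_permutations = as.integer(n_permutations))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @param out_dir,seed optional overrides.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(seed)) y$seed <- seed
  do.call(pipeline_config, y)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the end-to-end synthetic-study pipeline
#'
#' Orchestrates simulate -> motif scan -> translation efficiency ->
#' enrichment -> trajectory clustering, writing every stage's tables under
#' `config$out_dir` together with a `manifest.json` holding the seeds,
#' thresholds and md5 hashes of all outputs.  Re-running with the same
#' configuration reproduces byte-identical files.  A stage failure aborts
#' with the stage named and leaves partial outputs under a `failed/` marker.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return invisibly, a list with `dir`, `manifest`, and the main in-memory
#'   results (`te`, `motifs`, `venn`, `ora`, `candidates`, `trajectory`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  on_fail <- function() {
    file.create(file.path(config$out_dir, "failed"))
  }
  res <- tryCatch(
    run_pipeline_stages(config),
    error = function(e) { on_fail(); stop(e) }
  )
  invisible(res)
}

run_pipeline_stages <- function(config) {
  dir <- config$out_dir

  # 1 - simulate ------------------------------------------------------------
  study <- pipeline_stage("simulate", {
    s <- simulate_study(config$sim)
    write_study(s, dir)
    s
  })

  # 2 - motif scan ----------------------------------------------------------
  motifs <- pipeline_stage("motif_scan", {
    fasta <- file.path(dir, "proteome.fasta")
    if (!file.exists(fasta)) stop("missing input: proteome.fasta")
    prof <- profile_proteome(fasta)
    write_tsv(prof, file.path(dir, "motif_profiles.tsv"))
    write_tsv(motif_bin_summary(prof), file.path(dir, "motif_bin_summary.tsv"))
    prof
  })

  # 3 - translation efficiency ----------------------------------------------
  te_res <- pipeline_stage("translation_efficiency", {
    cf <- file.path(dir, "counts.tsv")
    sf <- file.path(dir, "samples.csv")
    if (!file.exists(cf) || !file.exists(sf)) {
      stop("missing input: counts.tsv / samples.csv")
    }
    ce <- read_counts(cf, sf)
    te <- compute_te(ce, pseudocount = config$pseudocount)
    res <- differential_te(te, control = "control", treated = "treated",
                           lfc_threshold = config$lfc_threshold,
                           alpha = config$alpha, min_count = config$min_count)
    write_tsv(res, file.path(dir, "te_results.tsv"))
    res
  })

  # 4 - enrichment ----------------------------------------------------------
  enr <- pipeline_stage("enrichment", {
    gmt_path <- file.path(dir, "gene_sets.gmt")
    if (!file.exists(gmt_path)) stop("missing input: gene_sets.gmt")
    sets <- read_gmt(gmt_path)
    if (!("METASTASIS" %in% names(sets))) stop("missing METASTASIS set in GMT")
    pathways <- sets[setdiff(names(sets), "METASTASIS")]
    mp <- match(te_res$gene, motifs$gene)
    contains_pp <- motifs$contains_pp[mp]
    up <- te_res$class == "up"
    down <- te_res$class == "down"
    tab <- rbind(up = c(pp = sum(up & contains_pp), free = sum(up & !contains_pp)),
                 down = c(pp = sum(down & contains_pp), free = sum(down & !contains_pp)))
    ct <- tryCatch(contingency_test(tab, method = "chi2"),
                   error = function(e) list(statistic = NA_real_,
                                            p_value = NA_real_,
                                            method = "chi2 (zero margin)"))
    rt <- if (any(up) && any(down)) {
      rank_test(motifs$pp_count[mp][up], motifs$pp_count[mp][down])
    } else {
      list(U = NA_real_, p_value = NA_real_, exact = NA)
    }
    rest <- te_res$tested & !down
    tab_down <- rbind(down = c(pp = sum(down & contains_pp),
                               free = sum(down & !contains_pp)),
                      rest = c(pp = sum(rest & contains_pp),
                               free = sum(rest & !contains_pp)))
    ct_down <- contingency_test(tab_down, method = "chi2")
    assoc <- data.frame(
      test = c("chi2_pp_by_class", "chi2_pp_down_vs_rest",
               "mannwhitney_ppcount_up_vs_down"),
      statistic = c(ct$statistic, ct_down$statistic, rt$U),
      p_value = c(ct$p_value, ct_down$p_value, rt$p_value),
      stringsAsFactors = FALSE)
    write_tsv(assoc, file.path(dir, "enrichment_association.tsv"))
    # three-way intersection: metastasis set, TE-down genes, PP-containing
    # genes among the genes with altered TE
    te_down <- te_res$gene[down]
    altered <- te_res$gene[up | down]
    pp_altered <- altered[motifs$contains_pp[match(altered, motifs$gene)]]
    venn <- intersect3(sets$METASTASIS, te_down, pp_altered,
                       set_names = c("metastasis", "te_down", "pp_altered"))
    write_tsv(data.frame(region = names(venn$regions), size = venn$regions,
                         stringsAsFactors = FALSE),
              file.path(dir, "venn_regions.tsv"))
    writeLines(venn$common, file.path(dir, "candidates.txt"))
    universe <- te_res$gene[te_res$tested]
    ora <- ora_test(te_down, pathways, universe)
    write_tsv(ora, file.path(dir, "ora_results.tsv"))
    list(table = tab, contingency = ct, table_down = tab_down,
         contingency_down = ct_down, rank = rt, venn = venn, ora = ora,
         candidates = venn$common)
  })

  # 5 - trajectory clustering -----------------------------------------------
  traj <- pipeline_stage("trajectory", {
    members <- list()
    details <- list()
    for (p in study$panels) {
      # panels already on the z scale are clustered as-is; re-standardising
      # them would blow noise-only (flat) profiles up to unit norm
      z <- if (identical(p$scale, "zscore")) p$abundance else
        zscore_profiles(p$abundance)
      k <- if (identical(config$k, "auto")) {
        kr <- config$k_range[config$k_range <= nrow(unique(z)) - 1L]
        choose_k_elbow(z, k_range = kr, m = config$m,
                       seed = child_seed(config$seed, 200L))$k
      } else {
        as.integer(config$k)
      }
      fit <- fuzzy_cmeans(z, k, m = config$m,
                          seed = child_seed(config$seed, 300L))
      sel <- select_monotone_cluster(fit, direction = config$direction,
                                     min_membership = config$min_membership)
      memb <- data.frame(metabolite = rownames(z),
                         cluster = fit$assignment,
                         membership = fit$memberships[cbind(seq_len(nrow(z)),
                                                            fit$assignment)],
                         selected = rownames(z) %in% sel,
                         stringsAsFactors = FALSE)
      write_tsv(memb, file.path(dir, sprintf("clusters_%s.tsv", p$cohort)))
      write_tsv(data.frame(cluster = rownames(fit$centers), fit$centers,
                           check.names = FALSE, stringsAsFactors = FALSE),
                file.path(dir, sprintf("centers_%s.tsv", p$cohort)))
      perm <- pcoa <- NULL
      if (!is.null(p$samples)) {
        dmat <- dist(p$samples)
        perm <- permanova(dmat, p$sample_group,
                          n_permutations = config$n_permutations,
                          seed = child_seed(config$seed, 400L))
        pcoa <- pcoa_embed(dmat, n_axes = 2L)
        write_tsv(data.frame(statistic = c("F", "R2", "p_value"),
                             value = c(perm$F, perm$R2, perm$p_value),
                             stringsAsFactors = FALSE),
                  file.path(dir, sprintf("permanova_%s.tsv", p$cohort)))
        write_tsv(data.frame(sample = rownames(pcoa$points),
                             group = as.character(p$sample_group),
                             pcoa$points, stringsAsFactors = FALSE),
                  file.path(dir, sprintf("pcoa_%s.tsv", p$cohort)))
      }
      members[[p$cohort]] <- sel
      details[[p$cohort]] <- list(k = k, fit = fit, permanova = perm, pcoa = pcoa)
    }
    common <- intersect_cohorts(members)
    writeLines(common, file.path(dir, "trajectory_intersection.txt"))
    list(members = members, common = common, details = details)
  })

  # manifest ------------------------------------------------------------------
  manifest <- pipeline_stage("manifest", {
    files <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.json"))
    m <- list(
      package = "ribopp",
      version = as.character(utils::packageVersion("ribopp")),
      seed = config$seed,
      thresholds = list(lfc_threshold = config$lfc_threshold,
                        alpha = config$alpha,
                        pseudocount = config$pseudocount,
                        min_count = config$min_count,
                        min_membership = config$min_membership,
                        k = config$k, m = config$m,
                        n_permutations = config$n_permutations),
      files = as.list(tools::md5sum(file.path(dir, files)))
    )
    names(m$files) <- files
    jsonlite::write_json(m, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })

  list(dir = dir, manifest = manifest, te = te_res, motifs = motifs,
       venn = enr$venn, ora = enr$ora,
       association = enr[c("table", "contingency", "table_down",
                           "contingency_down", "rank")],
       candidates = enr$candidates, trajectory = traj, study = study)
}
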