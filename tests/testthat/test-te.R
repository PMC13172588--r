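make_ce <- function(counts, conds = NULL) {
  # helper: counts is genes x 4 matrix (rna_c, rpf_c, rna_t, rpf_t) per rep
  counts_experiment(counts, data.frame(
    sample = colnames(counts),
    assay = rep(c("rna", "rpf"), length.out = ncol(counts)),
    condition = conds %||% rep("control", ncol(counts)),
    replicate = rep(seq_len(ncol(counts) / 2), each = 2)
  ))
}

test_that("counts_experiment enforces matched rna/rpf pairs and valid counts", {
  m <- matrix(1:8, 2, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  smp <- data.frame(sample = paste0("s", 1:4),
                    assay = c("rna", "rpf", "rna", "rpf"),
                    condition = c("a", "a", "b", "b"),
                    replicate = c(1, 1, 1, 1))
  expect_s3_class(counts_experiment(m, smp), "counts_experiment")
  bad <- smp; bad$assay <- c("rna", "rna", "rna", "rpf")
  expect_error(counts_experiment(m, bad), "matched rna/rpf pair")
  m2 <- m; m2[1, 1] <- -1
  expect_error(counts_experiment(m2, smp), "negative")
})

test_that("TE is 1 for a gene with equal rna/rpf counts in identical libraries", {
  m <- matrix(c(10, 30, 10, 30), 2,
              dimnames = list(c("g1", "g2"), c("rna1", "rpf1")))
  te <- compute_te(make_ce(m))
  expect_equal(unname(te$te[, 1]), c(1, 1))
})

test_that("rna = 0 with pseudocount 1 gives finite positive TE", {
  m <- matrix(c(0, 100, 50, 100), 2,
              dimnames = list(c("g1", "g2"), c("rna1", "rpf1")))
  te <- compute_te(make_ce(m), pseudocount = 1)
  expect_true(all(is.finite(te$te)) && all(te$te > 0))
  expect_error(compute_te(make_ce(m), pseudocount = 0), "pseudocount")
})

test_that("TE with a depth-scaled pseudocount is exactly depth invariant", {
  set.seed(1)
  m <- matrix(rpois(20, 60), 10,
              dimnames = list(paste0("g", 1:10), c("rna1", "rpf1")))
  te1 <- compute_te(make_ce(m), pseudocount = 1)
  # doubling every library together with the pseudocount leaves CPMs untouched
  te2 <- compute_te(make_ce(2L * m), pseudocount = 2)
  expect_equal(te2$te[, 1], te1$te[, 1], tolerance = 1e-12)
  # with the pseudocount held fixed the distortion is order pseudocount/count
  m3 <- m; m3[, 2] <- 2L * m3[, 2]
  te3 <- compute_te(make_ce(m3), pseudocount = 1)
  expect_equal(unname(te3$te[, 1]), unname(te1$te[, 1]), tolerance = 0.05)
})

test_that("TE is invariant to random per-library depth rescaling (to pseudocount order)", {
  set.seed(2)
  m <- matrix(rpois(200 * 4, 500), 200,
              dimnames = list(paste0("g", 1:200),
                              c("rna1", "rpf1", "rna2", "rpf2")))
  te1 <- compute_te(make_ce(m))
  f <- sample(c(2L, 3L, 5L), 4, replace = TRUE)
  te2 <- compute_te(make_ce(sweep(m, 2L, f, "*")))
  expect_lt(max(abs(log2(te2$te) - log2(te1$te))), 0.02)
})

test_that("missing assay partner raises an informative error", {
  m <- matrix(1:4, 1, dimnames = list("g1", paste0("s", 1:4)))
  smp <- data.frame(sample = paste0("s", 1:4), assay = rep("rna", 4),
                    condition = "a", replicate = 1:4)
  ce <- structure(list(counts = m, samples = smp), class = "counts_experiment")
  expect_error(compute_te(ce), "assay partner")
})

fake_te <- function(ctrl, trt, mean_rna = 100) {
  # build a te_matrix directly from per-replicate TE values (one gene per row)
  te <- cbind(ctrl, trt)
  colnames(te) <- c(paste0("control.", seq_len(ncol(ctrl))),
                    paste0("treated.", seq_len(ncol(trt))))
  structure(list(te = te,
                 condition = rep(c("control", "treated"),
                                 c(ncol(ctrl), ncol(trt))),
                 replicate = c(seq_len(ncol(ctrl)), seq_len(ncol(trt))),
                 mean_rna_count = rep(mean_rna, nrow(te))),
            class = "te_matrix")
}

test_that("differential TE classifies by |log2FC| > 1.5 and p < 0.05", {
  # identical TE vectors: log2fc 0, ns
  same <- fake_te(matrix(c(1, 1.1, 0.9), 1), matrix(c(1, 1.1, 0.9), 1))
  rownames(same$te) <- "g1"
  r <- differential_te(same, "control", "treated")
  expect_equal(r$log2fc, 0)
  expect_equal(r$class, "ns")

  # strong repression: log2fc ~ -2 with small p -> down
  dn <- fake_te(matrix(2^c(0, 0.02, -0.02), 1), matrix(2^c(-2, -1.98, -2.02), 1))
  rownames(dn$te) <- "g1"
  r <- differential_te(dn, "control", "treated")
  expect_lt(r$log2fc, -1.5)
  expect_lt(r$p_value, 0.05)
  expect_equal(r$class, "down")

  # same magnitude but not significant -> ns
  noisy <- fake_te(matrix(2^c(-1, 1, 0.5), 1), matrix(2^c(-3, 0.5, -2), 1))
  rownames(noisy$te) <- "g1"
  r <- differential_te(noisy, "control", "treated")
  expect_equal(r$class, "ns")
})

test_that("low-count genes are excluded from testing and flagged", {
  te <- fake_te(matrix(2^c(0, 0, 0), 1), matrix(2^c(-2, -2.1, -1.9), 1),
                mean_rna = 1)
  rownames(te$te) <- "g1"
  r <- differential_te(te, "control", "treated", min_count = 5)
  expect_false(r$tested)
  expect_true(is.na(r$p_value))
  expect_equal(r$class, "ns")
})

test_that("single-replicate designs report log2fc but no p-value", {
  te <- fake_te(matrix(1, 1), matrix(4, 1))
  rownames(te$te) <- "g1"
  expect_warning(r <- differential_te(te, "control", "treated"), "single replicate")
  expect_equal(r$log2fc, 2)
  expect_true(is.na(r$p_value))
  expect_equal(r$class, "ns")
})

test_that("reporter TE is the activity ratio over the mRNA ratio", {
  expect_equal(reporter_te(2, 1, 2, 1), 1)
  expect_equal(reporter_te(4, 1, 1, 1), 4)
  # scaling activity and mRNA of the firefly reporter by c cancels
  expect_equal(reporter_te(4 * 3, 1, 1 * 3, 1), reporter_te(4, 1, 1, 1))
  expect_error(reporter_te(0, 1, 1, 1), "positive")
  expect_error(reporter_te(1, -2, 1, 1), "positive")
})

test_that("polysome distribution normalises to proportions", {
  expect_equal(polysome_distribution(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(polysome_distribution(5), 1)
  x <- c(3, 1, 7, 2)
  perm <- c(3, 1, 4, 2)
  expect_equal(polysome_distribution(x)[perm], polysome_distribution(x[perm]))
  expect_equal(sum(polysome_distribution(runif(8))), 1, tolerance = 1e-9)
  expect_error(polysome_distribution(c(0, 0)), "all-zero")
  expect_error(polysome_distribution(c(-1, 2)), "non-negative")
})

test_that("type-I error is controlled on the null study and the equal-variance
           plug point is calibrated", {
  # beta = 0: no gene has a planted TE change
  st <- small_study(seed = 37, beta = 0)
  te <- compute_te(st$counts)
  welch <- differential_te(te, "control", "treated")
  student <- differential_te(te, "control", "treated", test = "student")
  ok <- welch$tested & !is.na(welch$p_value)
  half <- 2.576 * sqrt(0.05 * 0.95 / sum(ok))
  # Welch never exceeds the nominal level (it is conservative at n = 3)
  expect_lt(mean(welch$p_value[ok] < 0.05), 0.05 + half)
  # the equal-variance test sits inside the two-sided binomial band
  expect_gt(mean(student$p_value[ok] < 0.05), 0.05 - half)
  expect_lt(mean(student$p_value[ok] < 0.05), 0.05 + half)
  # and essentially no gene clears the fold-change + significance gate
  expect_lt(mean(welch$class != "ns"), 0.01)
})

test_that("counts round-trip through TSV/CSV unchanged", {
  st <- small_study(seed = 19)
  cf <- tempfile(fileext = ".tsv"); sf <- tempfile(fileext = ".csv")
  write_counts(st$counts, cf, sf)
  back <- read_counts(cf, sf)
  expect_equal(back$counts, st$counts$counts)
  expect_equal(back$samples$assay, st$counts$samples$assay)
})
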