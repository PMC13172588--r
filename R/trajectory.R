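#' Z-score trajectory profiles
#'
#' Standardises each row (metabolite) of a metabolite x ordered-group matrix
#' to mean 0 and sample sd 1 (n-1 denominator).  Constant rows become
#' all-zero and are flagged in the `"constant"` attribute.
#'
#' @param x numeric matrix, metabolites in rows, at least two ordered group
#'   columns.
#' @return matrix of z-scores with a logical `"constant"` attribute.
#' @examples
#' zscore_profiles(rbind(a = c(1, 2, 3)))  # (-1, 0, 1)
#' @export
zscore_profiles <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 groups to z-score", call. = FALSE)
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  const <- s == 0
  s[const] <- 1
  z <- (x - mu) / s
  z[const, ] <- 0
  attr(z, "constant") <- stats::setNames(const, rownames(x))
  z
}

# squared Euclidean distances between rows of x and rows of centers
sq_dist <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
  pmax(d2, 0)
}

fcm_fit_once <- function(x, k, m, tol, max_iter, zero_tol = 1e-12) {
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  obj <- numeric(0)
  j_prev <- Inf
  u <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist(x, centers)
    # membership update: u_ij proportional to (1/d^2)^(1/(m-1)); a profile
    # coinciding with a center takes full membership there (limit convention)
    w <- d2^(-1 / (m - 1))
    hit <- d2 < zero_tol
    anyhit <- rowSums(hit) > 0
    u <- w / rowSums(w)
    if (any(anyhit)) {
      u[anyhit, ] <- hit[anyhit, , drop = FALSE] /
        rowSums(hit[anyhit, , drop = FALSE])
    }
    um <- u^m
    j <- sum(um * d2)
    obj <- c(obj, j)
    if (is.finite(j_prev) && j_prev - j < tol) break
    j_prev <- j
    centers <- (t(um) %*% x) / colSums(um)
  }
  list(centers = centers, memberships = u, objective = j, trace = obj,
       iterations = iter)
}

#' Fuzzy c-means clustering of trajectory profiles
#'
#' Soft clustering by alternating membership and center updates:
#' memberships `u_ij` proportional to `(1/d^2(x_i, c_j))^(1/(m-1))`
#' normalised per row, centers `c_j = sum_i u_ij^m x_i / sum_i u_ij^m`.
#' Iteration stops when the objective decreases by less than `tol` or after
#' `max_iter` iterations; the best of `n_starts` random restarts (child
#' seeds derived from `seed`) is kept.
#'
#' @param x numeric matrix (profiles in rows, with rownames).
#' @param k number of clusters (>= 2 and <= number of distinct profiles).
#' @param m fuzzifier exponent (> 1, default 2).
#' @param tol convergence tolerance on the objective decrease.
#' @param max_iter iteration cap per restart.
#' @param n_starts random restarts.
#' @param seed integer seed.
#' @return object of class `fuzzy_cmeans`: list with `k`, `m`, `centers`,
#'   `memberships` (rows sum to 1), `assignment` (argmax membership,
#'   lowest-index tie-break), `objective`, `trace` (objective per
#'   iteration, non-increasing), `iterations`, `seed`.
#' @export
fuzzy_cmeans <- function(x, k, m = 2, tol = 1e-8, max_iter = 200L,
                         n_starts = 10L, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("row%d", seq_len(nrow(x)))
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop("k exceeds the number of distinct profiles", call. = FALSE)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(child_seed(seed, 1000L + s))
    fit <- fcm_fit_once(x, k, m, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  assign <- apply(best$memberships, 1L, which.max)  # lowest index wins ties
  rownames(best$memberships) <- rownames(x)
  rownames(best$centers) <- sprintf("cluster%d", seq_len(k))
  colnames(best$centers) <- colnames(x)
  structure(list(k = k, m = m, centers = best$centers,
                 memberships = best$memberships,
                 assignment = stats::setNames(assign, rownames(x)),
                 objective = best$objective, trace = best$trace,
                 iterations = best$iterations, seed = seed),
            class = "fuzzy_cmeans")
}

#' Choose the cluster number by the elbow method
#'
#' Fits fuzzy c-means for each k in `k_range` (best of `n_starts` restarts)
#' and operationalises the visual elbow as the k whose point (k, J(k)) lies
#' farthest from the chord joining the curve's endpoints (Kneedle-style
#' maximum chord distance).  A `k_range` of length 2 has a degenerate chord
#' and returns its smaller k with a warning; a non-monotone objective curve
#' (possible up to restart noise) also warns.
#'
#' @param x profile matrix.
#' @param k_range candidate cluster numbers (within `[2, nrow(x) - 1]`).
#' @inheritParams fuzzy_cmeans
#' @return list with `k` (selected), `curve` (data.frame k, objective) and
#'   `distances` (chord distances).
#' @export
choose_k_elbow <- function(x, k_range = 2:8, m = 2, n_starts = 10L,
                           seed = 1L, tol = 1e-8, max_iter = 200L) {
  x <- as.matrix(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > nrow(x) - 1L)) {
    stop("k_range must lie within [2, n_profiles - 1]", call. = FALSE)
  }
  js <- vapply(k_range, function(k) {
    fuzzy_cmeans(x, k, m = m, tol = tol, max_iter = max_iter,
                 n_starts = n_starts, seed = child_seed(seed, 10L * k))$objective
  }, numeric(1))
  curve <- data.frame(k = k_range, objective = js)
  if (any(diff(js) > max(1e-8, 1e-6 * js[1]))) {
    warning("objective curve is not monotone decreasing in k", call. = FALSE)
  }
  if (length(k_range) < 3L) {
    warning("k_range too short for an elbow; returning the smallest k",
            call. = FALSE)
    return(list(k = k_range[1], curve = curve,
                distances = rep(NA_real_, length(k_range))))
  }
  # perpendicular distance of each (k, J) from the chord between endpoints
  p1 <- c(k_range[1], js[1])
  p2 <- c(k_range[length(k_range)], js[length(js)])
  v <- p2 - p1
  nv <- sqrt(sum(v^2))
  dists <- vapply(seq_along(k_range), function(i) {
    w <- c(k_range[i], js[i]) - p1
    abs(v[1] * w[2] - v[2] * w[1]) / nv
  }, numeric(1))
  list(k = k_range[which.max(dists)], curve = curve, distances = dists)
}

#' Select members of strictly monotone clusters
#'
#' Clusters whose center vector is strictly monotone across the ordered
#' groups in the requested direction are selected; the returned metabolites
#' are those assigned (argmax membership) to a selected cluster with
#' membership at least `min_membership`.
#'
#' @param model a [fuzzy_cmeans()] fit.
#' @param direction `"increasing"` or `"decreasing"`.
#' @param min_membership membership cutoff (default 0.5).
#' @return character vector of member names (empty, with a warning, when no
#'   cluster is monotone); the selected cluster indices are in the
#'   `"clusters"` attribute.
#' @export
select_monotone_cluster <- function(model, direction = c("increasing", "decreasing"),
                                    min_membership = 0.5) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "fuzzy_cmeans"))
  mono <- apply(model$centers, 1L, function(v) {
    d <- diff(v)
    if (direction == "increasing") all(d > 0) else all(d < 0)
  })
  sel <- which(mono)
  if (!length(sel)) {
    warning("no strictly ", direction, " cluster found", call. = FALSE)
    return(structure(character(0), clusters = integer(0)))
  }
  top <- model$memberships[cbind(seq_len(nrow(model$memberships)),
                                 model$assignment)]
  keep <- model$assignment %in% sel & top >= min_membership
  structure(names(model$assignment)[keep], clusters = sel)
}

#' Intersect trajectory member sets across cohorts
#'
#' Exact name intersection after case/whitespace normalisation; the
#' per-cohort (normalised) sets are kept in the `"cohorts"` attribute for
#' provenance.
#'
#' @param member_sets list (>= 2) of character vectors, one per cohort.
#' @return sorted character vector of names present in every cohort.
#' @export
intersect_cohorts <- function(member_sets) {
  if (!is.list(member_sets) || length(member_sets) < 2L) {
    stop("need member sets from at least 2 cohorts", call. = FALSE)
  }
  norm <- lapply(member_sets, function(s) unique(norm_ids(s)))
  structure(sort(Reduce(intersect, norm)), cohorts = norm)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Embeds a distance matrix via eigen-decomposition of the double-centered
#' Gram matrix `-0.5 * C D^2 C`.  Axes are ordered by eigenvalue; axes with
#' negative eigenvalues are reported but dropped from the coordinates.
#'
#' @param d distance matrix (symmetric, zero diagonal, non-negative) or a
#'   `dist` object.
#' @param n_axes number of axes to return (capped by the number of positive
#'   eigenvalues).
#' @param tol asymmetry tolerance.
#' @return list with `points` (n x n_axes coordinates), `eigenvalues` (all,
#'   sorted decreasing) and `negative` (count of negative eigenvalues).
#' @export
pcoa_embed <- function(d, n_axes = 2L, tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > tol) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(d < -tol) || any(abs(diag(d)) > tol)) {
    stop("distances must be non-negative with a zero diagonal", call. = FALSE)
  }
  n <- nrow(d)
  cmat <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * cmat %*% (d^2) %*% cmat
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  pos <- which(e$values > tol * max(abs(e$values), 1))
  n_axes <- min(n_axes, length(pos))
  pts <- e$vectors[, pos[seq_len(n_axes)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(n_axes)]]), n_axes)
  rownames(pts) <- rownames(d)
  colnames(pts) <- sprintf("Axis%d", seq_len(n_axes))
  list(points = pts, eigenvalues = e$values,
       negative = sum(e$values < -tol * max(abs(e$values), 1)))
}

#' PERMANOVA (one-way, Anderson's pseudo-F)
#'
#' Partitions the total sum of squared interpoint distances into between-
#' and within-group components: `SS_T = sum_{i<j} d_ij^2 / n`,
#' `SS_W = sum_g sum_{i<j in g} d_ij^2 / n_g`, `SS_A = SS_T - SS_W`,
#' `F = (SS_A / (a-1)) / (SS_W / (n-a))`, `R^2 = SS_A / SS_T`.  The p-value
#' is `(1 + #{permuted F >= observed F}) / (n_permutations + 1)` under
#' random relabeling.
#'
#' @param d distance matrix or `dist` object.
#' @param groups group labels (>= 2 groups, each of size >= 2).
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list with `F`, `R2`, `p_value`, `n_permutations`, `seed`,
#'   `ss_between`, `ss_within`, `ss_total`.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = 1L) {
  d2 <- as.matrix(d)^2
  groups <- as.factor(groups)
  n <- nrow(d2)
  if (length(groups) != n) stop("labels must match the distance matrix", call. = FALSE)
  a <- nlevels(droplevels(groups))
  if (a < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("every group must have at least 2 members", call. = FALSE)
  }
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within_for <- function(lab) {
    sw <- 0
    for (g in levels(lab)) {
      idx <- which(lab == g)
      sw <- sw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    sw
  }
  ss_w <- ss_within_for(groups)
  ss_a <- ss_total - ss_w
  f_from_ssw <- function(sw) ((ss_total - sw) / (a - 1)) / (sw / (n - a))
  f_obs <- f_from_ssw(ss_w)
  set.seed(child_seed(seed, 77L))
  f_perm <- vapply(seq_len(n_permutations), function(i) {
    f_from_ssw(ss_within_for(groups[sample.int(n)]))
  }, numeric(1))
  p <- (1 + sum(f_perm >= f_obs)) / (n_permutations + 1)
  list(F = f_obs, R2 = ss_a / ss_total, p_value = p,
       n_permutations = n_permutations, seed = seed,
       ss_between = ss_a, ss_within = ss_w, ss_total = ss_total)
}
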