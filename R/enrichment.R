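#' Association test on a 2x2 contingency table
#'
#' Default is the chi-square test without continuity correction (its
#' statistic equals the textbook closed form
#' n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))).  `method = "auto"` falls back to
#' Fisher's exact test when any expected cell is below 5.
#'
#' @param table 2x2 matrix of non-negative counts (e.g. rows TE up/down,
#'   columns PP-containing / PP-free).
#' @param method `"chi2"`, `"fisher"` or `"auto"`.
#' @return list with `statistic` (chi-square statistic, NA for Fisher),
#'   `p_value`, `method`.
#' @export
contingency_test <- function(table, method = c("chi2", "fisher", "auto")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0)) {
    stop("table must be a 2x2 matrix of non-negative counts", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: the association p-value is undefined", call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (method == "auto") {
    method <- if (any(expected < 5)) "fisher" else "chi2"
  }
  if (method == "chi2") {
    ht <- suppressWarnings(chisq.test(table, correct = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value, method = "chi2")
  } else {
    ht <- fisher.test(table)
    list(statistic = NA_real_, p_value = ht$p.value, method = "fisher")
  }
}

# exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) label
# assignments; handles ties (U uses the 0.5 convention).
mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  mu <- n1 * (n - n1) / 2
  idx <- combn(n, n1)
  us <- apply(idx, 2L, function(i) u_stat(pooled[i], pooled[-i]))
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  list(U = u_obs, p_value = p)
}

#' Mann-Whitney rank test
#'
#' Two-sided Mann-Whitney U test.  When both groups have at most
#' `exact_max` observations the p-value is computed by exact enumeration of
#' all label assignments (valid under ties); otherwise the normal
#' approximation with tie correction is used.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact_max size threshold for exact enumeration (default 8).
#' @return list with `U` (statistic for group `a`), `p_value`, `exact`.
#' @examples
#' rank_test(c(4, 5, 6), c(1, 2, 3))$p_value  # exact 0.1
#' @export
rank_test <- function(a, b, exact_max = 8L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  if (length(a) <= exact_max && length(b) <= exact_max) {
    res <- mw_exact(a, b)
    list(U = res$U, p_value = res$p_value, exact = TRUE)
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
    list(U = unname(ht$statistic), p_value = ht$p.value, exact = FALSE)
  }
}

#' Three-way gene-set intersection
#'
#' Sizes of the 7 disjoint Venn regions of three sets plus the sorted common
#' intersection.  Identifiers are case-normalised and whitespace-stripped;
#' duplicates collapse with a warning.
#'
#' @param A,B,C character vectors of identifiers (empty sets allowed).
#' @param set_names names used in the region labels.
#' @return list with `regions` (named integer vector: `A_only`, `B_only`,
#'   `C_only`, `AB`, `AC`, `BC`, `ABC`), `common` (sorted members of all
#'   three), `union_size`, `set_names`.
#' @export
intersect3 <- function(A, B, C, set_names = c("A", "B", "C")) {
  A <- dedup_ids(A, "set A members")
  B <- dedup_ids(B, "set B members")
  C <- dedup_ids(C, "set C members")
  u <- union(union(A, B), C)
  inA <- u %in% A
  inB <- u %in% B
  inC <- u %in% C
  regions <- c(
    A_only = sum(inA & !inB & !inC),
    B_only = sum(!inA & inB & !inC),
    C_only = sum(!inA & !inB & inC),
    AB = sum(inA & inB & !inC),
    AC = sum(inA & !inB & inC),
    BC = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC)
  )
  list(regions = regions,
       common = sort(u[inA & inB & inC]),
       union_size = length(u),
       set_names = set_names)
}

#' Hypergeometric over-representation analysis
#'
#' For every gene set, the one-sided upper-tail hypergeometric p-value
#' P(X >= k) with X ~ Hypergeom(N, K, n), where N is the universe size, K
#' the set size inside the universe, n the query size and k the overlap.
#' Sets with zero overlap get p = 1.  P-values are BH-adjusted across all
#' tested sets and the result ranked by adjusted then raw p.
#'
#' @param query character vector of genes of interest (filtered to the
#'   universe).
#' @param collection named list of gene sets.
#' @param universe background gene vector (e.g. all genes with a computed
#'   TE); must be non-empty.
#' @param top optional integer: keep only the `top` best-ranked sets.
#' @return data.frame with columns `pathway`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value`, `genes` (comma-separated sorted overlap).
#' @export
ora_test <- function(query, collection, universe, top = NULL) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(collection)) stop("empty gene-set collection", call. = FALSE)
  universe <- dedup_ids(universe, "universe genes")
  query <- unique(norm_ids(query))
  query <- intersect(query, universe)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(norm_ids(collection[[nm]])), universe)
    K <- length(set)
    hits <- intersect(set, query)
    k <- length(hits)
    p <- if (k == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, k = k, K = K, n = n, N = N, p_value = p,
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$q_value, out$p_value, out$pathway), ]
  out <- out[, c("pathway", "k", "K", "n", "N", "p_value", "q_value", "genes")]
  rownames(out) <- NULL
  if (!is.null(top)) out <- utils::head(out, top)
  out
}
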