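# Independent oracles used across the suite.  These are deliberately naive
# (position-by-position loops, full enumeration) so they cannot share bugs
# with the vectorised implementations they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# naive O(n k) window scan for PP / PPG / PPP / longest proline run
oracle_scan <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  n <- length(ch)
  pp <- ppg <- ppp <- 0L
  if (n >= 2L) for (i in 1:(n - 1L)) {
    if (ch[i] == "P" && ch[i + 1L] == "P") pp <- pp + 1L
  }
  if (n >= 3L) for (i in 1:(n - 2L)) {
    if (ch[i] == "P" && ch[i + 1L] == "P" && ch[i + 2L] == "G") ppg <- ppg + 1L
    if (ch[i] == "P" && ch[i + 1L] == "P" && ch[i + 2L] == "P") ppp <- ppp + 1L
  }
  run <- 0L; best <- 0L
  for (i in seq_len(n)) {
    if (ch[i] == "P") { run <- run + 1L; best <- max(best, run) } else run <- 0L
  }
  list(pp = pp, ppg = ppg, ppp = ppp, max_run = best)
}

# exact two-sided Fisher p for a 2x2 table by enumerating every table with
# the observed margins (probability-ordering convention)
oracle_fisher2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; k <- a + c
  lo <- max(0L, k - (c + d)); hi <- min(m, k)
  xs <- lo:hi
  probs <- dhyper(xs, m, c + d, k)
  p_obs <- dhyper(a, m, c + d, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# per-element 3-bit classification of Venn regions
oracle_venn3 <- function(A, B, C) {
  A <- toupper(trimws(A)); B <- toupper(trimws(B)); C <- toupper(trimws(C))
  u <- unique(c(A, B, C))
  code <- vapply(u, function(e) {
    paste0(as.integer(e %in% A), as.integer(e %in% B), as.integer(e %in% C))
  }, character(1))
  c(A_only = sum(code == "100"), B_only = sum(code == "010"),
    C_only = sum(code == "001"), AB = sum(code == "110"),
    AC = sum(code == "101"), BC = sum(code == "011"),
    ABC = sum(code == "111"))
}

# small default-like study for fast tests
small_study <- function(seed = 1, ...) {
  simulate_study(sim_config(n_genes = 400, seed = seed, ...))
}
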