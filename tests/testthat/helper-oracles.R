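# Independent oracles used to cross-check implementations.

# Brute-force in-silico PCR with zero mismatches: every (i, j) placement of
# the forward primer and of the reverse complement of the reverse primer is
# checked character by character. Written independently of the package's
# scanning code.
oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_site_matches <- function(pattern, template_chars, pos) {
  p <- strsplit(pattern, "")[[1]]
  for (k in seq_along(p)) {
    tb <- template_chars[pos + k - 1]
    if (tb == "N" || !(tb %in% oracle_iupac[[p[k]]])) return(FALSE)
  }
  TRUE
}

oracle_product_lengths <- function(template, fwd, rev, max_len = 2000) {
  tc <- strsplit(toupper(template), "")[[1]]
  rr <- oracle_revcomp(toupper(rev))
  lf <- nchar(fwd); lr <- nchar(rr); n <- length(tc)
  lens <- integer(0)
  for (i in seq_len(max(0, n - lf + 1))) {
    if (!oracle_site_matches(toupper(fwd), tc, i)) next
    for (j in seq_len(max(0, n - lr + 1))) {
      if (!oracle_site_matches(rr, tc, j)) next
      len <- (j + lr - 1) - i + 1
      if (len >= lf + lr && len <= max_len) lens <- c(lens, len)
    }
  }
  sort(lens)
}

# Normal-equations OLS oracle: beta = (X'X)^{-1} X'y.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Numeric F-distribution upper-tail oracle via integration of the density.
oracle_f_pvalue <- function(f, df1, df2) {
  stats::integrate(function(x) stats::df(x, df1, df2), lower = f,
                   upper = Inf)$value
}
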