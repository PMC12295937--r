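# Shared fixtures and independent brute-force oracles. The oracles are
# deliberate re-derivations from first principles (explicit sums, normal
# equations) and never call the package's own implementations.

code5 <- genetic_code(5)
code1 <- genetic_code(1)

random_counts <- function(code, lambda = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::setNames(integer(64), names(code$codon_to_aa))
  x[code$sense_codons] <- stats::rpois(length(code$sense_codons), lambda)
  structure(x, scope = "random", class = "codon_counts")
}

# Wright's ENC transcribed directly: per-family F from explicit p_i sums,
# arithmetic class means, 1/F summation. No imputation (assumes all classes
# observed), which random_counts at lambda >= 2 guarantees.
oracle_enc <- function(counts, code) {
  x <- unclass(counts)[code$sense_codons]
  total <- 0
  for (k in sort(unique(lengths(code$families)))) {
    fams <- code$families[lengths(code$families) == k]
    if (k == 1) { total <- total + length(fams); next }
    Fs <- c()
    for (fam in fams) {
      n <- sum(x[fam])
      if (n < 2) next
      sp2 <- sum((x[fam] / n)^2)
      Fs <- c(Fs, (n * sp2 - 1) / (n - 1))
    }
    total <- total + length(fams) / mean(Fs)
  }
  total
}

oracle_rscu <- function(counts, code) {
  x <- unclass(counts)[code$sense_codons]
  out <- stats::setNames(numeric(length(x)), names(x))
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    tot <- sum(x[fam])
    out[fam] <- if (tot == 0) NA_real_ else length(fam) * x[fam] / tot
  }
  out
}

# Textbook OLS via the normal equations, plus Wherry adjusted R^2.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2))
}

# Pearson r by explicit sums and its two-sided t-test p-value (n - 2 df).
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}
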