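#' Parity-rule-2 coordinates
#'
#' The PR2-bias plot places each gene at x = G3/(G3 + C3), y = A3/(A3 + T3)
#' from its third-codon-position base proportions. Under parity rule 2
#' (no strand-specific mutation or selection pressure at the third
#' position) genes sit at the centre (0.5, 0.5).
#'
#' @param A3,T3,G3,C3 Third-position base proportions (or counts; the
#'   coordinates are scale-invariant). Vectorised.
#' @return List with \code{pr2_x} and \code{pr2_y}, both in [0, 1]; a gene
#'   with a zero denominator gets \code{NA} with a warning.
#' @examples
#' pr2_coordinates(0.25, 0.25, 0.25, 0.25)  # (0.5, 0.5)
#' @export
pr2_coordinates <- function(A3, T3, G3, C3) {
  gx <- G3 + C3
  ay <- A3 + T3
  bad <- gx <= 0 | ay <= 0
  if (any(bad)) {
    warning("PR2 coordinates undefined for ", sum(bad),
            " gene(s) with a zero denominator; returned NA")
  }
  list(pr2_x = ifelse(bad, NA_real_, G3 / gx),
       pr2_y = ifelse(bad, NA_real_, A3 / ay))
}

#' Per-gene codon-usage bias profiles
#'
#' Computes, for each coding sequence, the full vector of statistics the
#' diagnostic plots need: positional GC (GC1/GC2/GC3/GCall/GC12/GC3s),
#' third-position base proportions, ENC, the PR2 coordinates and the
#' deviation of ENC from its GC3s expectation.
#'
#' @param cds_list Named list of \code{coding_sequence} objects.
#' @param code A \code{genetic_code}.
#' @param species Species label attached to every row.
#' @param codonw_compat,synonymous_only,include_start See [enc()] and
#'   [positional_gc()].
#' @return Data frame with one row per gene: gene, species, the composition
#'   fields, \code{ENC}, \code{pr2_x}, \code{pr2_y}, \code{enc_deviation}.
#' @export
gene_bias_profiles <- function(cds_list, code = genetic_code(5),
                               species = NA_character_,
                               codonw_compat = FALSE,
                               synonymous_only = FALSE,
                               include_start = TRUE) {
  rows <- lapply(names(cds_list), function(g) {
    counts <- count_codons(cds_list[[g]], code, include_start = include_start)
    pg <- positional_gc(counts, code, synonymous_only = synonymous_only)
    e <- enc(counts, code, codonw_compat = codonw_compat)
    data.frame(gene = g, species = species, as.data.frame(pg),
               ENC = e$enc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pr2 <- pr2_coordinates(out$A3, out$T3, out$G3, out$C3)
  out$pr2_x <- pr2$pr2_x
  out$pr2_y <- pr2$pr2_y
  out$enc_deviation <- out$ENC - enc_expected(out$GC3s)
  rownames(out) <- NULL
  out
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares with GC3 as predictor and GC12 (the mean of GC1
#' and GC2) as response, the standard orientation of the neutrality plot. A
#' slope near 1 indicates that mutation pressure moves all three codon
#' positions together; a flat or negative slope indicates that selection
#' decouples the first/second positions from the third.
#'
#' @param profiles Data frame with columns \code{GC3} and \code{GC12} (e.g.
#'   from [gene_bias_profiles()]).
#' @return Object of class \code{neutrality_fit}: list with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{adj_r_squared} (Wherry
#'   formula with one predictor; may be negative), \code{p_value}
#'   (two-sided t test on the slope, n - 2 df) and \code{n}.
#' @export
neutrality_regression <- function(profiles) {
  df <- profiles[stats::complete.cases(profiles[c("GC3", "GC12")]), ]
  n <- nrow(df)
  if (n < 3) stop("neutrality regression needs at least 3 genes, got ", n)
  if (stats::var(df$GC3) == 0) {
    stop("neutrality regression undefined: GC3 has zero variance")
  }
  fit <- stats::lm(GC12 ~ GC3, data = df)
  # a perfect fit is a legitimate input here; silence summary.lm's caveat
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::coef(fit)
  p <- if (sm$sigma == 0) 0 else sm$coefficients["GC3", "Pr(>|t|)"]
  structure(
    list(slope = unname(co["GC3"]), intercept = unname(co["(Intercept)"]),
         r_squared = sm$r.squared,
         adj_r_squared = 1 - (1 - sm$r.squared) * (n - 1) / (n - 2),
         p_value = p, n = n),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf("GC12 = %.4f + %.4f * GC3  (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  R^2 = %.4f, adj R^2 = %.4f, p = %.4g\n",
              x$r_squared, x$adj_r_squared, x$p_value))
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Pairwise Pearson correlations among codon-usage parameters
#'
#' Pearson r with two-sided t-test p-values (n - 2 df) for every pair of
#' the chosen variables, with conventional significance stars (* p < 0.05,
#' ** p < 0.01, *** p < 0.001). P-values are not corrected for multiple
#' testing; each star reflects its own test. A zero-variance variable
#' yields \code{NA} for its pairs.
#'
#' @param profiles Data frame of per-gene statistics.
#' @param variables Columns to correlate (default GC1, GC2, GC3, GCall,
#'   ENC).
#' @return Object of class \code{correlation_matrix}: list with matrices
#'   \code{r}, \code{p}, \code{stars}, plus \code{n} and \code{variables}.
#'   \code{as.data.frame()} gives the long format (var1, var2, r, p,
#'   stars) over the lower triangle.
#' @export
correlation_matrix <- function(profiles,
                               variables = c("GC1", "GC2", "GC3", "GCall",
                                             "ENC")) {
  df <- profiles[variables]
  n <- nrow(df)
  if (n < 3) stop("correlation matrix needs at least 3 genes, got ", n)
  k <- length(variables)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- df[[i]]; y <- df[[j]]
      if (stats::var(x) == 0 || stats::var(y) == 0) next
      ct <- stats::cor.test(x, y, method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix(significance_stars(p), k, k,
                  dimnames = dimnames(p))
  diag(stars) <- ""
  structure(list(r = r, p = p, stars = stars, n = n, variables = variables),
            class = "correlation_matrix")
}

#' @export
as.data.frame.correlation_matrix <- function(x, ...) {
  pairs <- which(lower.tri(x$r), arr.ind = TRUE)
  data.frame(
    var1 = x$variables[pairs[, "col"]],
    var2 = x$variables[pairs[, "row"]],
    r = x$r[pairs], p = x$p[pairs], stars = x$stars[pairs],
    stringsAsFactors = FALSE
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  m <- matrix(sprintf("%.2f%s", x$r, x$stars), nrow(x$r),
              dimnames = dimnames(x$r))
  m[is.na(x$r)] <- "NA"
  diag(m) <- "1"
  print(m, quote = FALSE)
  invisible(x)
}
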