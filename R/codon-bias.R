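#' Relative synonymous codon usage
#'
#' For codon c of an amino acid with n synonymous codons, RSCU is the
#' observed count divided by the mean count of its family: \eqn{RSCU_c = n
#' x_c / \sum x}. Values above 1 mark codons used more often than expected
#' under uniform synonymous usage. Families with zero observations get
#' \code{NA} (not 0): their usage is unobserved, not unbiased.
#'
#' @param counts A \code{codon_counts} table.
#' @param code A \code{genetic_code}.
#' @return Data frame of class \code{rscu_table} with one row per sense
#'   codon: \code{codon}, \code{aa}, \code{family_size}, \code{count},
#'   \code{rscu}, \code{third_base}; attribute \code{scope}.
#' @export
rscu <- function(counts, code = genetic_code(5)) {
  x <- unclass(counts)[code$sense_codons]
  fam <- code$family_of
  fam_total <- tapply(x, fam, sum)[fam]
  size <- family_sizes_by_codon(code)
  val <- ifelse(fam_total > 0, size * x / fam_total, NA_real_)
  out <- data.frame(codon = code$sense_codons, aa = unname(fam),
                    family_size = unname(size), count = unname(x),
                    rscu = unname(val),
                    third_base = substring(code$sense_codons, 3, 3),
                    stringsAsFactors = FALSE)
  attr(out, "scope") <- attr(counts, "scope")
  class(out) <- c("rscu_table", "data.frame")
  out
}

#' High-frequency codons shared among and unique to species
#'
#' A codon is high-frequency in a species when its RSCU is strictly greater
#' than 1. Given one RSCU table per species, reports the per-species sets,
#' their intersection, and the codons whose high-frequency status is unique
#' to each single species.
#'
#' @param tables Named list of \code{rscu_table} objects (names = species).
#' @return List with \code{membership} (data frame: codon, third_base, one
#'   logical column per species, \code{n_species}), \code{per_species}
#'   (named list of codon sets), \code{shared} (codons high-frequency in all
#'   species) and \code{unique} (named list: codons high-frequency in that
#'   species only).
#' @export
high_frequency_codons <- function(tables) {
  stopifnot(length(tables) >= 1L)
  if (is.null(names(tables))) names(tables) <- paste0("species", seq_along(tables))
  sets <- lapply(tables, function(tb) tb$codon[!is.na(tb$rscu) & tb$rscu > 1])
  all_codons <- sort(unique(unlist(sets)))
  membership <- data.frame(codon = all_codons,
                           third_base = substring(all_codons, 3, 3),
                           stringsAsFactors = FALSE)
  for (sp in names(sets)) membership[[sp]] <- all_codons %in% sets[[sp]]
  membership$n_species <- rowSums(membership[names(sets)] == TRUE)
  shared <- membership$codon[membership$n_species == length(sets)]
  uniq <- lapply(names(sets), function(sp) {
    membership$codon[membership[[sp]] & membership$n_species == 1L]
  })
  names(uniq) <- names(sets)
  list(membership = membership, per_species = sets, shared = shared,
       unique = uniq)
}

# Wright's codon homozygosity for one family: F = (n * sum(p^2) - 1)/(n - 1),
# undefined for n < 2.
family_homozygosity <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Effective number of codons (Wright's ENC)
#'
#' Wright's estimator generalised to the degeneracy-class structure of the
#' active genetic code. For each synonymous family the codon homozygosity is
#' \eqn{F = (n \sum p_i^2 - 1)/(n - 1)}; families in the same degeneracy
#' class k are averaged to \eqn{\bar F_k}, and \eqn{ENC = \sum_k N_k / \bar
#' F_k} over the classes (with 1-fold classes contributing their family
#' count directly). Under the standard code this is the familiar 2 +
#' 9/F2 + 1/F3 + 5/F4 + 3/F6; under the invertebrate mitochondrial code the
#' classes are 12/F2 + 6/F4 + 1/F6 + 1/F8, so ENC ranges from 20 (one codon
#' per amino acid) to 62 (uniform usage).
#'
#' Families observed fewer than 2 times are excluded from their class mean;
#' a class left with no valid family (or a non-positive mean) has its mean
#' imputed from the nearest available classes (the generalisation of
#' Wright's F3 = (F2 + F4)/2 rule) and is recorded in
#' \code{imputed_classes}. The estimate is reported unclamped; when it
#' exceeds the code's sense-codon count the \code{exceeds_maximum} flag is
#' set.
#'
#' @param counts A \code{codon_counts} table.
#' @param code A \code{genetic_code}. With \code{codonw_compat = TRUE} the
#'   standard-code (table 1) family structure is used regardless of
#'   \code{code}, for comparison with CodonW output.
#' @param codonw_compat Force table-1 degeneracy classes (default FALSE).
#' @return Object of class \code{enc_result}: list with \code{enc},
#'   \code{class_means} (named by class size), \code{n_codons},
#'   \code{imputed_classes}, \code{exceeds_maximum}, \code{table_id}.
#' @export
enc <- function(counts, code = genetic_code(5), codonw_compat = FALSE) {
  if (codonw_compat) code <- genetic_code(1)
  x <- unclass(counts)[code$sense_codons]
  if (sum(x) == 0) stop("ENC undefined: no sense codons observed")
  fam_F <- vapply(code$families, function(cods) family_homozygosity(x[cods]),
                  numeric(1))
  fam_size <- lengths(code$families)
  class_sizes <- sort(unique(fam_size))
  n_fam <- vapply(class_sizes, function(k) sum(fam_size == k), numeric(1))
  fbar <- vapply(class_sizes, function(k) {
    f <- fam_F[fam_size == k & !is.na(fam_F)]
    if (length(f) == 0) NA_real_ else mean(f)
  }, numeric(1))
  names(fbar) <- names(n_fam) <- class_sizes
  # 1-fold families have F = 1 by definition
  fbar[class_sizes == 1L] <- 1
  usable <- !is.na(fbar) & fbar > 0
  if (!any(usable)) stop("ENC undefined: no degeneracy class has a valid mean")
  imputed <- character(0)
  for (i in which(!usable)) {
    lower <- which(usable & seq_along(fbar) < i)
    upper <- which(usable & seq_along(fbar) > i)
    neighbours <- c(if (length(lower)) max(lower), if (length(upper)) min(upper))
    fbar[i] <- mean(fbar[neighbours])
    imputed <- c(imputed, names(fbar)[i])
  }
  value <- sum(n_fam / fbar)
  structure(
    list(enc = value, class_means = fbar, n_codons = sum(x),
         imputed_classes = imputed,
         exceeds_maximum = value > length(code$sense_codons),
         table_id = code$table_id),
    class = "enc_result"
  )
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("ENC = %.4f (n = %d codons, table %d)\n",
              x$enc, x$n_codons, x$table_id))
  if (length(x$imputed_classes) > 0) {
    cat("  imputed class means:", paste(x$imputed_classes, collapse = ", "), "\n")
  }
  if (x$exceeds_maximum) cat("  note: estimate exceeds the code's sense-codon count\n")
  invisible(x)
}

#' Expected ENC under pure GC3s compositional drive
#'
#' The null curve \eqn{ENC = 2 + GC3s + 29/[GC3s^2 + (1 - GC3s)^2]}: the ENC
#' a gene would show if codon usage were determined solely by the GC content
#' at synonymous third positions. Genes falling well below this curve are
#' candidates for translational selection.
#'
#' @param gc3s GC3s value(s) in [0, 1]; vectorised.
#' @return Expected ENC value(s).
#' @examples
#' enc_expected(0.5)  # 60.5
#' @export
enc_expected <- function(gc3s) {
  if (any(gc3s < 0 | gc3s > 1, na.rm = TRUE)) {
    stop("GC3s must lie in [0, 1]")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}
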