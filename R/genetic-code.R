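#' Build a genetic code with its synonymous-family structure
#'
#' Wraps an NCBI translation table (as distributed with Biostrings) and
#' derives the structure every codon-usage statistic needs: the partition of
#' sense codons into synonymous families and the multiset of family sizes
#' (degeneracy classes). Table 5, the invertebrate mitochondrial code, has
#' twelve 2-fold, six 4-fold, one 6-fold (Leu) and one 8-fold (Ser) family
#' and therefore 62 sense codons; the standard code (table 1) has 61 sense
#' codons including two 1-fold families (Met, Trp).
#'
#' @param table_id Integer NCBI translation-table number (e.g. 1 standard,
#'   5 invertebrate mitochondrial).
#' @return An object of class \code{genetic_code}: a list with elements
#'   \code{table_id}, \code{codon_to_aa} (named character vector over the 64
#'   codons, stops as \code{"*"}), \code{start_codons}, \code{stop_codons},
#'   \code{sense_codons}, \code{families} (named list, amino acid ->
#'   synonymous sense codons), \code{family_of} (named character vector,
#'   codon -> amino acid, sense codons only) and \code{class_sizes} (table of
#'   family sizes).
#' @examples
#' code5 <- genetic_code(5)
#' code5$codon_to_aa[c("AGA", "ATA", "TGA")]  # Ser, Met, Trp
#' code5$class_sizes
#' @export
genetic_code <- function(table_id = 5L) {
  table_id <- as.integer(table_id)
  map <- Biostrings::getGeneticCode(as.character(table_id))
  alt_init <- attr(map, "alt_init_codons")
  codon_to_aa <- stats::setNames(as.character(map), names(map))
  stops <- names(codon_to_aa)[codon_to_aa == "*"]
  sense <- names(codon_to_aa)[codon_to_aa != "*"]
  families <- split(sense, codon_to_aa[sense])
  obj <- list(
    table_id = table_id,
    codon_to_aa = codon_to_aa,
    start_codons = sort(unique(c("ATG", alt_init))),
    stop_codons = stops,
    sense_codons = sense,
    families = families,
    family_of = codon_to_aa[sense],
    class_sizes = table(lengths(families))
  )
  class(obj) <- "genetic_code"
  obj
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI translation table", x$table_id, "\n")
  cat("  sense codons:", length(x$sense_codons),
      " stop codons:", paste(x$stop_codons, collapse = ","), "\n")
  sizes <- x$class_sizes
  cat("  degeneracy classes:",
      paste(sprintf("%sx%s-fold", sizes, names(sizes)), collapse = ", "), "\n")
  invisible(x)
}

#' Synonymous-family size of each codon
#'
#' @param code A \code{genetic_code}.
#' @return Named integer vector over sense codons giving the size of the
#'   synonymous family each codon belongs to.
#' @keywords internal
family_sizes_by_codon <- function(code) {
  fam_len <- lengths(code$families)
  stats::setNames(as.integer(fam_len[code$family_of]), names(code$family_of))
}
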