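#' Base composition of a DNA sequence
#'
#' Proportions of A, T, C, G over the counted bases. Ambiguous bases (N and
#' other IUPAC letters) are excluded from the denominator.
#'
#' @param seq DNA string.
#' @return Named list with \code{pA}, \code{pT}, \code{pC}, \code{pG},
#'   \code{at_content}, \code{gc_content}, \code{at_skew}, \code{gc_skew}.
#' @examples
#' base_composition("ACGT")$gc_content  # 0.5
#' @export
base_composition <- function(seq) {
  seq <- toupper(seq)
  counts <- vapply(c("A", "T", "C", "G"), function(b) {
    lengths(regmatches(seq, gregexpr(b, seq, fixed = TRUE)))
  }, numeric(1))
  total <- sum(counts)
  if (total == 0) stop("composition undefined: no unambiguous bases")
  p <- counts / total
  # skews left NA (not an error) for a sequence missing one base class
  list(pA = p[["A"]], pT = p[["T"]], pC = p[["C"]], pG = p[["G"]],
       at_content = p[["A"]] + p[["T"]],
       gc_content = p[["G"]] + p[["C"]],
       at_skew = if (p[["A"]] + p[["T"]] > 0) {
         (p[["A"]] - p[["T"]]) / (p[["A"]] + p[["T"]])
       } else NA_real_,
       gc_skew = if (p[["G"]] + p[["C"]] > 0) {
         (p[["G"]] - p[["C"]]) / (p[["G"]] + p[["C"]])
       } else NA_real_)
}

#' AT and GC skew
#'
#' Strand compositional asymmetry: \eqn{(A-T)/(A+T)} and \eqn{(G-C)/(G+C)},
#' computed from base proportions or counts (the ratio is scale-invariant).
#'
#' @param pA,pT,pC,pG Base proportions (or counts).
#' @return List with \code{at_skew} and \code{gc_skew}, both in [-1, 1].
#' @examples
#' skews(0.287, 0.368, 0.160, 0.186)  # AT skew -0.124, GC skew 0.075
#' @export
skews <- function(pA, pT, pC, pG) {
  if (pA + pT <= 0) stop("AT skew undefined: A + T is zero")
  if (pG + pC <= 0) stop("GC skew undefined: G + C is zero")
  list(at_skew = (pA - pT) / (pA + pT),
       gc_skew = (pG - pC) / (pG + pC))
}

is_gc_base <- function(ch) ch == "G" | ch == "C"

#' Codon-position composition statistics
#'
#' GC content by codon position (GC1, GC2, GC3), overall (GCall), the
#' GC1/GC2 average used on neutrality plots (GC12), GC at synonymously
#' degenerate third positions (GC3s), and the third-position base
#' proportions A3/T3/G3/C3. The terminal stop codon and any codon with an
#' ambiguous base are excluded throughout, so denominators are whole codons.
#'
#' By default A3/T3/G3/C3 are computed over the third positions of all sense
#' codons; \code{synonymous_only = TRUE} restricts them (like GC3s) to codons
#' whose amino acid has at least two synonymous codons, the convention of
#' CodonW's A3s/T3s/G3s/C3s.
#'
#' @param x A \code{coding_sequence}, a plain in-frame CDS string, or a
#'   \code{codon_counts} table.
#' @param code A \code{genetic_code}.
#' @param synonymous_only Restrict A3/T3/G3/C3 to synonymously degenerate
#'   codons (default FALSE).
#' @param include_start,exclude_ambiguous Passed to [count_codons()] when
#'   \code{x} is a sequence.
#' @return Named list with \code{GC1}, \code{GC2}, \code{GC3}, \code{GCall},
#'   \code{GC12}, \code{GC3s}, \code{A3}, \code{T3}, \code{G3}, \code{C3},
#'   \code{n_codons}.
#' @export
positional_gc <- function(x, code = genetic_code(5), synonymous_only = FALSE,
                          include_start = TRUE, exclude_ambiguous = TRUE) {
  counts <- if (inherits(x, "codon_counts")) x else {
    count_codons(x, code, include_start = include_start,
                 exclude_ambiguous = exclude_ambiguous)
  }
  counts <- unclass(counts)[code$sense_codons]
  n <- sum(counts)
  if (n == 0) stop("positional composition undefined: no sense codons")
  pos <- lapply(1:3, function(k) substring(code$sense_codons, k, k))
  gc_at <- vapply(pos, function(b) sum(counts[is_gc_base(b)]) / n, numeric(1))
  syn <- family_sizes_by_codon(code) >= 2L
  n_syn <- sum(counts[syn])
  gc3s <- if (n_syn > 0) {
    sum(counts[syn & is_gc_base(pos[[3]])]) / n_syn
  } else NA_real_
  third_scope <- if (synonymous_only) syn else rep(TRUE, length(counts))
  n3 <- sum(counts[third_scope])
  p3 <- vapply(c("A", "T", "G", "C"), function(b) {
    sum(counts[third_scope & pos[[3]] == b]) / n3
  }, numeric(1))
  list(GC1 = gc_at[1], GC2 = gc_at[2], GC3 = gc_at[3],
       GCall = mean(gc_at), GC12 = (gc_at[1] + gc_at[2]) / 2,
       GC3s = gc3s,
       A3 = p3[["A"]], T3 = p3[["T"]], G3 = p3[["G"]], C3 = p3[["C"]],
       n_codons = n)
}

#' Composition table for a set of genes plus the whole genome
#'
#' One row per coding sequence (positional statistics) and, when a genome is
#' supplied, one genome row carrying the whole-molecule base composition and
#' skews as deposited (heavy strand).
#'
#' @param cds_list Named list of \code{coding_sequence} objects.
#' @param code A \code{genetic_code}.
#' @param genome Optional \code{annotated_genome} for the genome row.
#' @param ... Passed to [positional_gc()].
#' @return A data frame, one row per gene (+ optional "genome" row).
#' @export
composition_table <- function(cds_list, code = genetic_code(5), genome = NULL,
                              ...) {
  rows <- lapply(names(cds_list), function(g) {
    cds <- cds_list[[g]]
    comp <- base_composition(cds$nt)
    pg <- positional_gc(cds, code, ...)
    data.frame(gene = g, strand = cds$strand,
               length_nt = nchar(cds$nt), as.data.frame(comp),
               as.data.frame(pg), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(genome)) {
    comp <- base_composition(genome$sequence)
    grow <- data.frame(gene = "genome", strand = "+",
                       length_nt = genome$length, as.data.frame(comp),
                       stringsAsFactors = FALSE)
    for (col in setdiff(names(out), names(grow))) grow[[col]] <- NA_real_
    out <- rbind(out, grow[names(out)])
  }
  rownames(out) <- NULL
  out
}
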