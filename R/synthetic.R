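#' Specification for a synthetic mitogenome-like CDS set
#'
#' Describes a set of in-frame coding sequences drawn under a
#' mutation-selection model with known parameters, sized to mimic a
#' metazoan mitochondrial genome: 13 protein-coding genes under the
#' invertebrate mitochondrial code, a few genes on the light strand, and a
#' few genes whose TAA stop is truncated in the annotation (completed in
#' vivo by polyadenylation).
#'
#' The sampling model is intentionally minimal so closed-form expectations
#' exist: codons are drawn i.i.d. with mutational weight
#' \eqn{g^{n_{GC}} (1-g)^{n_{AT}}} over sense codons (g = probability a
#' mutationally free base is G or C), and selection multiplies the weight
#' of each family's preferred codon by \eqn{1 + s}.
#'
#' @param n_genes Number of genes (default 13).
#' @param codons_per_gene Integer range (length-2) of codon counts drawn per
#'   gene, default 50--600, mimicking the atp8-to-nad5 length spread.
#' @param code A \code{genetic_code} (default table 5).
#' @param gc_pressure Either a single g in (0, 1) or one per gene.
#' @param selection_strength s >= 0; weight multiplier 1 + s on preferred
#'   codons.
#' @param preferred_codons One codon per synonymous family; defaults to the
#'   T-ending codon of each family when present, else the A-ending one
#'   (mirroring the U/A-ending preference typical of AT-rich mitogenomes).
#' @param light_strand_genes Indices of genes annotated on the '-' strand
#'   (default 4 genes: 3, 5, 8, 12).
#' @param incomplete_stop_genes Indices of genes emitted with truncated
#'   TA/T stops (default genes 2, 7 and 10; even indices truncate to "TA",
#'   odd to "T").
#' @param seed Integer master seed; all draws derive from it through a
#'   per-gene counter so individual genes are reproducible in isolation.
#' @return Object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_genes = 13L,
                           codons_per_gene = c(50L, 600L),
                           code = genetic_code(5),
                           gc_pressure = 0.35,
                           selection_strength = 0,
                           preferred_codons = default_preferred_codons(code),
                           light_strand_genes = c(3L, 5L, 8L, 12L),
                           incomplete_stop_genes = c(2L, 7L, 10L),
                           seed = 1L) {
  stopifnot(n_genes >= 1L, length(codons_per_gene) == 2L,
            all(gc_pressure > 0 & gc_pressure < 1),
            length(gc_pressure) %in% c(1L, n_genes),
            selection_strength >= 0)
  validate_preferred(preferred_codons, code)
  structure(
    list(n_genes = as.integer(n_genes),
         codons_per_gene = as.integer(codons_per_gene),
         code = code,
         gc_pressure = rep_len(gc_pressure, n_genes),
         selection_strength = selection_strength,
         preferred_codons = preferred_codons,
         light_strand_genes = intersect(as.integer(light_strand_genes),
                                        seq_len(n_genes)),
         incomplete_stop_genes = intersect(as.integer(incomplete_stop_genes),
                                           seq_len(n_genes)),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Default preferred-codon set: one codon per family, T-ending if available
#' else A-ending, else the family's first codon alphabetically.
#' @param code A \code{genetic_code}.
#' @return Named character vector, amino acid -> codon.
#' @export
default_preferred_codons <- function(code) {
  vapply(code$families, function(cods) {
    third <- substring(cods, 3, 3)
    if (any(third == "T")) return(sort(cods[third == "T"])[1])
    if (any(third == "A")) return(sort(cods[third == "A"])[1])
    sort(cods)[1]
  }, character(1))
}

validate_preferred <- function(preferred, code) {
  if (!setequal(names(preferred), names(code$families))) {
    stop("preferred_codons must name exactly one codon per amino acid family")
  }
  ok <- vapply(names(preferred),
               function(a) preferred[[a]] %in% code$families[[a]],
               logical(1))
  if (!all(ok)) {
    stop("preferred codon not in its family for: ",
         paste(names(preferred)[!ok], collapse = ", "))
  }
  invisible(TRUE)
}

#' Sense-codon sampling weights of the mutation-selection model
#'
#' @param code A \code{genetic_code}.
#' @param g GC mutation pressure in (0, 1).
#' @param s Selection strength (>= 0).
#' @param preferred_codons One codon per family (see [synthetic_spec()]).
#' @return Named probability vector over the code's sense codons.
#' @export
codon_sampling_weights <- function(code, g, s = 0,
                                   preferred_codons =
                                     default_preferred_codons(code)) {
  codons <- code$sense_codons
  n_gc <- vapply(strsplit(codons, ""), function(b) sum(b %in% c("G", "C")),
                 numeric(1))
  w <- g^n_gc * (1 - g)^(3 - n_gc)
  names(w) <- codons
  if (s > 0) w[preferred_codons] <- w[preferred_codons] * (1 + s)
  w / sum(w)
}

#' Closed-form expected composition under the sampling model
#'
#' Enumerates the sense codons to give the exact expected GC3, GC12 and
#' GC content of a gene drawn with the given parameters — the oracle used
#' in parameter-recovery checks.
#'
#' @inheritParams codon_sampling_weights
#' @return List with \code{GC1}, \code{GC2}, \code{GC3}, \code{GC12},
#'   \code{GCall}.
#' @export
expected_positional_gc <- function(code, g, s = 0,
                                   preferred_codons =
                                     default_preferred_codons(code)) {
  w <- codon_sampling_weights(code, g, s, preferred_codons)
  pos_gc <- vapply(1:3, function(k) {
    sum(w[is_gc_base(substring(names(w), k, k))])
  }, numeric(1))
  list(GC1 = pos_gc[1], GC2 = pos_gc[2], GC3 = pos_gc[3],
       GC12 = (pos_gc[1] + pos_gc[2]) / 2, GCall = mean(pos_gc))
}

# Per-gene RNG scope: deterministic function of (seed, counter), independent
# of draw order across genes. Restores the caller's RNG state on exit.
with_gene_seed <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.numeric(seed) * 1000003 + counter * 7919) %% 2147483647)
  expr
}

#' Draw one synthetic coding sequence
#'
#' Samples \code{length} codons i.i.d. from the mutation-selection weight
#' distribution, places a start codon drawn from the code's start set
#' first, and appends a TAA stop (truncated to "TA" or "T" when asked,
#' emulating stops completed by 3' polyadenylation; the returned object has
#' the stop completed and flagged).
#'
#' @param spec A \code{synthetic_spec}.
#' @param gene_index Which gene (1..n_genes); selects the per-gene seed, g,
#'   strand and stop treatment.
#' @param length Codon count; if missing, drawn uniformly from
#'   \code{spec$codons_per_gene}.
#' @return A \code{coding_sequence} (sense strand).
#' @export
sample_gene <- function(spec, gene_index = 1L, length = NULL) {
  g <- spec$gc_pressure[gene_index]
  w <- codon_sampling_weights(spec$code, g, spec$selection_strength,
                              spec$preferred_codons)
  with_gene_seed(spec$seed, gene_index, {
    if (is.null(length)) {
      lo <- spec$codons_per_gene[1]
      hi <- spec$codons_per_gene[2]
      length <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    }
    body <- sample(names(w), size = length - 1L, replace = TRUE, prob = w)
    start <- sample(intersect(spec$code$start_codons,
                              spec$code$sense_codons), 1L)
    nt <- paste(c(start, body), collapse = "")
    truncated <- gene_index %in% spec$incomplete_stop_genes
    stop_part <- if (truncated) {
      if (gene_index %% 2L == 0L) "TA" else "T"
    } else "TAA"
    strand <- if (gene_index %in% spec$light_strand_genes) "-" else "+"
    make_coding_sequence(paste0(nt, stop_part),
                         gene = mito_gene_names(spec$n_genes)[gene_index],
                         strand = strand, code = spec$code)
  })
}

mito_gene_names <- function(n) {
  base <- c("cox1", "cox2", "cox3", "cob", "nad1", "nad2", "nad3", "nad4",
            "nad4l", "nad5", "nad6", "atp6", "atp8")
  if (n <= length(base)) base[seq_len(n)] else {
    c(base, paste0("orf", seq_len(n - length(base))))
  }
}

#' Generate a full synthetic CDS set
#'
#' @param spec A \code{synthetic_spec}.
#' @return Named list of \code{coding_sequence} objects (sense strand) with
#'   attribute \code{truth}: a data frame of the true per-gene parameters
#'   (g, s, strand, truncated stop, length) for recovery tests.
#' @export
sample_genome_cds <- function(spec) {
  cds <- lapply(seq_len(spec$n_genes), function(i) sample_gene(spec, i))
  names(cds) <- vapply(cds, `[[`, "", "gene")
  truth <- data.frame(
    gene = names(cds),
    g = spec$gc_pressure,
    s = spec$selection_strength,
    strand = vapply(cds, `[[`, "", "strand"),
    stop_completed = vapply(cds, `[[`, TRUE, "stop_completed"),
    n_codons = vapply(cds, function(x) nchar(x$nt) %/% 3L, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  attr(cds, "truth") <- truth
  cds
}

#' Write a synthetic annotated genome as a GenBank flat file
#'
#' Assembles the sampled genes (light-strand genes stored
#' reverse-complemented, truncated stops emitted truncated), interleaves
#' placeholder tRNA and rRNA features in short spacers, and writes a
#' circular GenBank record that [read_genbank()] parses back. Output is
#' byte-stable for a fixed seed.
#'
#' @param spec A \code{synthetic_spec}.
#' @param path Output path (.gb). The true-parameter table is written
#'   alongside as \code{<path>.truth.tsv}.
#' @return Invisibly, \code{path}.
#' @export
emit_fixture_genome <- function(spec, path) {
  cds <- sample_genome_cds(spec)
  truth <- attr(cds, "truth")
  spacer <- "TATTAATTAATTAATTATTA"  # AT-rich intergenic filler
  trna_names <- paste0("trn", LETTERS[1:22])
  seq_parts <- character(0)
  feats <- list()
  pos <- 1L
  add_feat <- function(gene, type, start, end, strand) {
    loc <- if (strand == "+") sprintf("%d..%d", start, end) else
      sprintf("complement(%d..%d)", start, end)
    feats[[length(feats) + 1L]] <<- list(gene = gene, type = type, loc = loc)
  }
  trna_i <- 1L
  for (i in seq_len(spec$n_genes)) {
    gene <- cds[[i]]
    nt <- gene$nt
    if (gene$stop_completed) {  # emit truncated, as annotated in vivo
      pad <- if (i %% 2L == 0L) 1L else 2L
      nt <- substring(nt, 1L, nchar(nt) - pad)
    }
    emitted <- if (gene$strand == "-") dna_revcomp(nt) else nt
    add_feat(gene$gene, "CDS", pos, pos + nchar(emitted) - 1L, gene$strand)
    seq_parts <- c(seq_parts, emitted)
    pos <- pos + nchar(emitted)
    # placeholder tRNA in the spacer after each gene
    if (trna_i <= length(trna_names)) {
      add_feat(trna_names[trna_i], "tRNA", pos, pos + nchar(spacer) - 1L, "+")
      trna_i <- trna_i + 1L
    }
    seq_parts <- c(seq_parts, spacer)
    pos <- pos + nchar(spacer)
  }
  for (r in c("rrnS", "rrnL")) {
    add_feat(r, "rRNA", pos, pos + nchar(spacer) - 1L, "+")
    seq_parts <- c(seq_parts, spacer)
    pos <- pos + nchar(spacer)
  }
  genome_seq <- paste(seq_parts, collapse = "")
  writeLines(format_genbank(genome_seq, feats, spec), path)
  utils::write.table(truth, paste0(path, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_genbank <- function(genome_seq, feats, spec) {
  n <- nchar(genome_seq)
  lines <- c(
    sprintf("LOCUS       SYNMITO%02d %14d bp    DNA     circular INV 01-JAN-2000",
            spec$seed %% 100L, n),
    "DEFINITION  synthetic mitochondrial genome (simulated; not a real organism).",
    sprintf("ACCESSION   SYN%06d", spec$seed %% 1000000L),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    sprintf("                     /organism=\"synthetic construct\""),
    sprintf("                     /transl_table=%d", spec$code$table_id)
  )
  for (f in feats) {
    lines <- c(lines,
               sprintf("     %-16s%s", f$type, f$loc),
               sprintf("                     /gene=\"%s\"", f$gene))
    if (f$type == "CDS") {
      lines <- c(lines,
                 sprintf("                     /transl_table=%d",
                         spec$code$table_id))
    }
  }
  lines <- c(lines, "ORIGIN")
  starts <- seq(1L, n, by = 60L)
  for (st in starts) {
    chunk <- substring(genome_seq, st, min(st + 59L, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", st,
                              paste(tolower(groups), collapse = " ")))
  }
  c(lines, "//")
}
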