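#' @importFrom stats setNames
NULL

dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

split_codons <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return(character(0))
  substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Read an annotated genome from a GenBank flat file
#'
#' Parses the LOCUS line, the FEATURES table (CDS, tRNA and rRNA features
#' with their gene names, coordinates and strand) and the ORIGIN sequence
#' block of a GenBank flat file. Locations of the forms \code{a..b},
#' \code{complement(a..b)}, \code{join(a..b,c..d)} and
#' \code{complement(join(...))} are supported, so circular features spanning
#' the origin round-trip correctly; partial-location markers (\code{<},
#' \code{>}) are tolerated and stripped. Coordinates are kept in the GenBank
#' convention, 1-based and inclusive.
#'
#' @param path Path to a GenBank flat file (.gb/.gbk).
#' @return An object of class \code{annotated_genome}: a list with
#'   \code{accession}, \code{sequence} (uppercase character string),
#'   \code{length}, \code{circular} flag and \code{features}, a data frame
#'   with columns \code{gene}, \code{type}, \code{start}, \code{end},
#'   \code{strand} and \code{location} (the raw location string).
#' @seealso [extract_cds()] to obtain sense-strand coding sequences.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file (no LOCUS line): ", path)
  accession <- sub("^LOCUS\\s+(\\S+).*", "\\1", locus[1])
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line) > 0L) {
    acc <- sub("^ACCESSION\\s+(\\S+).*", "\\1", acc_line[1])
    if (nzchar(acc) && acc != "ACCESSION") accession <- acc
  }
  circular <- grepl("circular", locus[1], ignore.case = TRUE)

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L) stop("GenBank record has no ORIGIN block: ", path)
  seq_lines <- lines[(origin_at[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("ORIGIN block contains no sequence: ", path)

  feat_at <- grep("^FEATURES", lines)
  features <- empty_features()
  if (length(feat_at) > 0L) {
    block <- lines[(feat_at[1] + 1L):(origin_at[1] - 1L)]
    features <- parse_feature_block(block)
  }
  bad <- features$end > nchar(sequence) | features$start < 1L
  if (any(bad)) {
    stop("feature coordinates outside [1, genome length] for: ",
         paste(features$gene[bad], collapse = ", "))
  }
  structure(
    list(accession = accession, sequence = sequence,
         length = nchar(sequence), circular = circular, features = features),
    class = "annotated_genome"
  )
}

empty_features <- function() {
  data.frame(gene = character(0), type = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             location = character(0), stringsAsFactors = FALSE)
}

parse_feature_block <- function(block) {
  # feature keys start at column 6; qualifiers/continuations at column 22
  starts <- grep("^ {5}\\S", block)
  keep_types <- c("CDS", "tRNA", "rRNA")
  out <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(block)
    chunk <- block[from:to]
    type <- sub("^ {5}(\\S+).*", "\\1", chunk[1])
    if (!type %in% keep_types) next
    # location may continue over lines until the first qualifier
    qual_at <- grep("^\\s+/", chunk)
    loc_end <- if (length(qual_at) > 0L) qual_at[1] - 1L else length(chunk)
    loc <- paste(trimws(sub("^ {5}\\S+\\s*", "", chunk[1])),
                 paste(trimws(chunk[seq_len(loc_end)[-1]]), collapse = ""),
                 sep = "")
    loc <- gsub("\\s", "", loc)
    parsed <- tryCatch(parse_location(loc),
                       error = function(e) stop("unparseable location for ",
                                                type, " feature: ", loc))
    gene <- NA_character_
    gline <- grep('^\\s+/(gene|product)="', chunk, value = TRUE)
    if (length(gline) > 0L) gene <- sub('.*="([^"]*)".*', "\\1", gline[1])
    out[[length(out) + 1L]] <- data.frame(
      gene = gene, type = type,
      start = min(parsed$parts$start), end = max(parsed$parts$end),
      strand = parsed$strand, location = loc, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty_features())
  do.call(rbind, out)
}

# Parse a GenBank location string into ordered (start, end) parts and strand.
parse_location <- function(loc) {
  strand <- "+"
  x <- loc
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x)) x <- sub("^join\\((.*)\\)$", "\\1", x)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", parts))
  single <- regmatches(parts, regexec("^<?([0-9]+)>?$", parts))
  st <- en <- integer(length(parts))
  for (i in seq_along(parts)) {
    if (length(m[[i]]) == 3L) {
      st[i] <- as.integer(m[[i]][2]); en[i] <- as.integer(m[[i]][3])
    } else if (length(single[[i]]) == 2L) {
      st[i] <- en[i] <- as.integer(single[[i]][2])
    } else {
      stop("bad location part: ", parts[i])
    }
  }
  if (any(en < st)) stop("descending location part in: ", loc)
  list(strand = strand, parts = data.frame(start = st, end = en))
}

#' Extract a sense-strand coding sequence from an annotated genome
#'
#' Pulls the nucleotides covered by one CDS feature, reverse-complements
#' light-strand (\code{-}) features to sense orientation, and completes
#' incomplete stop codons: when the length is not a multiple of 3 and the
#' trailing partial codon is \code{"T"} or \code{"TA"} (a prefix of TAA, the
#' stop completed in vivo by 3' polyadenylation of the mRNA), it is padded
#' with A residues and flagged. Any other frame remainder is an error, as is
#' an internal stop codon under the active genetic code.
#'
#' @param genome An \code{annotated_genome} from [read_genbank()].
#' @param feature One row of \code{genome$features} (or its row index) with
#'   \code{type == "CDS"}.
#' @param code A \code{genetic_code}.
#' @return An object of class \code{coding_sequence}: list with \code{gene},
#'   \code{nt} (sense-strand DNA), \code{strand}, \code{stop_completed},
#'   \code{start_codon}, \code{stop_codon}.
#' @export
extract_cds <- function(genome, feature, code = genetic_code(5)) {
  if (is.numeric(feature)) feature <- genome$features[feature, , drop = FALSE]
  if (is.data.frame(feature)) feature <- as.list(feature[1, ])
  if (!identical(feature$type, "CDS")) {
    stop("extract_cds requires a CDS feature, got: ", feature$type)
  }
  parsed <- parse_location(feature$location)
  nt <- paste(substring(genome$sequence, parsed$parts$start, parsed$parts$end),
              collapse = "")
  if (parsed$strand == "-") nt <- dna_revcomp(nt)
  make_coding_sequence(nt, gene = feature$gene, strand = parsed$strand,
                       code = code)
}

#' Construct and validate a coding sequence
#'
#' Applies the incomplete-stop completion rule and the frame/internal-stop
#' checks directly to a sense-strand nucleotide string. Used by
#' [extract_cds()] and by the FASTA path.
#'
#' @param nt Sense-strand DNA string.
#' @param gene Gene name for error messages and provenance.
#' @param strand Source strand label ("+" or "-").
#' @param code A \code{genetic_code}.
#' @return A \code{coding_sequence}.
#' @export
make_coding_sequence <- function(nt, gene = NA_character_, strand = "+",
                                 code = genetic_code(5)) {
  nt <- toupper(nt)
  rem <- nchar(nt) %% 3L
  stop_completed <- FALSE
  if (rem != 0L) {
    tail_frag <- substring(nt, nchar(nt) - rem + 1L, nchar(nt))
    if (!tail_frag %in% c("T", "TA")) {
      stop("gene ", gene, ": length remainder ", rem,
           " not completable to a TAA stop (trailing '", tail_frag, "')")
    }
    nt <- paste0(nt, strrep("A", 3L - rem))
    stop_completed <- TRUE
  }
  codons <- split_codons(nt)
  if (length(codons) < 2L) stop("gene ", gene, ": fewer than two codons")
  aa <- code$codon_to_aa[codons]
  aa[is.na(aa)] <- "X"  # ambiguous codons translate to X, never to stop
  if (aa[length(aa)] != "*") {
    stop("gene ", gene, ": no terminal stop codon (ends ",
         codons[length(codons)], ")")
  }
  internal <- which(aa[-length(aa)] == "*")
  if (length(internal) > 0L) {
    stop("gene ", gene, ": internal stop codon at codon ", internal[1])
  }
  structure(
    list(gene = gene, nt = nt, strand = strand,
         stop_completed = stop_completed,
         start_codon = codons[1], stop_codon = codons[length(codons)]),
    class = "coding_sequence"
  )
}

#' Extract all coding sequences of a genome
#'
#' @param genome An \code{annotated_genome}.
#' @param code A \code{genetic_code}.
#' @return Named list of \code{coding_sequence} objects, one per CDS feature,
#'   in annotation order.
#' @export
extract_all_cds <- function(genome, code = genetic_code(5)) {
  idx <- which(genome$features$type == "CDS")
  out <- lapply(idx, function(i) extract_cds(genome, i, code))
  stats::setNames(out, genome$features$gene[idx])
}

#' Count codon usage of a coding sequence
#'
#' Tabulates sense-codon counts. The terminal stop codon never enters the
#' table; codons containing ambiguous bases are dropped when
#' \code{exclude_ambiguous} (the default); the start codon is counted as the
#' sense codon it encodes (TTG as Leu, ATT as Ile) unless
#' \code{include_start = FALSE}.
#'
#' @param cds A \code{coding_sequence}, or a plain in-frame DNA string whose
#'   last codon is the stop.
#' @param code A \code{genetic_code}.
#' @param include_start Count the initiation codon (default TRUE).
#' @param exclude_ambiguous Drop codons containing non-ACGT bases (default
#'   TRUE).
#' @return Object of class \code{codon_counts}: named integer vector over the
#'   64 codons (zeros included), with attribute \code{scope}.
#' @export
count_codons <- function(cds, code = genetic_code(5), include_start = TRUE,
                         exclude_ambiguous = TRUE) {
  if (is.character(cds)) cds <- make_coding_sequence(cds, code = code)
  codons <- split_codons(cds$nt)
  codons <- codons[-length(codons)]            # terminal stop excluded
  if (!include_start) codons <- codons[-1L]
  if (exclude_ambiguous) codons <- codons[grepl("^[ACGT]{3}$", codons)]
  codons <- codons[!codons %in% code$stop_codons]
  counts <- setNames(integer(64), names(code$codon_to_aa))
  tab <- table(codons)
  counts[names(tab)] <- as.integer(tab)
  structure(counts, scope = cds$gene, class = "codon_counts")
}

#' Sum codon-count tables
#'
#' @param counts_list List of \code{codon_counts} (e.g. one per gene).
#' @param scope Label for the pooled table.
#' @return A pooled \code{codon_counts}.
#' @export
pool_codon_counts <- function(counts_list, scope = "concatenated") {
  total <- Reduce(`+`, lapply(counts_list, unclass))
  structure(total, scope = scope, class = "codon_counts")
}

#' Read coding sequences from a multi-FASTA file
#'
#' Headers are taken as gene names; each record must be an in-frame
#' sense-strand CDS ending in a (possibly incomplete) stop codon.
#'
#' @param path FASTA file path.
#' @param code A \code{genetic_code}.
#' @return Named list of \code{coding_sequence} objects.
#' @export
read_cds_fasta <- function(path, code = genetic_code(5)) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    make_coding_sequence(as.character(set[[i]]), gene = names(set)[i],
                         code = code)
  })
  stats::setNames(out, names(set))
}

#' Write coding sequences to a multi-FASTA file
#'
#' @param cds_list Named list of \code{coding_sequence} objects.
#' @param path Output path.
#' @param width Line width for wrapped sequence (default 60).
#' @return Invisibly, \code{path}.
#' @export
write_cds_fasta <- function(cds_list, path, width = 60L) {
  seqs <- Biostrings::DNAStringSet(vapply(cds_list, `[[`, "", "nt"))
  names(seqs) <- vapply(cds_list, `[[`, "", "gene")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
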