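#' Run the full codon-usage-bias pipeline
#'
#' Orchestrates extraction, composition, RSCU, ENC, PR2 and neutrality
#' analyses for one or more annotated genomes and writes all tabular
#' outputs (TSV, UTF-8, '.' decimal), the diagnostic figures and a
#' machine-readable run manifest.
#'
#' @param inputs Named character vector or list of input files (GenBank
#'   .gb/.gbk or CDS FASTA .fa/.fasta); names become species labels
#'   (defaults to file base names).
#' @param out_dir Output directory, created if needed.
#' @param code_id NCBI translation-table number (default 5).
#' @param codonw_compat,synonymous_only,include_start Analysis flags, see
#'   [enc()] and [positional_gc()].
#' @param figures Render figures (default TRUE).
#' @param figure_formats Formats for [render_figures()].
#' @return Invisibly, a list with \code{profiles}, \code{rscu_tables},
#'   \code{regressions}, \code{correlations}, \code{hf_codons},
#'   \code{composition}, \code{manifest}.
#' @export
run_pipeline <- function(inputs, out_dir, code_id = 5L,
                         codonw_compat = FALSE, synonymous_only = FALSE,
                         include_start = TRUE, figures = TRUE,
                         figure_formats = c("png", "svg")) {
  inputs <- unlist(inputs)
  if (length(inputs) == 0L) stop("no input files given")
  missing_files <- inputs[!file.exists(inputs)]
  if (length(missing_files) > 0L) {
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    names(inputs) <- tools::file_path_sans_ext(basename(inputs))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  code <- genetic_code(code_id)

  per_species <- lapply(names(inputs), function(sp) {
    path <- inputs[[sp]]
    is_gb <- grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE)
    genome <- if (is_gb) read_genbank(path) else NULL
    cds <- if (is_gb) extract_all_cds(genome, code) else
      read_cds_fasta(path, code)
    counts <- lapply(cds, count_codons, code = code,
                     include_start = include_start)
    pooled <- pool_codon_counts(counts, scope = sp)
    list(species = sp, genome = genome, cds = cds,
         composition = composition_table(cds, code, genome,
                                         synonymous_only = synonymous_only),
         rscu = rscu(pooled, code),
         profiles = gene_bias_profiles(cds, code, species = sp,
                                       codonw_compat = codonw_compat,
                                       synonymous_only = synonymous_only,
                                       include_start = include_start))
  })
  names(per_species) <- names(inputs)

  profiles <- do.call(rbind, lapply(per_species, `[[`, "profiles"))
  rownames(profiles) <- NULL
  rscu_tables <- lapply(per_species, `[[`, "rscu")
  hf <- high_frequency_codons(rscu_tables)
  regressions <- lapply(per_species, function(x) {
    neutrality_regression(x$profiles)
  })
  correlations <- lapply(per_species, function(x) {
    correlation_matrix(x$profiles)
  })
  composition <- do.call(rbind, lapply(per_species, function(x) {
    cbind(species = x$species, x$composition)
  }))
  rownames(composition) <- NULL

  write_tsv <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    file
  }
  reg_df <- do.call(rbind, lapply(names(regressions), function(sp) {
    data.frame(species = sp, as.data.frame(unclass(regressions[[sp]])),
               stringsAsFactors = FALSE)
  }))
  cor_df <- do.call(rbind, lapply(names(correlations), function(sp) {
    cbind(species = sp, as.data.frame(correlations[[sp]]))
  }))
  rscu_wide <- Reduce(function(a, b) merge(a, b, by = c("codon", "aa"),
                                           all = TRUE, sort = TRUE),
                      lapply(names(rscu_tables), function(sp) {
                        tb <- rscu_tables[[sp]][c("codon", "aa", "rscu")]
                        names(tb)[3] <- sp
                        tb
                      }))
  hf_df <- hf$membership
  outputs <- c(
    write_tsv(composition, "composition.tsv"),
    write_tsv(profiles, "gene_profiles.tsv"),
    write_tsv(rscu_wide, "rscu_matrix.tsv"),
    write_tsv(hf_df, "high_frequency_codons.tsv"),
    write_tsv(reg_df, "neutrality_regressions.tsv"),
    write_tsv(cor_df, "correlations.tsv")
  )
  if (figures) {
    figs <- render_figures(profiles, rscu_tables, regressions,
                           out_dir = out_dir, formats = figure_formats)
    outputs <- c(outputs, basename(figs))
  }
  manifest <- list(
    tool = "mitocub",
    version = as.character(utils::packageVersion("mitocub")),
    inputs = lapply(names(inputs), function(sp) {
      list(species = sp, path = unname(inputs[[sp]]),
           md5 = unname(tools::md5sum(inputs[[sp]])))
    }),
    genetic_code = code_id,
    flags = list(codonw_compat = codonw_compat,
                 synonymous_only = synonymous_only,
                 include_start = include_start),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(profiles = profiles, rscu_tables = rscu_tables,
                 regressions = regressions, correlations = correlations,
                 hf_codons = hf, composition = composition,
                 manifest = manifest))
}
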