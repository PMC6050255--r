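# Plain-text readers/writers for the pipeline's TSV/CSV/BED/FASTA dialects.

write_tsv <- function(x, path, row_names = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = row_names,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

# Matrix TSV: first column = feature ids, header = sample ids.
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read and validate a sample sheet CSV
#'
#' Expects columns sample_id, lsi_score, age, batch. Non-numeric score or
#' age values raise a parse error naming the offending line.
#'
#' @param path CSV path
#' @return validated sample sheet data.frame
#' @export
read_sample_sheet <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "lsi_score", "age", "batch")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_pipeline("sample sheet %s lacks column(s): %s", path,
                  paste(miss, collapse = ", "))
  }
  for (col in c("lsi_score", "age")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop_pipeline("sample sheet %s: non-numeric %s at line %d ('%s')",
                    path, col, bad + 1L, df[[col]][bad])
    }
    df[[col]] <- v
  }
  if (anyDuplicated(df$sample_id)) {
    stop_pipeline("sample sheet %s: duplicated sample id(s)", path)
  }
  df
}

# BED (0-based half-open) writer/reader for the SNP table.
write_snp_bed <- function(snps, path) {
  bed <- data.frame(snps$chrom, snps$pos - 1L, snps$pos,
                    snps$snp_id %||% sprintf("rs%06d", seq_len(nrow(snps))))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

read_snp_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1]], pos = bed[[3]],
             snp_id = if (ncol(bed) >= 4) bed[[4]] else NA_character_,
             stringsAsFactors = FALSE)
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as.character(seqs)) |>
                                (\(x) { names(x) <- names(seqs); x })(),
                              path)
  invisible(path)
}

#' Write a simulated study to disk
#'
#' Emits the TSV/CSV/BED/FASTA file set a real study would provide: beta
#' and detection matrices, probe manifest, sample sheet, gene and isoform
#' counts, isoform map, gene list, SNP BED, flank FASTA and the truth
#' tables.
#'
#' @param study list from [simulate_study()]
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of written paths
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  paths <- c(
    beta = write_matrix_tsv(study$beta, p("beta.tsv"), "probe_id"),
    detection = write_matrix_tsv(study$detection_p, p("detection_p.tsv"),
                                 "probe_id"),
    manifest = write_tsv(study$probes, p("manifest.tsv")),
    samples = {
      write.table(study$samples, p("samples.csv"), sep = ",", quote = FALSE,
                  row.names = FALSE)
      p("samples.csv")
    },
    gene_counts = write_matrix_tsv(study$expression$gene_counts,
                                   p("gene_counts.tsv"), "gene_id"),
    isoform_counts = write_matrix_tsv(study$expression$isoform_counts,
                                      p("isoform_counts.tsv"), "isoform_id"),
    isoform_map = write_tsv(study$expression$isoform_map,
                            p("isoform_map.tsv")),
    gene_list = {
      writeLines(study$gene_list, p("gene_list.txt"))
      p("gene_list.txt")
    },
    snps = write_snp_bed(study$snps, p("snps.bed")),
    flanks = {
      seqs <- setNames(study$probes$flank, study$probes$probe_id)
      write_fasta(seqs, p("flanks.fasta"))
      p("flanks.fasta")
    },
    truth_meth = write_tsv(study$truth, p("truth_methylation.tsv")),
    truth_expr = write_tsv(study$expression$truth, p("truth_expression.tsv")),
    genes = write_tsv(study$genome$genes, p("genes.tsv")),
    islands = write_tsv(study$genome$islands, p("islands.tsv")),
    chromosomes = write_tsv(study$genome$chromosomes, p("chromosomes.tsv")))
  invisible(paths)
}
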