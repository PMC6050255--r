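# Shared fixtures, built in code at test time.

tiny_study <- function(seed = 1, ...) {
  simulate_study(n_chromosomes = 2, genes_per_chromosome = 20,
                 n_probes = 400, n_samples = 12, seed = seed, ...)
}

# A minimal hand-built probe manifest.
make_manifest <- function(n, chrom = "chr1", pos = seq_len(n) * 1000L,
                          structures = "Body", island = "OpenSea",
                          flank = NULL) {
  if (is.null(flank)) flank <- strrep("A", 501)
  data.frame(probe_id = sprintf("cg%07d", seq_len(n)),
             chrom = chrom, pos = pos,
             structures = structures, island_relation = island,
             snp_flag = FALSE, crossreactive_flag = FALSE,
             flank = flank, stringsAsFactors = FALSE)
}

# Random DNA sequences of fixed length.
random_dna <- function(n, len = 501, seed = NULL) {
  gen <- function() {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

canonical_kmer <- function(x) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  pmin(x, rc)
}
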