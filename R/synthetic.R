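# Synthetic study generator: miniature genome, probe manifest, sample sheet,
# methylation and expression matrices, SNP table, gene list, planted motif.
# Every generator is deterministic given (config, seed) and returns plain
# data.frames / matrices so that outputs round-trip through TSV unchanged.

#' Generate a miniature genome annotation
#'
#' Lays out non-overlapping genes along each chromosome with intergenic
#' gaps of at least 2 kb, and places a CpG island near a subset of
#' transcription start sites. This is the annotation substrate for probe
#' structure/island annotation and nearest-gene assignment.
#'
#' @param n_chromosomes number of chromosomes (>= 1)
#' @param genes_per_chromosome genes on each chromosome (>= 1)
#' @param seed integer RNG seed
#' @param gene_length gene length range in bp
#' @param gap intergenic gap range in bp (minimum must be >= 2000)
#' @param island_prob probability a gene carries a promoter CpG island
#' @return an object of class `genome_annotation`: a list with data.frames
#'   `chromosomes` (name, length), `genes` (gene_id, chrom, strand, start,
#'   end) and `islands` (chrom, start, end)
#' @export
generate_genome <- function(n_chromosomes, genes_per_chromosome, seed,
                            gene_length = c(2000, 10000),
                            gap = c(2000, 8000),
                            island_prob = 0.6) {
  if (n_chromosomes < 1) stop_config("n_chromosomes must be >= 1")
  if (genes_per_chromosome < 1) {
    stop_config("genes_per_chromosome must be >= 1")
  }
  if (gap[1] < 2000) stop_config("minimum intergenic gap must be >= 2000 bp")
  with_seed(seed, {
    genes <- vector("list", n_chromosomes)
    islands <- vector("list", n_chromosomes)
    chrom_len <- integer(n_chromosomes)
    chrom_names <- paste0("chr", seq_len(n_chromosomes))
    gidx <- 0L
    for (ci in seq_len(n_chromosomes)) {
      cursor <- round(runif(1, gap[1], gap[2]))
      start <- end <- integer(genes_per_chromosome)
      strand <- character(genes_per_chromosome)
      isl <- list()
      for (gi in seq_len(genes_per_chromosome)) {
        len <- round(runif(1, gene_length[1], gene_length[2]))
        start[gi] <- cursor + 1L
        end[gi] <- cursor + len
        strand[gi] <- sample(c("+", "-"), 1L)
        if (runif(1) < island_prob) {
          tss <- if (strand[gi] == "+") start[gi] else end[gi]
          half <- round(runif(1, 150, 750))
          isl[[length(isl) + 1L]] <- c(max(1L, tss - half), tss + half)
        }
        cursor <- end[gi] + round(runif(1, gap[1], gap[2]))
      }
      gidx_new <- gidx + seq_len(genes_per_chromosome)
      genes[[ci]] <- data.frame(
        gene_id = sprintf("G%04d", gidx_new),
        chrom = chrom_names[ci], strand = strand,
        start = start, end = end, stringsAsFactors = FALSE)
      gidx <- gidx + genes_per_chromosome
      chrom_len[ci] <- cursor
      if (length(isl)) {
        im <- do.call(rbind, isl)
        im <- im[order(im[, 1]), , drop = FALSE]
        # drop islands that would overlap a previously kept one
        keep <- rep(TRUE, nrow(im))
        last_end <- -1
        for (k in seq_len(nrow(im))) {
          if (im[k, 1] <= last_end) keep[k] <- FALSE else last_end <- im[k, 2]
        }
        im <- im[keep, , drop = FALSE]
        im[, 2] <- pmin(im[, 2], chrom_len[ci])
        islands[[ci]] <- data.frame(chrom = chrom_names[ci],
                                    start = im[, 1], end = im[, 2],
                                    stringsAsFactors = FALSE)
      } else {
        islands[[ci]] <- data.frame(chrom = character(), start = integer(),
                                    end = integer(), stringsAsFactors = FALSE)
      }
    }
    structure(list(
      chromosomes = data.frame(name = chrom_names, length = chrom_len,
                               stringsAsFactors = FALSE),
      genes = do.call(rbind, genes),
      islands = do.call(rbind, islands)),
      class = "genome_annotation")
  })
}

# Structure intervals for one gene, strand-adjusted. The gene span is
# partitioned 10/10/70/10% into 5'UTR / first exon / body / 3'UTR; promoter
# windows follow the 450k manifest convention (TSS200 = [TSS-200, TSS-1],
# TSS1500 = [TSS-1500, TSS-201], both measured along the strand).
gene_structure_intervals <- function(start, end, strand) {
  len <- end - start + 1L
  b1 <- start + max(1L, round(0.1 * len)) - 1L
  b2 <- b1 + max(1L, round(0.1 * len))
  b3 <- end - max(1L, round(0.1 * len))
  if (strand == "+") {
    rbind(
      data.frame(structure = "TSS1500", lo = start - 1500L, hi = start - 201L),
      data.frame(structure = "TSS200",  lo = start - 200L,  hi = start - 1L),
      data.frame(structure = "5UTR",    lo = start,         hi = b1),
      data.frame(structure = "1stExon", lo = b1 + 1L,       hi = b2),
      data.frame(structure = "Body",    lo = b2 + 1L,       hi = b3 - 1L),
      data.frame(structure = "3UTR",    lo = b3,            hi = end))
  } else {
    rbind(
      data.frame(structure = "TSS1500", lo = end + 201L, hi = end + 1500L),
      data.frame(structure = "TSS200",  lo = end + 1L,   hi = end + 200L),
      data.frame(structure = "5UTR",    lo = b3,         hi = end),
      data.frame(structure = "Body",    lo = b2 + 1L,    hi = b3 - 1L),
      data.frame(structure = "1stExon", lo = b1 + 1L,    hi = b2),
      data.frame(structure = "3UTR",    lo = start,      hi = b1))
  }
}

# CpG-island relation of a position: Island beats Shore beats Shelf;
# N_* is the lower-coordinate side. Shores are the 2 kb flanks, shelves
# the following 2-4 kb, OpenSea everything beyond.
island_relation <- function(pos, islands) {
  if (nrow(islands) == 0) return("OpenSea")
  d_in <- pos >= islands$start & pos <= islands$end
  if (any(d_in)) return("Island")
  n_shore <- pos >= islands$start - 2000 & pos < islands$start
  s_shore <- pos > islands$end & pos <= islands$end + 2000
  if (any(n_shore)) return("N_Shore")
  if (any(s_shore)) return("S_Shore")
  n_shelf <- pos >= islands$start - 4000 & pos < islands$start - 2000
  s_shelf <- pos > islands$end + 2000 & pos <= islands$end + 4000
  if (any(n_shelf)) return("N_Shelf")
  if (any(s_shelf)) return("S_Shelf")
  "OpenSea"
}

#' Generate a probe manifest over a genome annotation
#'
#' Samples distinct genomic positions, annotates each probe with every
#' genic structure its position overlaps (a probe may carry several
#' annotations, e.g. inside an island and in a gene body), its CpG-island
#' relation, SNP and cross-reactive flags, and a 501 bp flanking sequence
#' centered on the probe (N-padded where the window runs past a chromosome
#' end, so stored flanks always have odd length).
#'
#' @param genome a `genome_annotation`
#' @param n_probes number of probes to place
#' @param flag_rates list with elements `snp` and `crossreactive`,
#'   independent Bernoulli rates in \[0,1\]
#' @param seed integer RNG seed
#' @param flank_halfwidth half-width of the stored flank (default 250,
#'   matching the motif-stage window)
#' @return data.frame of class `probe_manifest` with columns probe_id,
#'   chrom, pos, structures (";"-separated), island_relation, snp_flag,
#'   crossreactive_flag, flank; rows sorted by (chrom, pos)
#' @export
generate_probes <- function(genome, n_probes,
                            flag_rates = list(snp = 0.05, crossreactive = 0.05),
                            seed = 1, flank_halfwidth = 250) {
  if (n_probes < 1) stop_config("n_probes must be >= 1")
  flag_rates <- merge_config(list(snp = 0.05, crossreactive = 0.05),
                             flag_rates, "flag_rates")
  if (any(unlist(flag_rates) < 0 | unlist(flag_rates) > 1)) {
    stop_config("flag_rates must lie in [0, 1]")
  }
  chrom <- genome$chromosomes
  total <- sum(chrom$length)
  if (n_probes > total) {
    stop_config("n_probes (%d) exceeds available positions (%d)",
                n_probes, total)
  }
  with_seed(seed, {
    offs <- sort(sample.int(total, n_probes))
    cum <- cumsum(chrom$length)
    ci <- findInterval(offs - 1L, c(0L, cum), rightmost.closed = FALSE)
    pos <- offs - c(0L, cum)[ci]
    ord <- order(ci, pos)
    ci <- ci[ord]; pos <- pos[ord]
    chrom_name <- chrom$name[ci]

    structures <- character(n_probes)
    island_rel <- character(n_probes)
    for (cn in unique(chrom_name)) {
      idx <- which(chrom_name == cn)
      g <- genome$genes[genome$genes$chrom == cn, , drop = FALSE]
      ivs <- if (nrow(g)) do.call(rbind, lapply(seq_len(nrow(g)), function(k) {
        gene_structure_intervals(g$start[k], g$end[k], g$strand[k])
      })) else NULL
      isl <- genome$islands[genome$islands$chrom == cn, , drop = FALSE]
      for (i in idx) {
        hit <- character(0)
        if (!is.null(ivs)) {
          hit <- unique(ivs$structure[pos[i] >= ivs$lo & pos[i] <= ivs$hi])
        }
        structures[i] <- if (length(hit)) paste(hit, collapse = ";")
                         else "Intergenic"
        island_rel[i] <- island_relation(pos[i], isl)
      }
    }
    snp_flag <- runif(n_probes) < flag_rates$snp
    cross_flag <- runif(n_probes) < flag_rates$crossreactive

    flank_w <- 2L * flank_halfwidth + 1L
    bases <- c("A", "C", "G", "T")
    chrom_len <- chrom$length[ci]
    flank <- vapply(seq_len(n_probes), function(i) {
      lo <- pos[i] - flank_halfwidth
      hi <- pos[i] + flank_halfwidth
      n_left <- max(0L, 1L - lo)
      n_right <- max(0L, hi - chrom_len[i])
      core <- paste(sample(bases, flank_w - n_left - n_right, replace = TRUE),
                    collapse = "")
      paste0(strrep("N", n_left), core, strrep("N", n_right))
    }, character(1))

    out <- data.frame(
      probe_id = sprintf("cg%07d", seq_len(n_probes)),
      chrom = chrom_name, pos = pos,
      structures = structures, island_relation = island_rel,
      snp_flag = snp_flag, crossreactive_flag = cross_flag,
      flank = flank, stringsAsFactors = FALSE)
    class(out) <- c("probe_manifest", "data.frame")
    out
  })
}

#' Generate a sample sheet
#'
#' Emulates the study design: prepubertal participants with a continuous
#' life-stress (LSI) severity score on a 5-point scale, half the cohort
#' drawn from the low end of the score range and half from the high end,
#' ages uniform on 9-12 years, and two beadchip batches assigned
#' alternately.
#'
#' @param n_samples number of samples (>= 4; the regression design has an
#'   intercept, score, age and batch column)
#' @param score_range numeric length-2, LSI score range (must be
#'   non-degenerate)
#' @param seed integer RNG seed
#' @param age_range age range in years
#' @return data.frame with columns sample_id, lsi_score, age, batch
#' @export
generate_samples <- function(n_samples = 22, score_range = c(1, 5), seed = 1,
                             age_range = c(9, 12)) {
  if (n_samples < 4) {
    stop_config("n_samples must be >= 4 (design has 4 columns)")
  }
  if (diff(range(score_range)) <= 0) {
    stop_config("score_range is degenerate: a constant LSI score cannot be used as regressor")
  }
  with_seed(seed, {
    lo <- min(score_range); hi <- max(score_range)
    span <- hi - lo
    n_low <- ceiling(n_samples / 2)
    n_high <- n_samples - n_low
    lsi <- c(runif(n_low, lo, lo + 0.4 * span),
             runif(n_high, hi - 0.4 * span, hi))
    lsi <- round(lsi, 2)
    if (length(unique(lsi)) < 2) lsi[1] <- lsi[1] + 0.01
    data.frame(
      sample_id = sprintf("S%02d", seq_len(n_samples)),
      lsi_score = lsi,
      age = round(runif(n_samples, age_range[1], age_range[2]), 1),
      batch = rep(c("chip1", "chip2"), length.out = n_samples),
      stringsAsFactors = FALSE)
  })
}

default_effect_config <- function() {
  list(n_clusters = 10, cluster_width = 12,
       effect_size = c(0.25, 0.6),  # |slope| range, M-units per LSI unit
       noise_sd = 0.5, rho = 0.3,
       age_sd = 0.02, batch_sd = 0.1,
       detection_fail_rate = 0.002)
}

#' Generate a methylation matrix with planted, spatially clustered effects
#'
#' Beta values are produced on the M (log2-logit) scale as
#' `baseline_i + b_i * lsi + a_i * age + batch_i + AR(1) noise` and mapped
#' back through the inverse logit2, so true effect slopes are expressed in
#' M-units per unit LSI score. Effect slopes `b_i` are non-zero only inside
#' planted clusters that are contiguous in genomic order and share one
#' slope per cluster, emulating coherent differentially methylated regions.
#' Noise is AR(1) along probe order within each chromosome (stationary
#' marginal SD `noise_sd`), giving the local correlation the HMM stage
#' exploits. Detection p-values are Uniform(0, 0.01) except for planted
#' failures, Uniform(0.01, 1).
#'
#' @param probes a `probe_manifest`
#' @param samples a sample sheet from [generate_samples()]
#' @param effect_config list overriding any of: n_clusters, cluster_width,
#'   effect_size (length-2 magnitude range), noise_sd (>= 0; 0 is the exact
#'   noiseless regime), rho (AR(1) coefficient), age_sd, batch_sd,
#'   detection_fail_rate
#' @param seed integer RNG seed
#' @return list with `beta` and `detection_p` (probes x samples matrices)
#'   and `truth` (data.frame: probe_id, chrom, pos, effect, effect_size)
#' @export
generate_methylation <- function(probes, samples, effect_config = list(),
                                 seed = 1) {
  cfg <- merge_config(default_effect_config(), effect_config, "effect_config")
  if (cfg$noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (cfg$rho < 0 || cfg$rho >= 1) stop_config("rho must be in [0, 1)")
  n <- nrow(probes); m <- nrow(samples)
  with_seed(seed, {
    # plant clusters: contiguous runs in genomic order within one chromosome
    effect <- logical(n)
    effect_size <- numeric(n)
    chrom_rle <- rle(probes$chrom)
    seg_end <- cumsum(chrom_rle$lengths)
    seg_start <- seg_end - chrom_rle$lengths + 1L
    if (cfg$n_clusters > 0) {
      w <- cfg$cluster_width
      eligible <- function() {
        # candidate start indices: run of w probes inside one chromosome,
        # not touching an existing effect probe (keeps clusters separated)
        ok <- logical(n)
        for (s in seq_along(seg_start)) {
          if (chrom_rle$lengths[s] >= w) {
            ok[seg_start[s]:(seg_end[s] - w + 1L)] <- TRUE
          }
        }
        bad <- which(effect)
        for (b in bad) ok[max(1L, b - w):(min(n, b + 1L))] <- FALSE
        which(ok)
      }
      for (k in seq_len(cfg$n_clusters)) {
        cand <- eligible()
        if (!length(cand)) {
          stop_config("cannot place %d clusters of width %d in %d probes",
                      cfg$n_clusters, w, n)
        }
        st <- cand[sample.int(length(cand), 1L)]
        idx <- st:(st + w - 1L)
        b <- runif(1, cfg$effect_size[1], cfg$effect_size[2]) *
          sample(c(-1, 1), 1L)
        effect[idx] <- TRUE
        effect_size[idx] <- b
      }
    }
    # probe-level parameters: bimodal baseline as on real arrays
    baseline <- ifelse(runif(n) < 0.5, rnorm(n, -2.5, 1), rnorm(n, 2.5, 1))
    age_coef <- rnorm(n, 0, cfg$age_sd)
    batch_coef <- rnorm(n, 0, cfg$batch_sd)
    batch_ind <- as.numeric(samples$batch == samples$batch[1])

    mmat <- baseline +
      outer(effect_size, samples$lsi_score) +
      outer(age_coef, samples$age) +
      outer(batch_coef, batch_ind)

    if (cfg$noise_sd > 0) {
      noise <- matrix(0, n, m)
      innov_sd <- cfg$noise_sd * sqrt(1 - cfg$rho^2)
      for (s in seq_along(seg_start)) {
        i0 <- seg_start[s]; i1 <- seg_end[s]
        noise[i0, ] <- rnorm(m, 0, cfg$noise_sd)
        if (i1 > i0) {
          for (i in (i0 + 1L):i1) {
            noise[i, ] <- cfg$rho * noise[i - 1L, ] + rnorm(m, 0, innov_sd)
          }
        }
      }
      mmat <- mmat + noise
    }
    beta <- ilogit2(mmat)
    eps <- 1e-12
    beta[beta <= 0] <- eps
    beta[beta >= 1] <- 1 - eps
    detp <- matrix(runif(n * m, 0, 0.01), n, m)
    fail <- matrix(runif(n * m) < cfg$detection_fail_rate, n, m)
    detp[fail] <- runif(sum(fail), 0.01, 1)
    dimnames(beta) <- dimnames(detp) <- list(probes$probe_id,
                                             samples$sample_id)
    truth <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                        pos = probes$pos, effect = effect,
                        effect_size = effect_size, stringsAsFactors = FALSE)
    list(beta = beta, detection_p = detp, truth = truth)
  })
}

default_de_config <- function() {
  list(de_fraction = 0.1, overlap_fraction = 0.5,
       dispersion = 0.1, mean_depth = 500,
       lfc_range = c(0.3, 0.8),  # |slope| of log2 mean per LSI unit
       isoforms_per_gene = c(1, 3))
}

#' Generate expression count matrices with planted differential expression
#'
#' Gene and isoform counts are negative-binomial with log mean linear in
#' the LSI score for planted DE genes; a configured fraction of DE genes is
#' taken from genes hosting methylation-effect probes (nearest-gene
#' assignment of the truth table), sharing the planted signal across data
#' types. Isoforms inherit their gene's DE slope.
#'
#' @param genome a `genome_annotation`
#' @param samples sample sheet
#' @param truth methylation truth table (from [generate_methylation()]);
#'   may be NULL, in which case no overlap is planted
#' @param de_config list overriding any of: de_fraction, overlap_fraction,
#'   dispersion (> 0), mean_depth, lfc_range, isoforms_per_gene
#' @param seed integer RNG seed
#' @return list with `gene_counts`, `isoform_counts` (integer matrices),
#'   `isoform_map` (isoform_id, gene_id) and `truth` (feature-level DE
#'   indicators and log-scale effect sizes)
#' @export
generate_expression <- function(genome, samples, truth = NULL,
                                de_config = list(), seed = 1) {
  cfg <- merge_config(default_de_config(), de_config, "de_config")
  if (cfg$dispersion <= 0) stop_config("dispersion must be > 0")
  genes <- genome$genes$gene_id
  ng <- length(genes); m <- nrow(samples)
  with_seed(seed, {
    n_de <- round(cfg$de_fraction * ng)
    meth_genes <- character(0)
    if (!is.null(truth) && any(truth$effect)) {
      eff <- truth[truth$effect, , drop = FALSE]
      meth_genes <- unique(map_nearest_gene(eff, genome)$gene_id)
      meth_genes <- meth_genes[!is.na(meth_genes)]
    }
    n_from_meth <- min(length(meth_genes), round(cfg$overlap_fraction * n_de))
    de_genes <- character(0)
    if (n_de > 0) {
      de_genes <- if (n_from_meth > 0) {
        sample(meth_genes, n_from_meth)
      } else character(0)
      rest <- setdiff(genes, meth_genes)
      n_rest <- min(length(rest), n_de - length(de_genes))
      if (n_rest > 0) de_genes <- c(de_genes, sample(rest, n_rest))
    }
    slope <- setNames(numeric(ng), genes)
    slope[de_genes] <- runif(length(de_genes), cfg$lfc_range[1],
                             cfg$lfc_range[2]) *
      sample(c(-1, 1), length(de_genes), replace = TRUE)

    base <- rnorm(ng, 0, 1)  # gene-level abundance offsets (log2 scale)
    base <- base - log2(mean(2^base))  # cohort-average depth = mean_depth
    lsi_c <- samples$lsi_score - mean(samples$lsi_score)
    mu <- cfg$mean_depth * 2^(outer(base, rep(1, m)) + outer(slope, lsi_c))
    gene_counts <- matrix(rnbinom(ng * m, mu = mu, size = 1 / cfg$dispersion),
                          ng, m, dimnames = list(genes, samples$sample_id))

    n_iso <- sample(cfg$isoforms_per_gene[1]:cfg$isoforms_per_gene[2],
                    ng, replace = TRUE)
    iso_gene <- rep(genes, n_iso)
    iso_id <- paste0(iso_gene, ".", unlist(lapply(n_iso, seq_len)))
    # split each gene's mean over its isoforms with fixed proportions
    props <- unlist(lapply(n_iso, function(k) {
      p <- runif(k, 0.2, 1); p / sum(p)
    }))
    iso_mu <- mu[match(iso_gene, genes), , drop = FALSE] * props
    isoform_counts <- matrix(
      rnbinom(length(iso_mu), mu = iso_mu, size = 1 / cfg$dispersion),
      nrow(iso_mu), m, dimnames = list(iso_id, samples$sample_id))

    truth_expr <- data.frame(
      feature_id = c(genes, iso_id),
      level = rep(c("gene", "isoform"), c(ng, length(iso_id))),
      gene_id = c(genes, iso_gene),
      de = c(slope != 0, slope[match(iso_gene, genes)] != 0),
      effect_size = c(slope, slope[match(iso_gene, genes)]),
      stringsAsFactors = FALSE)
    list(gene_counts = gene_counts, isoform_counts = isoform_counts,
         isoform_map = data.frame(isoform_id = iso_id, gene_id = iso_gene,
                                  stringsAsFactors = FALSE),
         truth = truth_expr)
  })
}

#' Generate a curated gene list enriched for true-effect genes
#'
#' Emulates a stress-related gene list: genes hosting true effects enter
#' the list with probability `min(1, enrichment_factor * base_rate)`, all
#' other genes at `base_rate`.
#'
#' @param genes character vector, the gene universe
#' @param effect_genes character vector of genes carrying true effects
#' @param enrichment_factor at least 1; 1 makes membership independent of
#'   truth
#' @param base_rate baseline inclusion probability
#' @param seed integer RNG seed
#' @return character vector (subset of `genes`)
#' @export
generate_gene_list <- function(genes, effect_genes = character(0),
                               enrichment_factor = 3, base_rate = 0.2,
                               seed = 1) {
  if (length(genes) == 0) stop_config("gene universe is empty")
  if (enrichment_factor < 1) stop_config("enrichment_factor must be >= 1")
  with_seed(seed, {
    p <- ifelse(genes %in% effect_genes,
                pmin(1, enrichment_factor * base_rate), base_rate)
    genes[runif(length(genes)) < p]
  })
}

#' Generate an mQTL/SNP position table
#'
#' Places a SNP within `max_offset` bp of a configured fraction of probes
#' (emulating methylation quantitative trait loci reported near CpGs) plus
#' uniformly scattered background SNPs.
#'
#' @param genome a `genome_annotation`
#' @param probes a `probe_manifest`
#' @param near_fraction fraction of probes given a nearby SNP
#' @param n_background count of uniformly placed background SNPs
#' @param max_offset maximal |SNP - probe| distance for planted SNPs (bp)
#' @param seed integer RNG seed
#' @return data.frame (chrom, pos, snp_id), sorted by (chrom, pos)
#' @export
generate_snps <- function(genome, probes, near_fraction = 0.1,
                          n_background = 200, max_offset = 150, seed = 1) {
  with_seed(seed, {
    n_near <- round(near_fraction * nrow(probes))
    idx <- if (n_near > 0) sample.int(nrow(probes), n_near) else integer(0)
    near <- data.frame(
      chrom = probes$chrom[idx],
      pos = pmax(1L, probes$pos[idx] +
                   sample(c(-1L, 1L), n_near, replace = TRUE) *
                   sample.int(max_offset, n_near, replace = TRUE)),
      stringsAsFactors = FALSE)
    ci <- sample.int(nrow(genome$chromosomes), n_background, replace = TRUE,
                     prob = genome$chromosomes$length)
    bg <- data.frame(
      chrom = genome$chromosomes$name[ci],
      pos = vapply(genome$chromosomes$length[ci],
                   function(L) sample.int(L, 1L), integer(1)),
      stringsAsFactors = FALSE)
    out <- rbind(near, bg)
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    out$snp_id <- sprintf("rs%06d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out
  })
}

#' Plant a motif into probe flanking sequences
#'
#' Overwrites (does not shift) bases at a random offset of the stored flank
#' for `round(fraction * length(which_probes))` of the designated probes.
#'
#' @param manifest a `probe_manifest`
#' @param motif DNA string, length 4-12, A/C/G/T only
#' @param fraction fraction of designated probes to receive the motif
#' @param which_probes probe ids to draw from (default: all probes)
#' @param seed integer RNG seed
#' @return the manifest with modified `flank` column; attribute
#'   `planted_probes` lists the probes that received the motif
#' @export
plant_motif <- function(manifest, motif, fraction, which_probes = NULL,
                        seed = 1) {
  if (!grepl("^[ACGT]+$", motif) || nchar(motif) < 4 || nchar(motif) > 12) {
    stop_config("motif must be a DNA string of length 4-12")
  }
  if (fraction < 0 || fraction > 1) stop_config("fraction must be in [0, 1]")
  which_probes <- which_probes %||% manifest$probe_id
  idx <- match(which_probes, manifest$probe_id)
  if (anyNA(idx)) stop_value("unknown probe id(s) in which_probes")
  if (any(nchar(motif) > nchar(manifest$flank[idx]))) {
    stop_config("motif longer than flank")
  }
  n_plant <- round(fraction * length(idx))
  with_seed(seed, {
    chosen <- if (n_plant > 0) sample(idx, n_plant) else integer(0)
    for (i in chosen) {
      L <- nchar(manifest$flank[i])
      off <- sample.int(L - nchar(motif) + 1L, 1L)
      substr(manifest$flank[i], off, off + nchar(motif) - 1L) <- motif
    }
    attr(manifest, "planted_probes") <- manifest$probe_id[chosen]
    manifest
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper running every generator with per-stage seeds derived
#' from one master seed, under the default study conditions (22 samples,
#' 2,000 probes, 10 planted clusters of width 12).
#'
#' @param n_chromosomes,genes_per_chromosome,n_probes,n_samples study sizes
#' @param effect_config,de_config generator overrides, see
#'   [generate_methylation()] and [generate_expression()]
#' @param motif optional DNA string planted into 30% of effect-probe flanks
#' @param seed master integer seed
#' @return list: genome, probes, samples, beta, detection_p, truth, snps,
#'   expression (gene_counts, isoform_counts, isoform_map, truth),
#'   gene_list
#' @export
simulate_study <- function(n_chromosomes = 4, genes_per_chromosome = 50,
                           n_probes = 2000, n_samples = 22,
                           effect_config = list(), de_config = list(),
                           motif = NULL, seed = 1) {
  s <- function(stage) derive_seed(seed, stage)
  genome <- generate_genome(n_chromosomes, genes_per_chromosome,
                            seed = s("simulate"))
  probes <- generate_probes(genome, n_probes, seed = s("preprocess"))
  samples <- generate_samples(n_samples, seed = s("dml"))
  meth <- generate_methylation(probes, samples, effect_config,
                               seed = s("enrich"))
  expr <- generate_expression(genome, samples, meth$truth, de_config,
                              seed = s("expression"))
  effect_genes <- unique(expr$truth$gene_id[expr$truth$de])
  gene_list <- generate_gene_list(genome$genes$gene_id, effect_genes,
                                  seed = s("integrate"))
  snps <- generate_snps(genome, probes, seed = s("motif"))
  if (!is.null(motif)) {
    eff_ids <- meth$truth$probe_id[meth$truth$effect]
    if (length(eff_ids)) {
      probes <- plant_motif(probes, motif, 0.3, eff_ids, seed = s("motif"))
    }
  }
  list(genome = genome, probes = probes, samples = samples,
       beta = meth$beta, detection_p = meth$detection_p, truth = meth$truth,
       snps = snps, expression = expr, gene_list = gene_list)
}
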