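# Flank extraction, composition-preserving background shuffles, and the
# internal discriminative k-mer enrichment check on DML flanking sequence.

#' Extract DML flanking sequences
#'
#' One record per called DML: the stored flank trimmed to position ±
#' `halfwidth`. N padding written by the generator at chromosome ends is
#' stripped, so records near a chromosome edge come out truncated (logged).
#'
#' @param dml_probes probe ids of called DMLs
#' @param manifest `probe_manifest` with `flank` column
#' @param halfwidth half-window in bp (default 250)
#' @return named [Biostrings::DNAStringSet]; attribute `n_truncated`
#' @export
extract_flanks <- function(dml_probes, manifest, halfwidth = 250) {
  if (halfwidth < 1) stop_config("halfwidth must be >= 1")
  if (length(dml_probes) == 0) {
    warning("no called DMLs; returning empty FASTA", call. = FALSE)
    return(Biostrings::DNAStringSet())
  }
  idx <- match(dml_probes, manifest$probe_id)
  if (anyNA(idx)) stop_value("probe id(s) absent from manifest")
  flank <- manifest$flank[idx]
  missing <- is.na(flank) | !nzchar(flank)
  if (any(missing)) {
    warning(sprintf("%d record(s) skipped: missing flank", sum(missing)),
            call. = FALSE)
    idx <- idx[!missing]; flank <- flank[!missing]
    dml_probes <- dml_probes[!missing]
  }
  stored_half <- (nchar(flank) - 1L) %/% 2L
  trim <- pmin(halfwidth, stored_half)
  center <- stored_half + 1L
  seqs <- substr(flank, center - trim, center + trim)
  # strip generator N padding at chromosome ends
  seqs <- sub("^N+", "", seqs)
  seqs <- sub("N+$", "", seqs)
  n_trunc <- sum(nchar(seqs) < 2L * halfwidth + 1L)
  if (n_trunc > 0) {
    message(sprintf("%d flank record(s) truncated at a chromosome end",
                    n_trunc))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- dml_probes
  attr(out, "n_truncated") <- n_trunc
  out
}

# Altschul-Erickson dinucleotide shuffle of one sequence: permutes the
# edges of the dinucleotide transition multigraph while preserving an
# Eulerian path from the first to the last symbol, so the dinucleotide
# count multiset is preserved exactly.
dinuc_shuffle_one <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 3) return(seq)
  verts <- unique(ch)
  from <- match(ch[-n], verts)
  to <- match(ch[-1], verts)
  last_v <- match(ch[n], verts)
  edges <- split(to, from)                      # out-edge targets per vertex
  out_v <- as.integer(names(edges))
  # choose each non-final vertex's last out-edge so the chosen edges form
  # an arborescence toward the final vertex (rejection sampling; the graph
  # has at most 4 vertices so acceptance is fast)
  repeat {
    last_edge <- rep(NA_integer_, length(verts))
    for (v in out_v) {
      if (v != last_v) {
        tv <- edges[[as.character(v)]]
        last_edge[v] <- tv[sample.int(length(tv), 1L)]
      }
    }
    ok <- TRUE
    for (v in out_v) {
      if (v == last_v) next
      cur <- v; steps <- 0L
      while (!is.na(cur) && cur != last_v && steps <= length(verts)) {
        cur <- last_edge[cur]
        steps <- steps + 1L
      }
      if (is.na(cur) || cur != last_v) { ok <- FALSE; break }
    }
    if (ok) break
  }
  # shuffle remaining edges, append the reserved last edges
  shuffled <- lapply(seq_along(verts), function(v) {
    tv <- edges[[as.character(v)]]
    if (is.null(tv)) return(integer(0))
    if (!is.na(last_edge[v])) {
      pos <- match(last_edge[v], tv)
      tv <- tv[-pos]
    }
    c(if (length(tv)) tv[sample.int(length(tv))] else integer(0),
      if (!is.na(last_edge[v])) last_edge[v] else integer(0))
  })
  ptr <- rep(1L, length(verts))
  path <- integer(n)
  path[1] <- match(ch[1], verts)
  for (i in 2:n) {
    v <- path[i - 1]
    path[i] <- shuffled[[v]][ptr[v]]
    ptr[v] <- ptr[v] + 1L
  }
  paste(verts[path], collapse = "")
}

#' Shuffle sequences preserving mono- or dinucleotide composition
#'
#' Mononucleotide mode permutes bases; dinucleotide mode performs an
#' Eulerian-path (Altschul–Erickson) shuffle preserving the exact
#' dinucleotide count multiset. Sequences shorter than 2 bases pass
#' through unchanged in dinucleotide mode.
#'
#' @param seqs [Biostrings::DNAStringSet] or character vector
#' @param mode "mononucleotide" or "dinucleotide"
#' @param seed integer RNG seed
#' @return shuffled sequences, same type and names as the input
#' @export
shuffle_background <- function(seqs, mode = c("dinucleotide",
                                              "mononucleotide"), seed = 1) {
  mode <- match.arg(mode)
  was_xs <- inherits(seqs, "XStringSet")
  s <- as.character(seqs)
  with_seed(seed, {
    out <- vapply(s, function(x) {
      if (mode == "mononucleotide") {
        paste(sample(strsplit(x, "")[[1]]), collapse = "")
      } else if (nchar(x) < 2) x else dinuc_shuffle_one(x)
    }, character(1), USE.NAMES = FALSE)
    if (was_xs) {
      res <- Biostrings::DNAStringSet(out)
      names(res) <- names(seqs)
      res
    } else {
      names(out) <- names(s)
      out
    }
  })
}

# Sequence-level presence counts of canonical k-mers (k-mer and reverse
# complement collapsed) for a DNAStringSet; windows containing N are
# ignored by the underlying counter.
canonical_presence <- function(seqs, k) {
  cnt <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  if (is.null(dim(cnt))) {
    cnt <- matrix(cnt, nrow = 1, dimnames = list(NULL, names(cnt)))
  }
  kmers <- colnames(cnt)
  canon <- pmin(kmers, revcomp(kmers))
  pres <- cnt > 0                                  # sequence x k-mer
  agg <- t(rowsum(t(pres) + 0L, group = canon))    # sequence x canonical
  colSums(agg > 0)
}

#' Discriminative k-mer enrichment of foreground vs background sequences
#'
#' For every distinct canonical k-mer present in the foreground (k-mer and
#' reverse complement collapsed), builds the 2x2 sequence-level presence
#' table against the background and computes a one-sided Fisher exact
#' p-value (hypergeometric tail). The E-value is p times the number of
#' distinct canonical k-mers tested across all k.
#'
#' @param foreground,background [Biostrings::DNAStringSet] or character
#' @param k_min,k_max k-mer length range (3 <= k_min <= k_max <= 10)
#' @param e_cutoff report k-mers with E below this (default 1e-3;
#'   use `Inf` to return the full ranking)
#' @return data.frame of class `kmer_result` sorted by E ascending: kmer,
#'   k, fg_count, bg_count, p, evalue; attribute `n_tested`
#' @export
kmer_enrichment <- function(foreground, background, k_min = 4, k_max = 8,
                            e_cutoff = 1e-3) {
  if (k_min < 3 || k_max > 10 || k_min > k_max) {
    stop_config("need 3 <= k_min <= k_max <= 10")
  }
  fg <- Biostrings::DNAStringSet(as.character(foreground))
  bg <- Biostrings::DNAStringSet(as.character(background))
  if (length(fg) == 0) stop_value("foreground is empty")
  if (length(bg) == 0) stop_value("background is empty")
  n_fg <- length(fg); n_bg <- length(bg)
  rows <- list()
  for (k in k_min:k_max) {
    fg_pres <- canonical_presence(fg, k)
    bg_pres <- canonical_presence(bg, k)
    keep <- fg_pres > 0
    if (!any(keep)) next
    km <- names(fg_pres)[keep]
    a <- fg_pres[keep]
    b <- bg_pres[km]
    b[is.na(b)] <- 0L
    # one-sided Fisher exact on [[a, n_fg - a], [b, n_bg - b]]
    p <- stats::phyper(a - 1, a + b, n_fg + n_bg - a - b, n_fg,
                       lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      kmer = km, k = k, fg_count = as.integer(a), bg_count = as.integer(b),
      p = p, stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, rows)
  n_tested <- nrow(res)
  res$evalue <- res$p * n_tested
  res <- res[order(res$evalue, res$p, res$kmer), , drop = FALSE]
  res <- res[res$evalue < e_cutoff, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_tested
  class(res) <- c("kmer_result", "data.frame")
  res
}
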