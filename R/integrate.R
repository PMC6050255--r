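# Gene-level integration: nearest-gene mapping, direction-classified gene
# sets, Venn overlap with DE genes and curated lists, Yates-corrected
# chi-square enrichment, and the consolidated report.

#' Assign each DML to its nearest gene
#'
#' A DML inside a gene's span is assigned to that gene; otherwise to the
#' gene on the same chromosome with minimal distance to the nearer of its
#' start/end boundaries. Exact ties go to the alphabetically first gene id.
#' DMLs on chromosomes with no genes stay unassigned (NA) with a warning.
#'
#' @param calls data.frame with probe_id, chrom, pos
#' @param genome a `genome_annotation`
#' @return data.frame: probe_id, chrom, pos, gene_id, distance (0 inside
#'   the gene span)
#' @export
map_nearest_gene <- function(calls, genome) {
  genes <- genome$genes
  out <- data.frame(probe_id = calls$probe_id, chrom = calls$chrom,
                    pos = calls$pos, gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  n_orphan <- 0L
  for (cn in unique(calls$chrom)) {
    ci <- which(calls$chrom == cn)
    g <- genes[genes$chrom == cn, , drop = FALSE]
    if (nrow(g) == 0) {
      n_orphan <- n_orphan + length(ci)
      next
    }
    g <- g[order(g$gene_id), , drop = FALSE]  # alphabetical tie-break
    for (i in ci) {
      p <- calls$pos[i]
      d <- ifelse(p >= g$start & p <= g$end, 0,
                  pmin(abs(p - g$start), abs(p - g$end)))
      k <- which.min(d)  # first minimum = alphabetically first on ties
      out$gene_id[i] <- g$gene_id[k]
      out$distance[i] <- d[k]
    }
  }
  if (n_orphan > 0) {
    warning(sprintf("%d DML(s) on chromosome(s) without genes left unassigned",
                    n_orphan), call. = FALSE)
  }
  out
}

#' Build direction-classified gene sets from DML assignments
#'
#' A gene enters the positive set if it hosts at least one positive DML,
#' the negative set likewise; genes hosting both kinds appear in both (the
#' `both` intersection), so |union| = |positive| + |negative| - |both|.
#' Unassigned DMLs (NA gene) are dropped.
#'
#' @param assignments data.frame with gene_id and direction
#'   ("positive"/"negative") per DML
#' @return object of class `gene_sets`: list(positive, negative, both,
#'   union, dml_per_gene)
#' @export
aggregate_genes <- function(assignments) {
  ok <- !is.na(assignments$gene_id) & !is.na(assignments$direction)
  a <- assignments[ok, , drop = FALSE]
  positive <- sort(unique(a$gene_id[a$direction == "positive"]))
  negative <- sort(unique(a$gene_id[a$direction == "negative"]))
  both <- intersect(positive, negative)
  un <- sort(union(positive, negative))
  stopifnot(length(un) == length(positive) + length(negative) - length(both))
  dml_per_gene <- table(a$gene_id)
  structure(list(positive = positive, negative = negative, both = both,
                 union = un,
                 dml_per_gene = setNames(as.integer(dml_per_gene),
                                         names(dml_per_gene))),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d genes (%d positive, %d negative, %d both)\n",
              length(x$union), length(x$positive), length(x$negative),
              length(x$both)))
  invisible(x)
}

#' Three-way Venn overlap of gene sets within a universe
#'
#' Computes the seven Venn region counts for methylation genes, expression
#' genes and a curated list. Members outside the stated universe are
#' dropped with a log note (count reported).
#'
#' @param meth_genes,de_genes,curated character vectors
#' @param universe character vector, the gene universe
#' @return list of class `overlap_report`: `regions` (named counts),
#'   `n_union`, `dropped` (outside-universe count per set)
#' @export
overlap_sets <- function(meth_genes, de_genes, curated, universe) {
  if (length(universe) == 0) stop_value("gene universe is empty")
  sets <- list(meth = unique(meth_genes), expr = unique(de_genes),
               curated = unique(curated))
  dropped <- vapply(sets, function(s) sum(!s %in% universe), integer(1))
  if (any(dropped > 0)) {
    message(sprintf("dropped outside-universe members: %s",
                    paste(sprintf("%s=%d", names(dropped), dropped),
                          collapse = ", ")))
  }
  sets <- lapply(sets, intersect, universe)
  all3 <- Reduce(union, sets)
  inm <- all3 %in% sets$meth
  ine <- all3 %in% sets$expr
  inc <- all3 %in% sets$curated
  regions <- c(
    meth_only = sum(inm & !ine & !inc),
    expr_only = sum(!inm & ine & !inc),
    curated_only = sum(!inm & !ine & inc),
    meth_expr = sum(inm & ine & !inc),
    meth_curated = sum(inm & !ine & inc),
    expr_curated = sum(!inm & ine & inc),
    all_three = sum(inm & ine & inc))
  stopifnot(sum(regions) == length(all3))
  structure(list(regions = regions, n_union = length(all3),
                 dropped = dropped, universe_size = length(unique(universe))),
            class = "overlap_report")
}

#' Yates-corrected chi-square enrichment of a gene set in a curated list
#'
#' Builds the 2x2 table (in `gene_set` vs rest of universe) x (in
#' `curated` vs not) and computes the continuity-corrected statistic
#' `sum((max(|O - E| - 0.5, 0))^2 / E)` on 1 df (the correction is clamped
#' at zero so exact proportional agreement gives statistic 0).
#'
#' @param gene_set,curated,universe character vectors
#' @return list: statistic, df, p.value, table (2x2), expected
#' @export
chisq_list_enrichment <- function(gene_set, curated, universe) {
  if (length(universe) == 0) stop_value("gene universe is empty")
  u <- unique(universe)
  gs <- intersect(unique(gene_set), u)
  cl <- intersect(unique(curated), u)
  a <- length(intersect(gs, cl))
  b <- length(gs) - a
  cc <- length(cl) - a
  d <- length(u) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(set = c("in_set", "out_set"),
                                list = c("in_list", "out_list")))
  margins <- c(rowSums(tab), colSums(tab))
  names(margins) <- c("in_set", "out_set", "in_list", "out_list")
  if (any(margins == 0)) {
    stop_value("zero margin in 2x2 table: %s",
               paste(names(margins)[margins == 0], collapse = ", "))
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum(pmax(abs(tab - E) - 0.5, 0)^2 / E)
  list(statistic = stat, df = 1L,
       p.value = pchisq(stat, df = 1, lower.tail = FALSE),
       table = tab, expected = E)
}

#' Consolidated methylation–expression–gene-list report
#'
#' Emits (a) genes both differentially methylated and expressed with their
#' DML counts, (b) chi-square enrichments of the methylation set, the
#' expression set, and their overlap against the curated list, (c) mQTL
#' near/far counts, and (d) re-verified set-arithmetic identities (a
#' violation raises a pipeline error, indicating an upstream bug).
#'
#' @param gene_sets `gene_sets` from [aggregate_genes()]
#' @param de_genes character vector of unique DE genes
#' @param curated curated gene list
#' @param universe gene universe for the chi-square tests
#' @param mqtl_summary optional named vector c(near=, far=) from
#'   [mqtl_proximity()]
#' @return list of class `integration_report`: overlap_genes (data.frame),
#'   chisq (list of three tests), counts (named numeric summary), venn
#'   (`overlap_report`)
#' @export
integrate_report <- function(gene_sets, de_genes, curated, universe,
                             mqtl_summary = NULL) {
  # identity re-verification
  if (length(gene_sets$union) !=
      length(gene_sets$positive) + length(gene_sets$negative) -
      length(gene_sets$both)) {
    stop_pipeline("gene-set inclusion-exclusion identity violated")
  }
  venn <- overlap_sets(gene_sets$union, de_genes, curated, universe)
  if (sum(venn$regions) != venn$n_union) {
    stop_pipeline("Venn region counts do not sum to the union size")
  }
  overlap <- intersect(gene_sets$union, de_genes)
  overlap_genes <- data.frame(
    gene_id = overlap,
    n_dml = as.integer(gene_sets$dml_per_gene[overlap]),
    stringsAsFactors = FALSE)
  chisq <- list(
    methylation = tryCatch(
      chisq_list_enrichment(gene_sets$union, curated, universe),
      stressmeth_value_error = function(e) e),
    expression = tryCatch(
      chisq_list_enrichment(de_genes, curated, universe),
      stressmeth_value_error = function(e) e),
    overlap = tryCatch(
      chisq_list_enrichment(overlap, curated, universe),
      stressmeth_value_error = function(e) e))
  counts <- c(
    n_meth_genes = length(gene_sets$union),
    n_meth_positive = length(gene_sets$positive),
    n_meth_negative = length(gene_sets$negative),
    n_meth_both = length(gene_sets$both),
    n_de_genes = length(unique(de_genes)),
    n_de_on_list = length(intersect(unique(de_genes), unique(curated))),
    n_de_off_list = length(setdiff(unique(de_genes), unique(curated))),
    n_overlap_genes = length(overlap))
  if (!is.null(mqtl_summary)) {
    counts <- c(counts, n_dml_mqtl_near = unname(mqtl_summary["near"]),
                n_dml_mqtl_far = unname(mqtl_summary["far"]),
                n_dml_total = unname(sum(mqtl_summary)))
  }
  structure(list(overlap_genes = overlap_genes, chisq = chisq,
                 counts = counts, venn = venn),
            class = "integration_report")
}

#' @export
print.integration_report <- function(x, ...) {
  cat("Integration report\n")
  for (nm in names(x$counts)) cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}
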