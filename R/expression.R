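# Expression arm: log transform, quantile normalization, and differential
# expression against the continuous stress score (same linear model and
# variance moderation as the methylation arm).

#' Log-transform and quantile-normalize a count matrix
#'
#' Applies `log2(count + 1)`, then quantile normalization: each column's
#' values are replaced by the cross-column means of the order statistics at
#' each rank, so every column shares an identical sorted-value vector
#' afterwards. Tied values within a column receive the mean of the
#' reference values their ranks span. A zero-variance column (all counts
#' equal) passes through with a warning (its rank structure is a single tie
#' group).
#'
#' @param counts non-negative features x samples count matrix
#' @param log_transform apply log2(x + 1) first (default TRUE)
#' @return normalized numeric matrix, same dimnames
#' @export
normalize_counts <- function(counts, log_transform = TRUE) {
  if (any(counts < 0)) stop_value("counts must be non-negative")
  x <- if (log_transform) log2(counts + 1) else counts
  if (ncol(x) == 1L) return(x)
  zero_var <- apply(x, 2, function(col) length(unique(col)) == 1L)
  if (any(zero_var)) {
    warning(sprintf("%d zero-variance column(s) in quantile normalization",
                    sum(zero_var)), call. = FALSE)
  }
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    v <- ref
    g <- match(x[o, j], unique(x[o, j]))  # tie groups along the sort
    v <- stats::ave(v, g)                 # ties share the mean of spanned refs
    out[o, j] <- v
  }
  out
}

#' Differential expression against the stress score
#'
#' Per-feature linear model (intercept + lsi_score + age + batch) with
#' empirical-Bayes variance moderation, identical to the methylation arm; a
#' feature is called when its moderated p-value is below `threshold`
#' (raw p, no multiple-testing correction, matching the analysis design).
#'
#' @param normalized normalized features x samples matrix from
#'   [normalize_counts()]
#' @param samples sample sheet
#' @param level "gene" or "isoform" (recorded in the output)
#' @param threshold call threshold on p (default 0.05)
#' @param prior_df optional moderation override
#' @return data.frame of class `de_result`: feature_id, level, coef,
#'   moderated_t, p, called
#' @export
fit_de <- function(normalized, samples, level = c("gene", "isoform"),
                   threshold = 0.05, prior_df = NULL) {
  level <- match.arg(level)
  st <- fit_locus_models(normalized, samples)
  st <- moderate_variances(st, prior_df = prior_df)
  out <- data.frame(feature_id = st$id, level = level, coef = st$coef,
                    moderated_t = st$moderated_t, p = st$p,
                    called = !is.na(st$p) & st$p < threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Unique differentially expressed genes across levels
#'
#' The union of genes called at the gene level and parent genes of called
#' isoforms; invariant to duplicated isoform rows.
#'
#' @param gene_res gene-level `de_result` (or NULL)
#' @param isoform_res isoform-level `de_result` (or NULL)
#' @param isoform_map data.frame (isoform_id, gene_id)
#' @return character vector of unique DE genes
#' @export
unique_de_genes <- function(gene_res = NULL, isoform_res = NULL,
                            isoform_map = NULL) {
  genes <- character(0)
  if (!is.null(gene_res)) {
    genes <- gene_res$feature_id[gene_res$called]
  }
  if (!is.null(isoform_res) && any(isoform_res$called)) {
    if (is.null(isoform_map)) {
      stop_value("isoform_map required when isoform results are supplied")
    }
    iso <- unique(isoform_res$feature_id[isoform_res$called])
    parents <- isoform_map$gene_id[match(iso, isoform_map$isoform_id)]
    if (anyNA(parents)) stop_value("isoform(s) missing from isoform_map")
    genes <- c(genes, parents)
  }
  sort(unique(genes))
}

#' Run the expression arm end to end
#'
#' Normalizes the gene and isoform count matrices, fits both DE models and
#' derives the unique DE gene set.
#'
#' @param gene_counts,isoform_counts count matrices
#' @param isoform_map data.frame (isoform_id, gene_id)
#' @param samples sample sheet
#' @param threshold p-value call threshold (default 0.05)
#' @return list of class `expression_result`: gene, isoform (de_result
#'   data.frames), de_genes (character)
#' @export
run_expression_de <- function(gene_counts, isoform_counts = NULL,
                              isoform_map = NULL, samples,
                              threshold = 0.05) {
  gene_res <- fit_de(normalize_counts(gene_counts), samples, "gene",
                     threshold = threshold)
  iso_res <- NULL
  if (!is.null(isoform_counts)) {
    iso_res <- fit_de(normalize_counts(isoform_counts), samples, "isoform",
                      threshold = threshold)
  }
  structure(list(gene = gene_res, isoform = iso_res,
                 de_genes = unique_de_genes(gene_res, iso_res, isoform_map)),
            class = "expression_result")
}
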