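# Probe-level QC filtering and beta -> M-value conversion.

#' Filter probes by SNP/cross-reactive flags and detection failures
#'
#' A probe is removed if it is SNP-flagged, cross-reactive-flagged, or has
#' more than `max_failed_samples` samples with detection p-value above
#' `detection_threshold`. A probe failing several rules is counted once per
#' rule in the report but removed once. Retained probe order is preserved.
#'
#' @param beta probes x samples beta matrix (rownames = probe ids)
#' @param detection_p matrix of detection p-values, same shape
#' @param manifest `probe_manifest` covering all probes in `beta`
#' @param max_failed_samples maximum tolerated failed samples (default 0,
#'   the strictest reading of standard 450k QC)
#' @param detection_threshold detection p-value threshold (default 0.01)
#' @return list: `beta`, `detection_p` (filtered), `manifest` (filtered),
#'   `report` data.frame (reason, n_flagged) plus attribute
#'   `n_removed`/`n_retained`
#' @export
filter_probes <- function(beta, detection_p, manifest,
                          max_failed_samples = 0, detection_threshold = 0.01) {
  if (detection_threshold <= 0 || detection_threshold >= 1) {
    stop_config("detection_threshold must be in (0, 1)")
  }
  if (max_failed_samples < 0) stop_config("max_failed_samples must be >= 0")
  if (!identical(dim(beta), dim(detection_p))) {
    stop_value("beta and detection_p shapes differ")
  }
  ids <- rownames(beta)
  mi <- match(ids, manifest$probe_id)
  if (anyNA(mi)) {
    stop_pipeline("probe(s) missing from manifest: %s",
                  paste(head(ids[is.na(mi)], 5), collapse = ", "))
  }
  man <- manifest[mi, , drop = FALSE]
  snp <- man$snp_flag
  cross <- man$crossreactive_flag
  n_failed <- rowSums(detection_p > detection_threshold)
  det <- n_failed > max_failed_samples
  drop <- snp | cross | det
  report <- data.frame(
    reason = c("snp_flag", "crossreactive_flag", "detection_failure"),
    n_flagged = c(sum(snp), sum(cross), sum(det)),
    stringsAsFactors = FALSE)
  if (all(drop)) {
    stop_pipeline("no probes remain after filtering", data = report)
  }
  keep <- !drop
  out <- list(beta = beta[keep, , drop = FALSE],
              detection_p = detection_p[keep, , drop = FALSE],
              manifest = man[keep, , drop = FALSE],
              report = report)
  attr(out$report, "n_removed") <- sum(drop)
  attr(out$report, "n_retained") <- sum(keep)
  out
}

#' Convert beta values to M-values
#'
#' `m = log2(b' / (1 - b'))` with `b' = min(max(beta, epsilon), 1 - epsilon)`.
#' Clamping (rather than dropping extreme betas) keeps the matrix shape
#' stable; the transform is strictly monotone on the unclamped range.
#'
#' @param beta beta matrix (or vector) in \[0, 1\]
#' @param epsilon clamp in (0, 0.5), default 1e-6
#' @return M-value matrix of the same shape, all entries finite
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (epsilon <= 0 || epsilon >= 0.5) stop_config("epsilon must be in (0, 0.5)")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dimnames(out) <- dimnames(beta)
  out
}
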