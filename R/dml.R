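# Direction classification, mQTL proximity flagging and the assembled
# differential-methylation caller.

#' Classify DML direction from the beta–score Pearson correlation
#'
#' Direction is positive when the Pearson correlation between the probe's
#' beta values and the LSI score is > 0, negative when < 0. A correlation
#' of exactly 0 is assigned positive with a warning; a zero-variance beta
#' row falls back to the sign of the regression coefficient (warning).
#'
#' @param beta probes x samples beta matrix
#' @param samples sample sheet with lsi_score
#' @param probe_ids probes to classify (must be rownames of `beta`)
#' @param coef optional named coefficient vector used as fallback for
#'   zero-variance rows
#' @return data.frame: probe_id, pearson_r, direction
#' @export
classify_direction <- function(beta, samples, probe_ids = rownames(beta),
                               coef = NULL) {
  idx <- match(probe_ids, rownames(beta))
  if (anyNA(idx)) stop_value("probe id(s) absent from beta matrix")
  lsi <- samples$lsi_score
  r <- vapply(idx, function(i) {
    suppressWarnings(cor(beta[i, ], lsi))
  }, numeric(1))
  direction <- ifelse(r > 0, "positive", "negative")
  if (any(is.na(r))) {
    warning(sprintf("%d probe(s) with zero beta variance; direction taken from coefficient sign", sum(is.na(r))), call. = FALSE)
    na_i <- which(is.na(r))
    fb <- if (!is.null(coef)) coef[probe_ids[na_i]] else rep(0, length(na_i))
    direction[na_i] <- ifelse(fb < 0, "negative", "positive")
  }
  if (any(!is.na(r) & r == 0)) {
    warning("probe(s) with exactly zero correlation assigned positive",
            call. = FALSE)
    direction[!is.na(r) & r == 0] <- "positive"
  }
  data.frame(probe_id = probe_ids, pearson_r = r, direction = direction,
             stringsAsFactors = FALSE)
}

#' Flag DMLs lying near a known SNP (mQTL proximity)
#'
#' A probe is near an mQTL when a SNP on the same chromosome lies within
#' `max_distance` bp (boundary inclusive). Proximity to a reported SNP
#' suggests the methylation difference may be genetically rather than
#' environmentally driven.
#'
#' @param calls data.frame with probe_id, chrom, pos
#' @param snp_table data.frame with chrom, pos (malformed rows are skipped
#'   with a warning)
#' @param max_distance distance threshold in bp (default 200)
#' @return `calls` with logical column `mqtl_near`; attribute `summary`
#'   holds the near/far counts
#' @export
mqtl_proximity <- function(calls, snp_table, max_distance = 200) {
  if (max_distance < 0) stop_config("max_distance must be >= 0")
  posn <- suppressWarnings(as.numeric(snp_table$pos))
  bad <- is.na(snp_table$chrom) | is.na(posn) | (!is.na(posn) & posn < 1)
  snp_table$pos <- posn
  if (any(bad)) {
    warning(sprintf("skipping %d malformed SNP record(s)", sum(bad)),
            call. = FALSE)
    snp_table <- snp_table[!bad, , drop = FALSE]
  }
  near <- logical(nrow(calls))
  for (cn in unique(calls$chrom)) {
    ci <- which(calls$chrom == cn)
    sp <- sort(snp_table$pos[snp_table$chrom == cn])
    if (!length(sp)) next
    # distance to the nearest SNP via findInterval on the sorted positions
    pos <- calls$pos[ci]
    k <- findInterval(pos, sp)
    d_lo <- ifelse(k >= 1, pos - sp[pmax(k, 1)], Inf)
    d_hi <- ifelse(k < length(sp), sp[pmin(k + 1, length(sp))] - pos, Inf)
    near[ci] <- pmin(d_lo, d_hi) <= max_distance
  }
  calls$mqtl_near <- near
  attr(calls, "summary") <- c(near = sum(near), far = sum(!near))
  calls
}

#' Call differentially methylated loci end to end
#'
#' Runs the full methylation arm: optional probe filtering, beta-to-M
#' conversion, per-probe linear models, empirical-Bayes moderation, signed
#' z-scores, HMM LIS fitting per chromosome, aLIS adjustment and calling,
#' direction classification and (optionally) mQTL proximity flagging.
#'
#' @param beta,detection_p probes x samples matrices
#' @param manifest `probe_manifest`
#' @param samples sample sheet
#' @param snps optional SNP table for mQTL flagging
#' @param alpha aLIS call threshold (default 0.05)
#' @param mqtl_distance mQTL proximity distance in bp (default 200)
#' @param hmm_restarts random EM restarts (default 3)
#' @param seed integer seed (HMM restarts)
#' @param filter apply [filter_probes()] first (default TRUE)
#' @param prior_df optional moderation override, see [moderate_variances()]
#' @return list of class `dml_result`: `calls` (probe_id, chrom, pos, lis,
#'   alis, called, pearson_r, direction, mqtl_near), `stats` (locus-level
#'   statistics incl. z), `hmm` (fitted model), `filter_report`
#' @export
call_dmls <- function(beta, detection_p, manifest, samples, snps = NULL,
                      alpha = 0.05, mqtl_distance = 200, hmm_restarts = 3,
                      seed = 1, filter = TRUE, prior_df = NULL) {
  filter_report <- NULL
  if (filter) {
    f <- filter_probes(beta, detection_p, manifest)
    beta <- f$beta; manifest <- f$manifest
    filter_report <- f$report
  } else {
    manifest <- manifest[match(rownames(beta), manifest$probe_id), ,
                         drop = FALSE]
  }
  m <- beta_to_m(beta)
  stats <- fit_locus_models(m, samples)
  stats <- moderate_variances(stats, prior_df = prior_df)
  stats$chrom <- manifest$chrom
  stats$pos <- manifest$pos
  usable <- is.finite(stats$p)
  if (!all(usable)) {
    warning(sprintf("%d probe(s) excluded from HMM stage (undefined p)",
                    sum(!usable)), call. = FALSE)
  }
  st <- stats[usable, , drop = FALSE]
  ord <- order(st$chrom, st$pos)
  st <- st[ord, , drop = FALSE]
  st$z <- p_to_z(st$p, st$coef)
  hmm <- fit_hmm_lis(st$z, st$chrom, restarts = hmm_restarts, seed = seed)
  adj <- adjust_lis(hmm$lis, alpha = alpha)
  calls <- data.frame(probe_id = st$id, chrom = st$chrom, pos = st$pos,
                      z = st$z, lis = adj$lis, alis = adj$alis,
                      called = adj$called, stringsAsFactors = FALSE)
  calls$pearson_r <- NA_real_
  calls$direction <- NA_character_
  if (any(calls$called)) {
    dir <- classify_direction(beta, samples, calls$probe_id[calls$called],
                              coef = setNames(st$coef, st$id))
    calls$pearson_r[calls$called] <- dir$pearson_r
    calls$direction[calls$called] <- dir$direction
  }
  if (!is.null(snps)) {
    calls <- mqtl_proximity(calls, snps, max_distance = mqtl_distance)
    # near/far summary reported over the called DML set
    attr(calls, "summary") <- c(near = sum(calls$mqtl_near & calls$called),
                                far = sum(!calls$mqtl_near & calls$called))
  }
  structure(list(calls = calls, stats = st, hmm = hmm,
                 filter_report = filter_report), class = "dml_result")
}
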