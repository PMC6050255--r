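# Permutation enrichment of DMLs over genic structures, CpG-island
# relations and chromosomes, run separately for all / positive / negative
# call subsets.

split_structures <- function(x) strsplit(x, ";", fixed = TRUE)

#' Tally DML annotations per category
#'
#' For genic structures a probe contributes one tally per annotation it
#' carries (a CpG may sit, e.g., in one gene's body and another's
#' promoter); for island relation and chromosome each probe contributes
#' exactly one tally.
#'
#' @param dml_probes probe ids of the called DMLs
#' @param manifest `probe_manifest`
#' @param category_type one of "structure", "island_relation", "chromosome"
#' @return named integer vector of actual counts
#' @export
tally_annotations <- function(dml_probes, manifest,
                              category_type = c("structure",
                                                "island_relation",
                                                "chromosome")) {
  category_type <- match.arg(category_type)
  idx <- match(dml_probes, manifest$probe_id)
  if (anyNA(idx)) {
    stop_pipeline("probe(s) missing from manifest: %s",
                  paste(head(dml_probes[is.na(idx)], 5), collapse = ", "))
  }
  ann <- switch(category_type,
    structure = unlist(split_structures(manifest$structures[idx])),
    island_relation = manifest$island_relation[idx],
    chromosome = manifest$chrom[idx])
  if (is.null(ann) || length(ann) == 0) {
    return(setNames(integer(0), character(0)))
  }
  tab <- table(ann)
  setNames(as.integer(tab), names(tab))
}

# Pooled annotation multiset over the whole tested universe.
universe_annotations <- function(manifest, category_type) {
  switch(category_type,
    structure = unlist(split_structures(manifest$structures)),
    island_relation = manifest$island_relation,
    chromosome = manifest$chrom)
}

#' Permutation test for structure / island-relation enrichment
#'
#' Each replicate samples `n_draws` annotations without replacement from
#' the pooled annotation multiset of all tested probes and tallies them per
#' category. `p_enrich` is the fraction of replicates whose permuted count
#' reaches the actual count (non-strict `>=` by default, so a degenerate
#' single-category universe yields p = 1); `p_deplete` uses `<=`.
#'
#' @param universe character vector: pooled annotation multiset of all
#'   tested probes
#' @param n_draws total annotation count of the DML set
#' @param actual_counts named integer vector from [tally_annotations()]
#' @param reps permutation replicates (>= 1000; default 10000)
#' @param seed integer RNG seed (fixes the whole permutation stream)
#' @param strict use strict inequalities, reproducing the tallying rule
#'   that counts only replicates exceeding the actual number
#' @param smooth add-one smoothing: (tally + 1) / (reps + 1)
#' @return data.frame of class `enrichment_result`: category, actual,
#'   p_enrich, p_deplete, reps
#' @export
permute_structures <- function(universe, n_draws, actual_counts,
                               reps = 10000, seed = 1, strict = FALSE,
                               smooth = FALSE) {
  if (reps < 1000) stop_config("reps must be >= 1000")
  if (n_draws > length(universe)) {
    stop_value("n_draws (%d) exceeds universe size (%d)", n_draws,
               length(universe))
  }
  cats <- sort(unique(c(names(actual_counts), unique(universe))))
  code <- match(universe, cats)
  nc <- length(cats)
  actual <- setNames(integer(nc), cats)
  actual[names(actual_counts)] <- actual_counts
  with_seed(seed, {
    ge <- le <- integer(nc)
    for (r in seq_len(reps)) {
      perm <- tabulate(code[sample.int(length(universe), n_draws)], nc)
      if (strict) {
        ge <- ge + (perm > actual)
        le <- le + (perm < actual)
      } else {
        ge <- ge + (perm >= actual)
        le <- le + (perm <= actual)
      }
    }
    denom <- if (smooth) reps + 1 else reps
    num_add <- if (smooth) 1 else 0
    out <- data.frame(category = cats, actual = as.integer(actual),
                      p_enrich = (ge + num_add) / denom,
                      p_deplete = (le + num_add) / denom,
                      reps = reps, stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    out
  })
}

#' Permutation test for chromosome-level enrichment
#'
#' Each replicate draws `n_dml` probes without replacement from the tested
#' universe and computes per-chromosome proportions. In the default
#' family-wise mode the actual proportion of a chromosome is compared with
#' the maximum permuted proportion over any chromosome (and the minimum
#' for depletion) — the multiple-testing-corrected comparison across the
#' autosomes and X; "marginal" compares each chromosome only with itself.
#'
#' @param universe_chrom chromosome label of every tested probe
#' @param n_dml number of DMLs
#' @param actual_proportions named numeric vector summing to 1
#' @param reps permutation replicates (>= 1000)
#' @param seed integer RNG seed
#' @param mode "familywise" or "marginal"
#' @param strict strict inequalities as in [permute_structures()]
#' @return `enrichment_result` data.frame with proportions in `actual`
#' @export
permute_chromosomes <- function(universe_chrom, n_dml, actual_proportions,
                                reps = 10000, seed = 1,
                                mode = c("familywise", "marginal"),
                                strict = FALSE) {
  mode <- match.arg(mode)
  if (reps < 1000) stop_config("reps must be >= 1000")
  cats <- sort(unique(universe_chrom))
  missing_cat <- setdiff(names(actual_proportions), cats)
  if (length(missing_cat)) {
    stop_value("chromosome(s) absent from universe: %s",
               paste(missing_cat, collapse = ", "))
  }
  if (abs(sum(actual_proportions) - 1) > 1e-8) {
    stop_value("actual proportions must sum to 1")
  }
  nc <- length(cats)
  actual <- setNames(numeric(nc), cats)
  actual[names(actual_proportions)] <- actual_proportions
  code <- match(universe_chrom, cats)
  cmp_ge <- if (strict) `>` else `>=`
  cmp_le <- if (strict) `<` else `<=`
  with_seed(seed, {
    ge <- le <- numeric(nc)
    for (r in seq_len(reps)) {
      prop <- tabulate(code[sample.int(length(code), n_dml)], nc) / n_dml
      if (mode == "familywise") {
        ge <- ge + cmp_ge(max(prop), actual)
        le <- le + cmp_le(min(prop), actual)
      } else {
        ge <- ge + cmp_ge(prop, actual)
        le <- le + cmp_le(prop, actual)
      }
    }
    out <- data.frame(category = cats, actual = actual,
                      p_enrich = ge / reps, p_deplete = le / reps,
                      reps = reps, stringsAsFactors = FALSE, row.names = NULL)
    class(out) <- c("enrichment_result", "data.frame")
    out
  })
}

#' Run the full enrichment suite
#'
#' All three category types (genic structure, CpG-island relation,
#' chromosome) for each DML subset (all, positive, negative). Subsets with
#' zero DMLs are skipped with a warning.
#'
#' @param calls DML call data.frame (probe_id, called, direction)
#' @param manifest `probe_manifest` of all tested probes
#' @param reps permutation replicates per block (default 10000)
#' @param seed integer RNG seed
#' @param strict,chromosome_mode passed through to the block tests
#' @return one data.frame with columns subset, category_type, category,
#'   actual, p_enrich, p_deplete, reps
#' @export
run_enrichment_suite <- function(calls, manifest, reps = 10000, seed = 1,
                                 strict = FALSE,
                                 chromosome_mode = "familywise") {
  called <- calls[calls$called, , drop = FALSE]
  subsets <- list(all = called$probe_id,
                  positive = called$probe_id[!is.na(called$direction) &
                                               called$direction == "positive"],
                  negative = called$probe_id[!is.na(called$direction) &
                                               called$direction == "negative"])
  blocks <- list()
  seed_i <- 0L
  for (sub in names(subsets)) {
    ids <- subsets[[sub]]
    if (length(ids) == 0) {
      warning(sprintf("DML subset '%s' is empty; block skipped", sub),
              call. = FALSE)
      next
    }
    for (ct in c("structure", "island_relation", "chromosome")) {
      seed_i <- seed_i + 1L
      actual <- tally_annotations(ids, manifest, ct)
      if (ct == "chromosome") {
        res <- permute_chromosomes(manifest$chrom, length(ids),
                                   actual / sum(actual), reps = reps,
                                   seed = seed + seed_i,
                                   mode = chromosome_mode, strict = strict)
      } else {
        uni <- universe_annotations(manifest, ct)
        res <- permute_structures(uni, sum(actual), actual, reps = reps,
                                  seed = seed + seed_i, strict = strict)
      }
      res$subset <- sub
      res$category_type <- ct
      blocks[[length(blocks) + 1L]] <- res
    }
  }
  out <- do.call(rbind, blocks)
  out[, c("subset", "category_type", "category", "actual", "p_enrich",
          "p_deplete", "reps")]
}
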