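# Permutation enrichment: tallies, hypergeometric agreement, chromosome
# family-wise comparison, suite assembly.

test_that("structure tallies honor the multiplicity rule", {
  man <- make_manifest(3, structures = c("Body", "Body;TSS200", "Intergenic"))
  tal <- tally_annotations(man$probe_id, man, "structure")
  expect_equal(unname(tal["Body"]), 2)
  expect_equal(unname(tal["TSS200"]), 1)
  expect_equal(sum(tal), 4)   # total annotation multiplicity

  expect_equal(length(tally_annotations(character(0), man, "structure")), 0)
  expect_error(tally_annotations("cgZ", man, "structure"),
               class = "stressmeth_pipeline_error")

  # island relation / chromosome: one tally per probe
  expect_equal(sum(tally_annotations(man$probe_id, man, "island_relation")),
               3)
  expect_equal(sum(tally_annotations(man$probe_id, man, "chromosome")), 3)

  # brute-force recount on a synthetic call set
  st <- tiny_study(seed = 2)
  ids <- st$probes$probe_id[1:50]
  tal <- tally_annotations(ids, st$probes, "structure")
  recount <- length(unlist(strsplit(
    st$probes$structures[match(ids, st$probes$probe_id)], ";")))
  expect_equal(sum(tal), recount)
})

test_that("permutation p matches the hypergeometric tail", {
  universe <- rep(c("Island", "OpenSea"), c(40, 160))
  for (actual in c(4, 6, 8)) {
    res <- permute_structures(universe, 20,
                              c(Island = actual), reps = 4000, seed = 11)
    p_perm <- res$p_enrich[res$category == "Island"]
    p_hyper <- phyper(actual - 1, 40, 160, 20, lower.tail = FALSE)
    se <- sqrt(p_hyper * (1 - p_hyper) / 4000)
    expect_lt(abs(p_perm - p_hyper), max(3 * se, 0.02))
    # both tails include ties
    p_dep <- res$p_deplete[res$category == "Island"]
    expect_gte(p_perm + p_dep, 1)
  }
  # determinism
  r1 <- permute_structures(universe, 20, c(Island = 6), reps = 1000,
                           seed = 11)
  r2 <- permute_structures(universe, 20, c(Island = 6), reps = 1000,
                           seed = 11)
  expect_identical(r1, r2)
})

test_that("degenerate one-category universe gives p = 1 both ways", {
  res <- permute_structures(rep("Body", 100), 10, c(Body = 10),
                            reps = 1000, seed = 1)
  expect_equal(res$p_enrich, 1)
  expect_equal(res$p_deplete, 1)
  # strict mode turns the all-equal case into p = 0
  res_s <- permute_structures(rep("Body", 100), 10, c(Body = 10),
                              reps = 1000, seed = 1, strict = TRUE)
  expect_equal(res_s$p_enrich, 0)
  expect_error(permute_structures(rep("Body", 5), 10, c(Body = 3),
                                  reps = 1000), "exceeds universe",
               class = "stressmeth_value_error")
})

test_that("chromosome family-wise p matches exhaustive enumeration", {
  universe <- rep(c("chr1", "chr2"), each = 100)
  res <- permute_chromosomes(universe, 10, c(chr1 = 0.9, chr2 = 0.1),
                             reps = 5000, seed = 7, mode = "familywise")
  # exact enumeration over the 11 possible splits: X ~ Hypergeom(100,100,10)
  px <- dhyper(0:10, 100, 100, 10)
  p_exact_fw_chr1 <- sum(px[pmax(0:10, 10 - (0:10)) / 10 >= 0.9])
  got <- res$p_enrich[res$category == "chr1"]
  se <- sqrt(p_exact_fw_chr1 * (1 - p_exact_fw_chr1) / 5000)
  expect_lt(abs(got - p_exact_fw_chr1), max(3 * se, 0.01))

  res_m <- permute_chromosomes(universe, 10, c(chr1 = 0.9, chr2 = 0.1),
                               reps = 5000, seed = 7, mode = "marginal")
  p_exact_m <- sum(px[(0:10) / 10 >= 0.9])
  got_m <- res_m$p_enrich[res_m$category == "chr1"]
  expect_lt(abs(got_m - p_exact_m), max(3 * sqrt(p_exact_m * (1 - p_exact_m) / 5000), 0.01))

  # single-chromosome universe: every proportion is 1
  r1 <- permute_chromosomes(rep("chr1", 50), 5, c(chr1 = 1), reps = 1000,
                            seed = 1)
  expect_equal(r1$p_enrich, 1)
  expect_error(permute_chromosomes(universe, 5, c(chr3 = 1), reps = 1000),
               class = "stressmeth_value_error")
})

test_that("the suite runs all blocks and positive+negative partition all", {
  st <- tiny_study(seed = 4)
  n <- 60
  calls <- data.frame(probe_id = st$probes$probe_id[1:n],
                      called = TRUE,
                      direction = rep(c("positive", "negative"),
                                      c(40, 20)))
  suite <- run_enrichment_suite(calls, st$probes, reps = 1000, seed = 5)
  expect_setequal(unique(suite$subset), c("all", "positive", "negative"))
  expect_setequal(unique(suite$category_type),
                  c("structure", "island_relation", "chromosome"))
  expect_true(all(suite$p_enrich >= 0 & suite$p_enrich <= 1))
  expect_true(all(suite$p_deplete >= 0 & suite$p_deplete <= 1))
  # island relation is single-annotation: all = positive + negative
  for (cat in unique(suite$category[suite$category_type == "island_relation"])) {
    sel <- suite$category_type == "island_relation" & suite$category == cat
    a <- suite$actual[sel & suite$subset == "all"]
    p <- suite$actual[sel & suite$subset == "positive"]
    n_ <- suite$actual[sel & suite$subset == "negative"]
    if (length(a) && length(p) && length(n_)) expect_equal(a, p + n_)
  }
  # an empty subset is skipped with a warning
  calls$direction <- "positive"
  expect_warning(s2 <- run_enrichment_suite(calls, st$probes, reps = 1000,
                                            seed = 5),
                 "negative")
  expect_false("negative" %in% s2$subset)
})

test_that("enrichment p-values are calibrated under random DML draws", {
  # spread-out count distribution so the discrete null is close to uniform
  withr::with_seed(77, {
    universe <- rep(c("Body", "Other"), c(1000, 1000))
    pvals <- numeric(100)
    for (i in 1:100) {
      dml_ann <- sample(universe, 200)
      res <- permute_structures(universe, 200,
                                c(Body = sum(dml_ann == "Body")),
                                reps = 1000, seed = 1000 + i)
      pvals[i] <- res$p_enrich[res$category == "Body"]
    }
    ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
    expect_gt(ks$p.value, 0.01)
  })
})
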