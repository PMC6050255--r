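# Nearest-gene mapping, gene-set aggregation, Venn overlap, chi-square
# list enrichment and the consolidated report.

test_that("nearest-gene assignment: containment, ties, brute-force oracle", {
  genome <- generate_genome(2, 10, seed = 5)
  g <- genome$genes[1, ]
  inside <- data.frame(probe_id = "p1", chrom = g$chrom,
                       pos = g$start + 10)
  expect_equal(map_nearest_gene(inside, genome)$gene_id, g$gene_id)

  # exact equidistance -> alphabetically first gene id
  tie_genome <- list(
    chromosomes = data.frame(name = "chr1", length = 100000L),
    genes = data.frame(gene_id = c("GB", "GA"), chrom = "chr1",
                       strand = "+", start = c(1000L, 3000L),
                       end = c(1400L, 3400L)),
    islands = data.frame(chrom = character(), start = integer(),
                         end = integer()))
  class(tie_genome) <- "genome_annotation"
  mid <- data.frame(probe_id = "p1", chrom = "chr1", pos = 2200L)
  expect_equal(map_nearest_gene(mid, tie_genome)$gene_id, "GA")

  # geneless chromosome -> NA with warning
  orphan <- data.frame(probe_id = "p2", chrom = "chrU", pos = 5L)
  expect_warning(res <- map_nearest_gene(orphan, genome), "without genes")
  expect_true(is.na(res$gene_id))

  # brute-force all-pairs oracle on random probes
  withr::with_seed(6, {
    probes <- data.frame(
      probe_id = paste0("p", 1:100),
      chrom = sample(genome$chromosomes$name, 100, replace = TRUE),
      pos = sample.int(min(genome$chromosomes$length), 100))
    got <- map_nearest_gene(probes, genome)
    for (i in 1:100) {
      gg <- genome$genes[genome$genes$chrom == probes$chrom[i], ]
      d <- ifelse(probes$pos[i] >= gg$start & probes$pos[i] <= gg$end, 0,
                  pmin(abs(probes$pos[i] - gg$start),
                       abs(probes$pos[i] - gg$end)))
      best <- sort(gg$gene_id[d == min(d)])[1]
      expect_identical(got$gene_id[i], best)
    }
  })
})

test_that("gene aggregation reproduces the dual-membership arithmetic", {
  # 84 positive genes, 50 negative genes, 12 in both -> 122 total
  pos_genes <- sprintf("g%03d", 1:84)
  neg_genes <- sprintf("g%03d", 73:122)
  assign <- data.frame(
    probe_id = paste0("d", 1:134),
    gene_id = c(pos_genes, neg_genes),
    direction = rep(c("positive", "negative"), c(84, 50)))
  gs <- aggregate_genes(assign)
  expect_equal(length(gs$positive), 84)
  expect_equal(length(gs$negative), 50)
  expect_equal(length(gs$both), 12)
  expect_equal(length(gs$union), 122)

  # disjoint sets
  d2 <- data.frame(probe_id = paste0("d", 1:7),
                   gene_id = paste0("x", 1:7),
                   direction = rep(c("positive", "negative"), c(3, 4)))
  gs2 <- aggregate_genes(d2)
  expect_equal(length(gs2$union), 7)
  expect_equal(length(gs2$both), 0)

  # one gene with one positive and one negative DML
  d3 <- data.frame(probe_id = c("a", "b"), gene_id = "g1",
                   direction = c("positive", "negative"))
  gs3 <- aggregate_genes(d3)
  expect_equal(length(gs3$union), 1)
  expect_equal(gs3$both, "g1")
  expect_equal(unname(gs3$dml_per_gene["g1"]), 2)
})

test_that("Venn regions partition the union", {
  u <- paste0("g", 1:100)
  s <- paste0("g", 1:5)
  id3 <- overlap_sets(s, s, s, u)
  expect_equal(unname(id3$regions["all_three"]), 5)
  expect_equal(sum(id3$regions), 5)

  dis <- overlap_sets(paste0("g", 1:3), paste0("g", 4:6), paste0("g", 7:9), u)
  expect_equal(unname(dis$regions[c("meth_only", "expr_only",
                                    "curated_only")]), c(3, 3, 3))
  expect_equal(sum(dis$regions), 9)

  withr::with_seed(8, {
    universe <- paste0("g", 1:2000)
    a <- sample(universe, 122); b <- sample(universe, 500)
    c_ <- sample(universe, 800)
    ov <- overlap_sets(a, b, c_, universe)
    expect_equal(sum(ov$regions), length(unique(c(a, b, c_))))
  })
  expect_error(overlap_sets(s, s, s, character(0)),
               class = "stressmeth_value_error")
})

test_that("Yates chi-square matches the textbook formula and chisq.test", {
  # proportional table: continuity-corrected statistic is 0, p = 1
  u <- paste0("g", 1:1000)
  gs <- u[1:100]; cl <- u[c(1:10, 101:190)]  # 10% in both strata
  res <- chisq_list_enrichment(gs, cl, u)
  expect_equal(res$statistic, 0)
  expect_gte(res$p.value, 0.3)

  # random 2x2 tables vs closed form and stats::chisq.test
  withr::with_seed(19, {
    for (i in 1:100) {
      tb <- matrix(rpois(4, 40) + 1, 2, 2)
      u2 <- paste0("x", seq_len(sum(tb)))
      set_genes <- u2[1:(tb[1, 1] + tb[1, 2])]
      list_genes <- c(u2[1:tb[1, 1]],
                      u2[(tb[1, 1] + tb[1, 2] + 1):(tb[1, 1] + tb[1, 2] + tb[2, 1])])
      got <- chisq_list_enrichment(set_genes, list_genes, u2)
      E <- outer(rowSums(got$table), colSums(got$table)) / sum(got$table)
      stat_oracle <- sum(pmax(abs(got$table - E) - 0.5, 0)^2 / E)
      expect_equal(got$statistic, stat_oracle, tolerance = 1e-8)
      ref <- suppressWarnings(stats::chisq.test(got$table, correct = TRUE))
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-8)
      expect_equal(got$p.value, ref$p.value, tolerance = 1e-8)
    }
  })
  expect_error(chisq_list_enrichment(u, cl, u),
               class = "stressmeth_value_error")  # zero out-of-set margin
})

test_that("the consolidated report reproduces the headline arithmetic", {
  universe <- sprintf("g%05d", 1:23407)
  pos_genes <- universe[1:84]
  neg_genes <- universe[73:122]
  assign <- data.frame(probe_id = paste0("d", 1:550),
                       gene_id = c(pos_genes, rep(pos_genes[1], 273),
                                   neg_genes, rep(neg_genes[1], 143)),
                       direction = rep(c("positive", "negative"),
                                       c(357, 193)))
  gs <- aggregate_genes(assign)
  de_genes <- universe[1000:2404]                 # 1,405 DE genes
  curated <- c(de_genes[1:349], universe[20000:22000])
  mqtl <- c(near = 94, far = 456)
  rep_ <- integrate_report(gs, de_genes, curated, universe,
                           mqtl_summary = mqtl)
  expect_equal(unname(rep_$counts["n_meth_genes"]), 122)
  expect_equal(unname(rep_$counts["n_de_genes"]), 1405)
  expect_equal(unname(rep_$counts["n_de_on_list"]), 349)
  expect_equal(unname(rep_$counts["n_de_off_list"]), 1056)
  expect_equal(unname(rep_$counts["n_dml_mqtl_near"]), 94)
  expect_equal(unname(rep_$counts["n_dml_total"]), 550)
  expect_equal(sum(rep_$venn$regions), rep_$venn$n_union)

  # empty methylation-expression overlap still succeeds
  gs0 <- aggregate_genes(data.frame(probe_id = "d1", gene_id = universe[1],
                                    direction = "positive"))
  r0 <- integrate_report(gs0, universe[500:600], curated, universe)
  expect_equal(nrow(r0$overlap_genes), 0)
})
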