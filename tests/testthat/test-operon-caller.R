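test_that("cds_distance counts ordinal differences and flags other contigs", {
  a <- list(gene_id = "a", contig_id = "c1", ordinal = 5L)
  b <- list(gene_id = "b", contig_id = "c1", ordinal = 6L)
  f <- list(gene_id = "f", contig_id = "c1", ordinal = 16L)
  z <- list(gene_id = "z", contig_id = "c2", ordinal = 5L)
  expect_equal(cds_distance(a, b), 1L)
  expect_equal(cds_distance(b, list(gene_id = "k", contig_id = "c1", ordinal = 10L)), 4L)
  expect_equal(cds_distance(list(gene_id = "x", contig_id = "c1", ordinal = 10L), f), 6L)
  expect_true(is.na(cds_distance(a, z)))
  expect_error(cds_distance(a, a), "distinct")
})

test_that("the iac rule is strict at 7 CDS and the iad rule at adjacency", {
  g <- make_ruled_genome("rule1", 20)
  gid <- g$genes$gene_id

  call6 <- call_degrader(g, make_hits("rule1", c("iacA", "iacE"),
                                      gid[c(3, 9)], c(2, 8)))
  expect_equal(call6$degrader_type, "iac")
  expect_equal(call6$evidence$iac$distance, 6L)

  call7 <- call_degrader(g, make_hits("rule1", c("iacA", "iacE"),
                                      gid[c(3, 10)], c(2, 9)))
  expect_equal(call7$degrader_type, "none")

  adj <- call_degrader(g, make_hits("rule1", c("iadD", "iadE"),
                                    gid[c(5, 6)], c(4, 5)))
  expect_equal(adj$degrader_type, "iad")
  expect_equal(adj$evidence$iad$distance, 1L)

  gap2 <- call_degrader(g, make_hits("rule1", c("iadD", "iadE"),
                                     gid[c(5, 7)], c(4, 6)))
  expect_equal(gap2$degrader_type, "none")
})

test_that("markers on different contigs never satisfy a rule", {
  g <- make_genome(vapply(1:6, function(i) random_aa(40), character(1)),
                   genome_id = "ct1", contigs = c("c1", "c1", "c1", "c2", "c2", "c2"))
  hits <- make_hits("ct1", c("iacA", "iacE"),
                    g$genes$gene_id[c(1, 4)], c(0, 0),
                    contig_id = c("c1", "c2"))
  expect_equal(call_degrader(g, hits)$degrader_type, "none")
})

test_that("both rules satisfied gives type both, on any contigs", {
  g <- make_genome(vapply(1:8, function(i) random_aa(40), character(1)),
                   genome_id = "both1",
                   contigs = c(rep("c1", 4), rep("c2", 4)))
  gid <- g$genes$gene_id
  hits <- rbind(
    make_hits("both1", c("iacA", "iacE"), gid[c(1, 3)], c(0, 2), contig_id = "c1"),
    make_hits("both1", c("iadD", "iadE"), gid[c(5, 6)], c(0, 1), contig_id = "c2"))
  call <- call_degrader(g, hits)
  expect_equal(call$degrader_type, "both")
  expect_equal(call$evidence$iac$distance, 2L)
  expect_equal(call$evidence$iad$distance, 1L)
})

test_that("evidence picks the smallest distance, ties by smallest ordinal", {
  g <- make_ruled_genome("ev1", 20)
  gid <- g$genes$gene_id
  hits <- make_hits("ev1", c("iacA", "iacE", "iacA", "iacE"),
                    gid[c(1, 6, 10, 13)], c(0, 5, 9, 12))
  call <- call_degrader(g, hits)
  expect_equal(call$evidence$iac$distance, 3L)
  expect_equal(call$evidence$iac$gene_a, gid[10])
  # tie on distance: two pairs at distance 3; lower min ordinal wins
  hits2 <- make_hits("ev1", c("iacA", "iacE", "iacA", "iacE"),
                     gid[c(1, 4, 10, 13)], c(0, 3, 9, 12))
  call2 <- call_degrader(g, hits2)
  expect_equal(call2$evidence$iac$gene_a, gid[1])
})

test_that("widening the iac gap never flips a positive call negative", {
  g <- make_ruled_genome("monog", 20)
  gid <- g$genes$gene_id
  for (d in c(2L, 5L, 6L)) {
    hits <- make_hits("monog", c("iacA", "iacE"), gid[c(1, 1 + d)], c(0, d))
    for (gap in 7:12) {
      call <- call_degrader(g, hits, threshold_config(max_cds_gap_iac = gap))
      expect_equal(call$degrader_type, "iac")
    }
  }
})

test_that("the alternative intervening-CDS reading extends the window to 8", {
  g <- make_ruled_genome("alt1", 20)
  gid <- g$genes$gene_id
  hits <- make_hits("alt1", c("iacA", "iacE"), gid[c(1, 9)], c(0, 8))
  expect_equal(call_degrader(g, hits)$degrader_type, "none")
  cfg <- threshold_config(iac_gap_counts_intervening = TRUE)
  expect_equal(call_degrader(g, hits, cfg)$degrader_type, "iac")
})

test_that("an intact planted operon reconstructs as complete", {
  g <- generate_genome("arch1", n_decoys = 12, specs = plant_spec("iac", 90),
                       seed = 31)
  call <- scan_genome(g)
  expect_equal(call$degrader_type, "iac")
  expect_equal(length(call$clusters), 1L)
  arch <- call$clusters[[1]]
  expect_equal(arch$completeness_status, "complete")
  expect_equal(arch$n_template_genes_found, 10L)  # iacA-I plus regulator
  expect_equal(sum(vapply(arch$members, function(m) m$label == "unknown",
                          logical(1))), 0L)
})

test_that("deleting template genes yields a fragmented cluster", {
  keep <- setdiff(paste0("iac", c(LETTERS[1:9], "R")),
                  c("iacB", "iacC", "iacG", "iacH"))
  g <- generate_genome("arch2", n_decoys = 12,
                       specs = plant_spec("iac", 90, gene_subset = keep),
                       seed = 32)
  call <- scan_genome(g)
  expect_equal(call$degrader_type, "iac")
  expect_equal(call$clusters[[1]]$completeness_status, "fragmented")
})

test_that("an inserted decoy inside the cluster appears as unknown", {
  # iacA . iacB . iacE: anchors stay within the distance rule, the two
  # interleaved decoys are bridged by the gap allowance
  g <- generate_genome("arch3", n_decoys = 10,
                       specs = plant_spec("iac", 90,
                                          gene_subset = c("iacA", "iacB", "iacE"),
                                          inter_gene_gap = 1),
                       seed = 33)
  call <- scan_genome(g)
  expect_equal(call$degrader_type, "iac")
  expect_equal(length(call$clusters), 1L)
  arch <- call$clusters[[1]]
  labs <- vapply(arch$members, `[[`, character(1), "label")
  expect_equal(sum(labs == "unknown"), 2L)
  expect_equal(labs[labs != "unknown"], c("iacA", "iacB", "iacE"))
  expect_equal(arch$completeness_status, "fragmented")
})

test_that("cluster members always lie inside the reported span", {
  specs <- list(plant_spec("iad", 85),
                plant_spec("iac", 85),
                plant_spec("iad", 85, shuffle = TRUE),
                plant_spec("iac", 85, shuffle = TRUE))
  n_clusters <- 0L
  for (seed in 41:44) {
    g <- generate_genome(paste0("span", seed), n_decoys = 15,
                         specs = specs[[seed - 40]], seed = seed)
    call <- scan_genome(g)
    for (arch in call$clusters) {
      n_clusters <- n_clusters + 1L
      ords <- vapply(arch$members, `[[`, integer(1), "ordinal")
      expect_true(all(ords >= arch$span[1] & ords <= arch$span[2]))
      expect_false(is.unsorted(ords))
    }
  }
  expect_gte(n_clusters, 2L)  # the unshuffled plants always reconstruct
})

test_that("reconstruction fails loudly when anchors are inconsistent", {
  g <- generate_genome("bad1", n_decoys = 6, specs = plant_spec("iac", 90),
                       seed = 35)
  expect_error(
    reconstruct_cluster(g, synthetic_operon_templates(),
                        anchor = list(gene_a = "ghost_1", gene_b = "ghost_2",
                                      contig_id = "ctg_1"),
                        cluster_type = "iac"),
    "anchor genes missing")
})
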