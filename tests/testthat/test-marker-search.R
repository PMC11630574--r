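test_that("align_local handles the identity and half-template cases", {
  s <- random_aa(40)
  r <- align_local(s, s)
  expect_equal(r[["identity"]], 100)
  expect_equal(r[["coverage"]], 100)

  tpl <- paste0(paste(AA20_TEST[1:20], collapse = ""),
                paste(rev(AA20_TEST)[1:20], collapse = ""),
                paste(AA20_TEST[c(3:12, 15:19, 1, 2, 13, 14, 20)], collapse = ""),
                paste(AA20_TEST[20:1], collapse = ""),
                paste(AA20_TEST[c(5:20, 1:4)], collapse = ""))  # 100 residues
  expect_equal(nchar(tpl), 100)
  half <- substr(tpl, 1, 50)
  r2 <- align_local(half, tpl)
  expect_equal(r2[["identity"]], 100)
  expect_equal(r2[["coverage"]], 50)
})

test_that("align_local matches the brute-force oracle on a frozen example", {
  # oracle-derived values for the single-substitution pair
  r <- align_local("MKTAYVAKQR", "MKTAYIAKQR")
  o <- oracle_sw("MKTAYVAKQR", "MKTAYIAKQR")
  expect_equal(o$score, 48)
  expect_equal(o$identity, 90)
  expect_equal(r[["score"]], 48)
  expect_equal(r[["identity"]], 90)
  expect_equal(r[["coverage"]], 100)
})

test_that("align_local rejects empty or illegal sequences by name", {
  expect_error(align_local("", "MKT"), "non-empty")
  expect_error(align_local("MKT", ""), "non-empty")
  expect_error(align_local("MK1T", "MKT"), "1")
  expect_error(align_local("MKT", "MKBT"), "B")
})

test_that("identity is symmetric under a symmetric substitution matrix", {
  set.seed(71)
  for (i in 1:25) {
    a <- random_aa(sample(8:30, 1))
    b <- random_aa(sample(8:30, 1))
    ra <- align_local(a, b)
    rb <- align_local(b, a)
    expect_equal(ra[["identity"]], rb[["identity"]])
    expect_equal(ra[["score"]], rb[["score"]])
  }
})

test_that("strict gates reject boundary identities and coverages", {
  # crafted pair: optimal local alignment has exactly 50.0% identity
  q50 <- "CAHAWDGFRY"
  t50 <- "CRHQWGDFSY"
  r <- align_local(q50, t50)
  expect_equal(r[["identity"]], 50)
  expect_equal(r[["coverage"]], 100)
  o <- oracle_sw(q50, t50)
  expect_equal(o$identity, 50)

  g <- make_genome(c(q50, random_aa(60)), genome_id = "bnd1")
  hits <- screen_markers(g, c(m1 = t50), threshold_config())
  expect_equal(nrow(hits), 0L)  # identity == 50 fails the strict gate
  hits_low <- screen_markers(g, c(m1 = t50),
                             threshold_config(min_identity = 49.9,
                                              min_coverage = 90))
  expect_true(g$genes$gene_id[1] %in% hits_low$gene_id)

  # exact copy of 6 of 10 template residues: coverage exactly 60.0
  t10 <- "CHWFYDEKRN"
  q6 <- substr(t10, 3, 8)
  r2 <- align_local(q6, t10)
  expect_equal(r2[["identity"]], 100)
  expect_equal(r2[["coverage"]], 60)
  g2 <- make_genome(c(q6, random_aa(60)), genome_id = "bnd2")
  expect_equal(nrow(screen_markers(g2, c(m1 = t10), threshold_config())), 0L)
  expect_equal(nrow(screen_markers(g2, c(m1 = t10),
                                   threshold_config(min_coverage = 59.9))), 1L)
})

test_that("hits are tiered by identity and the best hit is flagged", {
  tpl <- synthetic_operon_templates()
  iacA <- unname(tpl["iacA|synthetic"])
  high <- mutate_protein(iacA, 85, seed = 5)
  mod <- mutate_protein(iacA, 55, seed = 6)
  g <- make_genome(c(mod, high, random_aa(200)), genome_id = "tier1")
  hits <- screen_markers(g, c(iacA = iacA))
  hits <- hits[order(hits$gene_id), ]
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$tier, c("moderate", "high"))
  expect_equal(hits$best, c(FALSE, TRUE))  # verbatim-closer copy scores higher
})

test_that("a verbatim marker copy self-hits at 100/100 in tier high", {
  tpl <- synthetic_operon_templates()
  for (mk in c("iacA", "iadE")) {
    seq <- unname(tpl[paste0(mk, "|synthetic")])
    g <- make_genome(c(random_aa(180), seq, random_aa(240)),
                     genome_id = paste0("self_", mk))
    hits <- screen_markers(g, setNames(seq, mk))
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$identity, 100)
    expect_equal(hits$coverage, 100)
    expect_equal(hits$tier, "high")
    expect_true(hits$best)
  }
})

test_that("lowering thresholds never removes hits; raising never adds", {
  tpl <- synthetic_operon_templates()
  iacE <- unname(tpl["iacE|synthetic"])
  prots <- c(mutate_protein(iacE, 55, seed = 21),
             mutate_protein(iacE, 65, seed = 22),
             mutate_protein(iacE, 75, seed = 23),
             vapply(1:3, function(i) random_aa(300), character(1)))
  g <- make_genome(prots, genome_id = "mono1")
  key <- function(h) paste(h$gene_id, h$marker_id)
  gates <- list(c(40, 50), c(50, 60), c(60, 70), c(70, 80))
  prev <- NULL
  for (gt in gates) {
    h <- screen_markers(g, c(iacE = iacE),
                        threshold_config(min_identity = gt[1],
                                         min_coverage = gt[2]))
    if (!is.null(prev)) expect_true(all(key(h) %in% key(prev)))
    prev <- h
  }
})

test_that("marker FASTA ids of the form marker|strain are parsed", {
  tpl <- synthetic_operon_templates()
  fa <- file.path(tempdir(), "markers.faa")
  writeLines(c(">iacA|strainX", unname(tpl["iacA|synthetic"]),
               ">iacE|strainX", unname(tpl["iacE|synthetic"])), fa)
  g <- make_genome(c(unname(tpl["iacA|synthetic"]), random_aa(100)),
                   genome_id = "fa1")
  hits <- screen_markers(g, fa)
  expect_equal(hits$marker_id, "iacA")
})

test_that("an empty genome yields an empty result, not an error", {
  g <- genome("empty", NULL)
  hits <- screen_markers(g, c(m = random_aa(50)))
  expect_s3_class(hits, "marker_hits")
  expect_equal(nrow(hits), 0L)
})
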