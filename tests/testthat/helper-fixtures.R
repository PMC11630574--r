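# Fixture builders used across test files. All fixtures are constructed
# in code; file-based ones are written to tempdirs at test time.

# A genome whose proteins are supplied directly; coordinates are laid out
# left to right per contig in the order given.
make_genome <- function(proteins, genome_id = "gfix",
                        contigs = rep("c1", length(proteins)), ...) {
  stopifnot(length(contigs) == length(proteins))
  rows <- list()
  pos <- list()
  for (i in seq_along(proteins)) {
    ct <- contigs[i]
    k <- (pos[[ct]] <- (if (is.null(pos[[ct]])) 0L else pos[[ct]] + 1L))
    len <- 3L * nchar(proteins[i]) + 3L
    start <- 1L + k * 2000L
    rows[[i]] <- gene_record(sprintf("%s_g%03d", genome_id, i), ct,
                             start, start + len - 1L, "+", k, proteins[i])
  }
  genome(genome_id, do.call(rbind, rows), ...)
}

# A marker-hits table built by hand, bypassing alignment, for exercising
# the co-localization rule in isolation.
make_hits <- function(genome_id, marker_id, gene_id, ordinal,
                      contig_id = "c1", identity = 80, coverage = 90,
                      score = 500) {
  n <- length(marker_id)
  structure(
    data.frame(genome_id = rep_len(genome_id, n), gene_id = gene_id,
               marker_id = marker_id,
               identity = rep_len(identity, n),
               coverage = rep_len(coverage, n),
               score = rep_len(score, n),
               tier = rep_len("high", n), best = rep_len(TRUE, n),
               contig_id = rep_len(contig_id, n),
               ordinal = as.integer(ordinal),
               stringsAsFactors = FALSE),
    class = c("marker_hits", "data.frame"))
}

# A genome object whose gene table places named marker genes at given
# ordinals, padded with decoy-like placeholders.
make_ruled_genome <- function(genome_id, n_genes) {
  prot <- vapply(seq_len(n_genes), function(i)
    paste(rep(c("A", "G", "S", "T", "V")[1 + i %% 5], 60), collapse = ""),
    character(1))
  make_genome(prot, genome_id = genome_id)
}

# Write a small FASTA + GFF3 pair by hand (independent of write_genome).
write_annotation_fixture <- function(dir, fasta_records, gff_lines) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  faa <- file.path(dir, "fix.faa")
  gff <- file.path(dir, "fix.gff")
  writeLines(unlist(lapply(names(fasta_records), function(id)
    c(paste0(">", id), fasta_records[[id]]))), faa)
  writeLines(c("##gff-version 3", gff_lines), gff)
  list(faa = faa, gff = gff)
}
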