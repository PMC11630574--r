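#' @importFrom stats setNames
NULL

AA_ALPHABET_20X <- c("A","C","D","E","F","G","H","I","K","L",
                     "M","N","P","Q","R","S","T","V","W","Y","X")

#' Construct a gene record
#'
#' One annotated coding sequence (CDS): contig, 1-based inclusive
#' coordinates, strand, the per-contig CDS ordinal and the encoded protein.
#' All gene-neighborhood arithmetic in the package is done on ordinals
#' (rank of a CDS among all CDS on its contig, 0-based), never on base
#' pairs: co-localization rules for the iac/iad operons are expressed in
#' CDS units.
#'
#' @param gene_id Unique CDS identifier within the genome.
#' @param contig_id Contig the CDS lies on.
#' @param start,end 1-based inclusive nucleotide coordinates (GFF3
#'   convention); `start <= end` on both strands.
#' @param strand `"+"` or `"-"`.
#' @param ordinal 0-based rank of the CDS among all CDS on its contig,
#'   sorted by ascending start.
#' @param protein Uppercase amino-acid string (20 standard letters plus X).
#' @return A one-row `data.frame` with the gene fields.
#' @export
gene_record <- function(gene_id, contig_id, start, end, strand, ordinal, protein) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (start > end) stop("gene ", gene_id, ": start > end")
  if (!strand %in% c("+", "-")) stop("gene ", gene_id, ": strand must be '+' or '-'")
  check_protein(protein, gene_id)
  data.frame(gene_id = gene_id, contig_id = contig_id,
             start = as.integer(start), end = as.integer(end),
             strand = strand, ordinal = as.integer(ordinal),
             protein = protein, stringsAsFactors = FALSE)
}

check_protein <- function(protein, label = "protein") {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
    stop(label, ": protein sequence must be a non-empty string")
  bad <- setdiff(strsplit(protein, "")[[1]], AA_ALPHABET_20X)
  if (length(bad) > 0)
    stop(label, ": illegal amino-acid character(s): ",
         paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' Construct a genome object
#'
#' Container for one annotated genome: a CDS table plus survey metadata
#' (taxonomy, habitat, assembly quality). Completeness and contamination
#' are required for metagenome-assembled genomes (MAGs) and may be `NA`
#' for isolates, which then pass quality filtering by default.
#'
#' @param genome_id Genome identifier.
#' @param genes A `data.frame` of gene records (rows as produced by
#'   [gene_record()]), or a list of such rows; may be empty.
#' @param taxonomy Character vector of taxonomic labels (domain..species,
#'   may be partial).
#' @param habitat Habitat label (free text, e.g. `"plant_root"`).
#' @param completeness,contamination Assembly quality percentages
#'   (CheckM-style); `NA` allowed for isolates.
#' @param source_kind `"isolate"` or `"MAG"`.
#' @return An object of class `"genome"`.
#' @export
genome <- function(genome_id, genes,
                   taxonomy = character(), habitat = NA_character_,
                   completeness = NA_real_, contamination = NA_real_,
                   source_kind = c("isolate", "MAG")) {
  source_kind <- match.arg(source_kind)
  if (is.list(genes) && !is.data.frame(genes))
    genes <- do.call(rbind, genes)
  if (is.null(genes) || nrow(genes) == 0L) {
    genes <- data.frame(gene_id = character(), contig_id = character(),
                        start = integer(), end = integer(),
                        strand = character(), ordinal = integer(),
                        protein = character(), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(genes$gene_id))
    stop("genome ", genome_id, ": duplicate gene_ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  # ordinals must form 0..k-1 per contig with no gaps
  for (ct in unique(genes$contig_id)) {
    o <- sort(genes$ordinal[genes$contig_id == ct])
    if (!identical(o, seq_along(o) - 1L))
      stop("genome ", genome_id, ", contig ", ct,
           ": ordinals do not form 0..k-1")
  }
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, genes = genes,
                 taxonomy = taxonomy, habitat = habitat,
                 completeness = completeness, contamination = contamination,
                 source_kind = source_kind),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", x$genome_id, ": ", nrow(x$genes), " CDS on ",
      length(unique(x$genes$contig_id)), " contig(s); source ",
      x$source_kind, "\n", sep = "")
  invisible(x)
}

# Assign per-contig 0-based ordinals by ascending start, ties broken by
# ascending end then original file order.
assign_ordinals <- function(genes) {
  genes$.file_order <- seq_len(nrow(genes))
  out <- lapply(split(genes, genes$contig_id), function(g) {
    g <- g[order(g$start, g$end, g$.file_order), , drop = FALSE]
    g$ordinal <- seq_len(nrow(g)) - 1L
    g
  })
  out <- do.call(rbind, out)
  out <- out[order(out$.file_order), , drop = FALSE]
  out$.file_order <- NULL
  rownames(out) <- NULL
  out
}

#' Read an annotated genome from protein FASTA and GFF3
#'
#' Loads a Prokka-style annotation pair into a [genome()] object. Only
#' features of type `CDS` are used; other feature types are ignored. FASTA
#' record identifiers are linked to GFF3 CDS features through the `ID`
#' attribute, falling back to `locus_tag`, then `protein_id`. CDS features
#' without a matching protein are skipped with one warning giving the
#' count; FASTA proteins without a CDS feature are likewise dropped with a
#' warning. Per-contig CDS ordinals are assigned by ascending start
#' coordinate (ties: ascending end, then order in file).
#'
#' @param protein_fasta Path to the protein FASTA file.
#' @param gff Path to the GFF3 annotation.
#' @param genome_id Identifier for the genome; defaults to the FASTA
#'   file name without extension.
#' @param ... Metadata passed on to [genome()] (`taxonomy`, `habitat`,
#'   `completeness`, `contamination`, `source_kind`).
#' @return A `"genome"` object.
#' @export
read_annotated_genome <- function(protein_fasta, gff, genome_id = NULL, ...) {
  if (!file.exists(protein_fasta)) stop("protein FASTA not found: ", protein_fasta)
  if (!file.exists(gff)) stop("GFF3 not found: ", gff)
  if (is.null(genome_id))
    genome_id <- sub("\\.(fa|faa|fasta)$", "", basename(protein_fasta))

  aa <- Biostrings::readAAStringSet(protein_fasta)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA record IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(aa) <- ids

  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  mc <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% names(mc)) as.character(mc[[col]]) else rep(NA_character_, length(gr))
  feat_id <- pick("ID")
  for (fallback in c("locus_tag", "protein_id")) {
    alt <- pick(fallback)
    feat_id <- ifelse(is.na(feat_id) | !nzchar(feat_id), alt, feat_id)
  }
  if (anyDuplicated(feat_id[!is.na(feat_id)]))
    stop("duplicate CDS feature IDs in GFF3: ",
         paste(unique(feat_id[duplicated(feat_id)]), collapse = ", "))

  has_prot <- !is.na(feat_id) & feat_id %in% names(aa)
  n_skip <- sum(!has_prot)
  if (n_skip > 0)
    warning(genome_id, ": skipped ", n_skip,
            " CDS feature(s) with no protein sequence")
  orphan <- setdiff(names(aa), feat_id)
  if (length(orphan) > 0)
    warning(genome_id, ": ", length(orphan),
            " FASTA protein(s) have no matching GFF3 CDS and were dropped")

  gr <- gr[has_prot]
  feat_id <- feat_id[has_prot]
  strands <- as.character(BiocGenerics::strand(gr))
  if (any(strands == "*"))
    stop("CDS feature(s) without strand in GFF3: ",
         paste(feat_id[strands == "*"], collapse = ", "))
  genes <- data.frame(gene_id = feat_id,
                      contig_id = as.character(GenomicRanges::seqnames(gr)),
                      start = BiocGenerics::start(gr),
                      end = BiocGenerics::end(gr),
                      strand = strands,
                      ordinal = NA_integer_,
                      protein = as.character(aa[feat_id]),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) check_protein(genes$protein[i], genes$gene_id[i])
  genes <- assign_ordinals(genes)
  genome(genome_id, genes, ...)
}

#' Write a genome to protein FASTA and GFF3
#'
#' Emits the genome's CDS table as a Prokka-style annotation pair:
#' `<genome_id>.faa` (protein FASTA) and `<genome_id>.gff` (GFF3 with CDS
#' features carrying `ID` and `locus_tag` attributes). Output is
#' byte-identical across runs for identical input.
#'
#' @param g A `"genome"` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths (`faa`, `gff`).
#' @export
write_genome <- function(g, dir) {
  stopifnot(inherits(g, "genome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  faa <- file.path(dir, paste0(g$genome_id, ".faa"))
  gff <- file.path(dir, paste0(g$genome_id, ".gff"))
  aa <- Biostrings::AAStringSet(setNames(g$genes$protein, g$genes$gene_id))
  Biostrings::writeXStringSet(aa, faa)
  gn <- g$genes
  lines <- c("##gff-version 3",
             sprintf("%s\tiaaminer\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s",
                     gn$contig_id, gn$start, gn$end, gn$strand,
                     gn$gene_id, gn$gene_id))
  writeLines(lines, gff)
  invisible(c(faa = faa, gff = gff))
}

#' Write operon calls to TSV
#'
#' One row per genome with the degrader verdict, the evidence pair
#' distances and per-cluster completeness. Missing values are written as
#' `"."`. Rerunning on identical input produces byte-identical output.
#'
#' @param calls A list of `"operon_call"` objects (see [call_degrader()]),
#'   or a `data.frame` as returned by [calls_table()].
#' @param out Output TSV path.
#' @return Invisibly, the table that was written.
#' @export
write_calls <- function(calls, out) {
  tab <- if (is.data.frame(calls)) calls else calls_table(calls)
  tab2 <- tab
  for (j in seq_along(tab2)) {
    v <- as.character(tab2[[j]])
    v[is.na(v)] <- "."
    tab2[[j]] <- v
  }
  con <- file(out, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(tab2), collapse = "\t"), con, sep = "\n")
  if (nrow(tab2) > 0)
    writeLines(do.call(paste, c(unname(as.list(tab2)), sep = "\t")), con, sep = "\n")
  invisible(tab)
}

#' Summarise operon calls as a table
#'
#' @param calls List of `"operon_call"` objects.
#' @return A `data.frame` with columns `genome_id`, `degrader_type`,
#'   `iac_pair_distance`, `iad_pair_distance`, `n_clusters`,
#'   `completeness_status` (comma-separated, one entry per cluster).
#' @export
calls_table <- function(calls) {
  if (inherits(calls, "operon_call")) calls <- list(calls)
  rows <- lapply(calls, function(cl) {
    data.frame(
      genome_id = cl$genome_id,
      degrader_type = cl$degrader_type,
      iac_pair_distance = if (is.null(cl$evidence$iac)) NA_integer_ else cl$evidence$iac$distance,
      iad_pair_distance = if (is.null(cl$evidence$iad)) NA_integer_ else cl$evidence$iad$distance,
      n_clusters = length(cl$clusters),
      completeness_status = if (length(cl$clusters) == 0) NA_character_ else
        paste(vapply(cl$clusters, `[[`, character(1), "completeness_status"),
              collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(genome_id = character(), degrader_type = character(),
                      iac_pair_distance = integer(), iad_pair_distance = integer(),
                      n_clusters = integer(), completeness_status = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write cluster architectures to JSON
#'
#' Dumps the ordered member genes of each reconstructed cluster (template
#' label, gene id, strand, ordinal) in a form suitable for rendering
#' gene-arrow diagrams.
#'
#' @param calls List of `"operon_call"` objects.
#' @param out Output JSON path.
#' @return Invisibly, the list that was serialised.
#' @export
write_architecture_json <- function(calls, out) {
  if (inherits(calls, "operon_call")) calls <- list(calls)
  payload <- lapply(calls, function(cl) {
    list(genome_id = cl$genome_id,
         degrader_type = cl$degrader_type,
         clusters = lapply(cl$clusters, function(arch) {
           list(cluster_type = arch$cluster_type,
                contig_id = arch$contig_id,
                completeness_status = arch$completeness_status,
                n_template_genes_found = arch$n_template_genes_found,
                span = arch$span,
                members = arch$members)
         }))
  })
  jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(payload)
}
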