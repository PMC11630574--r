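#' CDS-ordinal distance between two genes
#'
#' The co-localization rules of the iac/iad screen are expressed in
#' coding-sequence units: the distance between two CDS on the same contig
#' is the absolute difference of their per-contig ordinals, so adjacent
#' CDS are at distance 1. Genes on different contigs are *not
#' co-localized*; this is signalled by `NA_integer_`, never by a large
#' number.
#'
#' @param a,b Single rows of a genome's gene table (or equivalent lists
#'   with `gene_id`, `contig_id` and `ordinal` fields).
#' @return Integer ordinal distance, or `NA_integer_` when the genes lie
#'   on different contigs.
#' @export
cds_distance <- function(a, b) {
  if (identical(a$gene_id, b$gene_id))
    stop("cds_distance requires two distinct genes")
  if (!identical(a$contig_id, b$contig_id)) return(NA_integer_)
  abs(a$ordinal - b$ordinal)
}

# All passing-hit pairs (one hit from each marker) on a shared contig,
# with their ordinal distances; empty data.frame when no pair exists.
pair_distances <- function(hits, marker_a, marker_b) {
  ha <- hits[hits$marker_id == marker_a, , drop = FALSE]
  hb <- hits[hits$marker_id == marker_b, , drop = FALSE]
  if (nrow(ha) == 0L || nrow(hb) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      contig_id = character(), distance = integer(),
                      min_ordinal = integer(), stringsAsFactors = FALSE))
  grid <- expand.grid(i = seq_len(nrow(ha)), j = seq_len(nrow(hb)))
  same <- ha$contig_id[grid$i] == hb$contig_id[grid$j] &
    ha$gene_id[grid$i] != hb$gene_id[grid$j]
  grid <- grid[same, , drop = FALSE]
  data.frame(gene_a = ha$gene_id[grid$i], gene_b = hb$gene_id[grid$j],
             contig_id = ha$contig_id[grid$i],
             distance = abs(ha$ordinal[grid$i] - hb$ordinal[grid$j]),
             min_ordinal = pmin(ha$ordinal[grid$i], hb$ordinal[grid$j]),
             stringsAsFactors = FALSE)
}

# Best satisfying pair under a distance predicate: smallest distance,
# ties -> smallest min ordinal, then gene ids (determinism).
best_pair <- function(pairs, rule) {
  ok <- pairs[rule(pairs$distance), , drop = FALSE]
  if (nrow(ok) == 0L) return(NULL)
  ok <- ok[order(ok$distance, ok$min_ordinal, ok$gene_a, ok$gene_b), , drop = FALSE]
  as.list(ok[1, c("gene_a", "gene_b", "contig_id", "distance")])
}

#' Call the IAA-degrader status of a genome
#'
#' Applies the dual-marker co-localization rule to the marker hits of one
#' genome. A genome is iac-positive when some iacA hit and some iacE hit
#' lie on the same contig at an ordinal distance strictly below
#' `max_cds_gap_iac` (default 7); it is iad-positive when some iadD and
#' iadE hits are within `iad_adjacency_gap` (default 1, i.e. adjacent
#' CDS). Both rules satisfied (possibly on different contigs) gives type
#' `"both"`; neither gives `"none"`. The recorded evidence is the
#' satisfying pair with the smallest distance (ties: smallest minimum
#' ordinal).
#'
#' @param genome A `"genome"` object.
#' @param hits `"marker_hits"` from [screen_markers()] on the same genome.
#' @param cfg A [threshold_config()].
#' @return An object of class `"operon_call"`: list with `genome_id`,
#'   `degrader_type` (`iac`/`iad`/`both`/`none`), `evidence` (per positive
#'   type, the gene pair and its CDS distance) and `clusters` (filled in
#'   by [reconstruct_cluster()] / [scan_genome()]).
#' @export
call_degrader <- function(genome, hits, cfg = threshold_config()) {
  stopifnot(inherits(genome, "genome"))
  if (nrow(hits) > 0 && !all(hits$genome_id == genome$genome_id))
    stop("hits were produced for a different genome")
  iac_rule <- if (isTRUE(cfg$iac_gap_counts_intervening))
    function(d) d - 1L <= cfg$max_cds_gap_iac
  else
    function(d) d < cfg$max_cds_gap_iac
  iad_rule <- function(d) d <= cfg$iad_adjacency_gap

  ev_iac <- best_pair(pair_distances(hits, "iacA", "iacE"), iac_rule)
  ev_iad <- best_pair(pair_distances(hits, "iadD", "iadE"), iad_rule)
  type <- if (!is.null(ev_iac) && !is.null(ev_iad)) "both"
  else if (!is.null(ev_iac)) "iac"
  else if (!is.null(ev_iad)) "iad"
  else "none"
  structure(list(genome_id = genome$genome_id,
                 degrader_type = type,
                 evidence = list(iac = ev_iac, iad = ev_iad),
                 clusters = list()),
            class = "operon_call")
}

#' @export
print.operon_call <- function(x, ...) {
  cat("<operon_call> ", x$genome_id, ": ", x$degrader_type, sep = "")
  for (ty in c("iac", "iad")) {
    ev <- x$evidence[[ty]]
    if (!is.null(ev))
      cat("  [", ty, " ", ev$gene_a, "-", ev$gene_b, " d=", ev$distance, "]",
          sep = "")
  }
  cat("; ", length(x$clusters), " cluster(s)\n", sep = "")
  invisible(x)
}

# Per-gene best template label from whole-operon template hits on one
# contig: for each gene the highest-scoring template (ties: lexicographic
# template label).
gene_template_labels <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$gene_id, -hits$score, hits$marker_id), , drop = FALSE]
  hits[!duplicated(hits$gene_id), , drop = FALSE]
}

# Maximal runs of template-hit ordinals allowing <= gap intervening
# non-template CDS between consecutive members.
split_runs <- function(ordinals, gap) {
  ordinals <- sort(unique(ordinals))
  breaks <- which(diff(ordinals) > gap + 1L)
  unname(split(ordinals, cumsum(c(0L, seq_along(ordinals)[-1] %in% (breaks + 1L)))))
}

#' Reconstruct the architecture of an operon cluster
#'
#' Maps every gene of a whole-operon template set onto the genome (same
#' identity/coverage gates as the marker screen), then grows the cluster
#' around the anchor evidence pair: the maximal run of template-hit CDS in
#' which consecutive members are separated by at most `cfg$cluster_gap`
#' non-template CDS. Genes inside the cluster span with no template match
#' are reported with label `"unknown"`. The cluster is `complete` when
#' every gene of the configured core set is present, else `fragmented`.
#' Additional template runs elsewhere in the genome (at least two template
#' genes) are reported as extra clusters.
#'
#' @param genome A `"genome"` object, positive for `cluster_type`.
#' @param templates Whole-operon template proteins (named vector,
#'   `AAStringSet` or FASTA path); labels like `"iacA"`, `"iadR"`.
#' @param cfg A [threshold_config()].
#' @param anchor The evidence entry of an [call_degrader()] result for
#'   this cluster type (list with `gene_a`, `gene_b`, `contig_id`).
#' @param cluster_type `"iac"` or `"iad"`.
#' @param core_genes Character vector of template labels required for a
#'   `complete` call; defaults to the full catabolic gene set of the
#'   template operon ([core_gene_set()]).
#' @param template_hits Optional precomputed [screen_markers()] result for
#'   `templates` (avoids re-alignment when scanning many genomes).
#' @return A list of `"cluster_architecture"` objects, the anchored
#'   cluster first.
#' @export
reconstruct_cluster <- function(genome, templates, cfg = threshold_config(),
                                anchor, cluster_type = c("iac", "iad"),
                                core_genes = NULL, template_hits = NULL) {
  cluster_type <- match.arg(cluster_type)
  stopifnot(inherits(genome, "genome"))
  if (is.null(core_genes)) core_genes <- core_gene_set(cluster_type)
  if (is.null(template_hits)) template_hits <- screen_markers(genome, templates, cfg)
  th <- template_hits[startsWith(template_hits$marker_id, cluster_type), , drop = FALSE]
  gn <- genome$genes
  if (!all(c(anchor$gene_a, anchor$gene_b) %in% gn$gene_id))
    stop("anchor genes missing from genome ", genome$genome_id)
  lab <- gene_template_labels(th)

  make_arch <- function(contig, run) {
    span <- range(run)
    in_span <- gn[gn$contig_id == contig &
                    gn$ordinal >= span[1] & gn$ordinal <= span[2], , drop = FALSE]
    in_span <- in_span[order(in_span$ordinal), , drop = FALSE]
    memb_lab <- lab$marker_id[match(in_span$gene_id, lab$gene_id)]
    memb_lab[is.na(memb_lab)] <- "unknown"
    members <- lapply(seq_len(nrow(in_span)), function(i)
      list(label = memb_lab[i], gene_id = in_span$gene_id[i],
           strand = in_span$strand[i], ordinal = in_span$ordinal[i]))
    found <- unique(memb_lab[memb_lab != "unknown"])
    structure(list(cluster_type = cluster_type,
                   contig_id = contig,
                   members = members,
                   n_template_genes_found = length(found),
                   template_genes_found = sort(found),
                   completeness_status = if (all(core_genes %in% found))
                     "complete" else "fragmented",
                   span = span),
              class = "cluster_architecture")
  }

  anchor_ords <- gn$ordinal[match(c(anchor$gene_a, anchor$gene_b), gn$gene_id)]
  archs <- list()
  for (contig in unique(lab$contig_id)) {
    runs <- split_runs(lab$ordinal[lab$contig_id == contig], cfg$cluster_gap)
    for (run in runs) {
      anchored <- identical(contig, anchor$contig_id) && any(anchor_ords %in% run)
      if (anchored || length(run) >= 2L)
        archs <- c(archs, list(c(make_arch(contig, run), list(anchored = anchored))))
    }
  }
  ord <- order(!vapply(archs, function(a) isTRUE(a$anchored), logical(1)))
  archs[ord]
}

#' Core gene sets defining a "complete" operon
#'
#' The default requirement for calling a reconstructed cluster complete:
#' all catabolic genes of the template operon (iacA-iacI for the iac
#' cluster; iadA-iadN for the iad cluster). The regulator gene (iacR /
#' iadR) is mapped when present but not required.
#'
#' @param cluster_type `"iac"` or `"iad"`.
#' @return Character vector of template gene labels.
#' @export
core_gene_set <- function(cluster_type = c("iac", "iad")) {
  cluster_type <- match.arg(cluster_type)
  switch(cluster_type,
         iac = paste0("iac", LETTERS[1:9]),
         iad = paste0("iad", LETTERS[1:14]))
}

#' Scan one genome end-to-end
#'
#' Convenience wrapper: screens the four anchor markers, applies the
#' co-localization rule, and for each positive type reconstructs the
#' cluster architecture against the full template set.
#'
#' @param genome A `"genome"` object.
#' @param templates Whole-operon template set (must contain the anchor
#'   markers iacA, iacE, iadD, iadE); defaults to the package's synthetic
#'   templates.
#' @param cfg A [threshold_config()].
#' @return An `"operon_call"` with `clusters` populated.
#' @export
scan_genome <- function(genome, templates = synthetic_operon_templates(),
                        cfg = threshold_config()) {
  templates <- as_marker_set(templates)
  anchors <- c("iacA", "iacE", "iadD", "iadE")
  missing_anchors <- setdiff(anchors, names(templates))
  if (length(missing_anchors) > 0)
    stop("templates lack anchor marker(s): ", paste(missing_anchors, collapse = ", "))
  # screen the anchor markers first; the full template set is only needed
  # for cluster reconstruction on positive genomes
  anchor_hits <- screen_markers(genome, templates[anchors], cfg)
  call <- call_degrader(genome, anchor_hits, cfg)
  if (call$degrader_type == "none") return(call)
  remaining <- templates[setdiff(names(templates), anchors)]
  hits <- if (length(remaining) > 0)
    rbind(anchor_hits, screen_markers(genome, remaining, cfg))
  else anchor_hits
  for (ty in c("iac", "iad")) {
    ev <- call$evidence[[ty]]
    if (!is.null(ev))
      call$clusters <- c(call$clusters,
                         reconstruct_cluster(genome, templates, cfg, ev, ty,
                                             template_hits = hits))
  }
  call
}

#' Scan a collection of genomes
#'
#' @param genomes List of `"genome"` objects.
#' @inheritParams scan_genome
#' @return Named list of `"operon_call"` objects (by genome id).
#' @export
scan_genomes <- function(genomes, templates = synthetic_operon_templates(),
                         cfg = threshold_config()) {
  calls <- lapply(genomes, scan_genome, templates = templates, cfg = cfg)
  names(calls) <- vapply(calls, `[[`, character(1), "genome_id")
  calls
}
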