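#' Concatenate cluster proteins per genome
#'
#' Builds, for each genome, the concatenation of its best-hit proteins for
#' a fixed, configured gene order (e.g. `c("iacA", "iacE")` or a full
#' operon gene set). Genomes missing any requested gene are excluded with
#' a warning. Identical genomes yield identical concatenations, so the
#' downstream tree is reproducible.
#'
#' @param genomes List of `"genome"` objects (or a single genome).
#' @param hits A `"marker_hits"` table covering all genomes (template
#'   labels in `marker_id`), e.g. from [screen_markers()] run per genome
#'   and row-bound.
#' @param genes Character vector of template gene labels, in the
#'   concatenation order to use.
#' @return Named character vector of concatenated protein strings, one
#'   per retained genome.
#' @export
concat_markers <- function(genomes, hits, genes) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  stopifnot(length(genes) > 0)
  out <- character()
  for (g in genomes) {
    gh <- hits[hits$genome_id == g$genome_id & hits$marker_id %in% genes &
                 hits$best, , drop = FALSE]
    if (!all(genes %in% gh$marker_id)) {
      warning("genome ", g$genome_id, " lacks gene(s) ",
              paste(setdiff(genes, gh$marker_id), collapse = ", "),
              "; excluded from concatenation")
      next
    }
    gene_ids <- gh$gene_id[match(genes, gh$marker_id)]
    prots <- g$genes$protein[match(gene_ids, g$genes$gene_id)]
    out[g$genome_id] <- paste(prots, collapse = "")
  }
  out
}

#' Pairwise p-distance between two protein sequences
#'
#' One minus the identity fraction of a global (Needleman-Wunsch)
#' alignment under affine gap penalties, with identity computed over all
#' aligned columns (gap columns included in the denominator). A simple,
#' fully documented substitute for a multiple-alignment-based distance:
#' adequate for quantifying tree *incongruence*, not branch-length
#' estimation.
#'
#' @param a,b Protein strings.
#' @param cfg A [threshold_config()] supplying the substitution matrix and
#'   gap penalties.
#' @return Distance in `[0, 1]`; 0 for identical sequences.
#' @export
pdistance <- function(a, b, cfg = threshold_config()) {
  check_protein(a, "a")
  check_protein(b, "b")
  if (identical(a, b)) return(0)
  submat <- get_submat(cfg$matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = submat,
    gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend,
    type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  1 - sum(p == s & p != "-") / length(p)
}

#' Pairwise distance matrix over concatenated sequences
#'
#' @param seqs Named character vector of (concatenated) protein strings.
#' @param cfg A [threshold_config()].
#' @return Symmetric numeric matrix with zero diagonal, labelled by the
#'   sequence names.
#' @export
pdistance_matrix <- function(seqs, cfg = threshold_config()) {
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- pdistance(seqs[[i]], seqs[[j]], cfg)
    }
  }
  d
}

check_dist_matrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  invisible(TRUE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via `ape::nj`) with deterministic
#' tie-breaking: taxa are ordered lexicographically before joining, so
#' permuting the input rows never changes the topology.
#'
#' @param d Labelled symmetric distance matrix (zero diagonal).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  check_dist_matrix(d)
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  ape::nj(stats::as.dist(d))
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the non-trivial bipartitions unique to each of two unrooted
#' trees over the same taxon set (the standard symmetric-difference
#' metric). Used to quantify the incongruence between a gene-cluster tree
#' and the whole-genome tree.
#'
#' @param tree1,tree2 `phylo` objects, Newick strings, or paths to Newick
#'   files.
#' @return Integer RF distance; 0 for topologically identical trees, at
#'   most `2 * (n - 3)` for `n` taxa when both trees are binary.
#' @export
rf_distance <- function(tree1, tree2) {
  t1 <- as_phylo(tree1)
  t2 <- as_phylo(tree2)
  if (!setequal(t1$tip.label, t2$tip.label)) {
    only1 <- setdiff(t1$tip.label, t2$tip.label)
    only2 <- setdiff(t2$tip.label, t1$tip.label)
    stop("taxon sets differ; only in tree1: {",
         paste(only1, collapse = ", "), "}; only in tree2: {",
         paste(only2, collapse = ", "), "}")
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

as_phylo <- function(x) {
  if (inherits(x, "phylo")) return(x)
  if (is.character(x) && length(x) == 1L) {
    tr <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
    if (is.null(tr)) stop("could not parse Newick input")
    return(tr)
  }
  stop("expected a phylo object, a Newick string or a Newick file path")
}

#' Compare a gene-cluster tree to a whole-genome tree
#'
#' End-to-end wrapper: concatenates the requested cluster genes across
#' degrader genomes, builds the neighbor-joining tree from global-
#' alignment p-distances, restricts the supplied whole-genome tree to the
#' same taxa and reports the Robinson-Foulds incongruence.
#'
#' @param genomes List of `"genome"` objects.
#' @param hits Combined `"marker_hits"` table for the template set.
#' @param genes Gene labels to concatenate (fixed order).
#' @param wgs_tree Whole-genome reference tree (`phylo`, Newick string or
#'   file).
#' @param cfg A [threshold_config()].
#' @return List with `cluster_tree` (`phylo`), `wgs_tree` (pruned
#'   `phylo`), `rf` (integer) and `rf_max` (`2 * (n - 3)`).
#' @export
compare_cluster_to_wgs <- function(genomes, hits, genes, wgs_tree,
                                   cfg = threshold_config()) {
  seqs <- concat_markers(genomes, hits, genes)
  if (length(seqs) < 4)
    stop("need at least 4 genomes with the full gene set; have ", length(seqs))
  ct <- nj_tree(pdistance_matrix(seqs, cfg))
  wt <- as_phylo(wgs_tree)
  missing_taxa <- setdiff(names(seqs), wt$tip.label)
  if (length(missing_taxa) > 0)
    stop("whole-genome tree lacks taxa: ", paste(missing_taxa, collapse = ", "))
  wt <- ape::keep.tip(wt, names(seqs))
  rf <- rf_distance(ct, wt)
  list(cluster_tree = ct, wgs_tree = wt, rf = rf,
       rf_max = 2L * (length(seqs) - 3L))
}
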