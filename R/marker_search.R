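#' Threshold and scoring configuration for the operon scan
#'
#' Bundles every tunable cutoff of the detection pipeline. The defaults
#' are the published screen settings: marker hits must exceed 50% amino
#' acid identity and 60% template coverage (both strict), the iacA-iacE
#' pair must lie less than 7 CDS apart (strict), and iadD must be adjacent
#' to iadE (ordinal distance of at most 1). An alternative identity preset
#' of 40% ("relaxed", used for annotation-figure style labelling) is
#' available via `preset = "relaxed"`.
#'
#' @param min_identity Minimum percent identity, strict `>`. Default 50.
#' @param min_coverage Minimum percent coverage of the template, strict
#'   `>`. Default 60.
#' @param max_cds_gap_iac iacA-iacE ordinal distance must be strictly
#'   below this. Default 7.
#' @param iad_adjacency_gap Maximum iadD-iadE ordinal distance
#'   (inclusive). Default 1, i.e. strictly adjacent CDS.
#' @param iac_gap_counts_intervening If `TRUE`, read "less than 7 CDS" as
#'   "at most 7 intervening CDS" (ordinal distance `<= 8`) instead of the
#'   default ordinal-difference reading (`< 7`). Default `FALSE`.
#' @param cluster_gap Maximum number of non-template CDS tolerated between
#'   consecutive template genes when growing a cluster. Default 3.
#' @param matrix Substitution matrix name (from `Biostrings`). Default
#'   `"BLOSUM62"`.
#' @param gap_open,gap_extend Affine gap penalties (positive costs). A gap
#'   of length L costs `gap_open + L * gap_extend`. Defaults 11 and 1.
#' @param preset `"default"` or `"relaxed"` (lowers `min_identity` to 40).
#' @return A list of class `"threshold_config"`.
#' @export
threshold_config <- function(min_identity = 50, min_coverage = 60,
                             max_cds_gap_iac = 7, iad_adjacency_gap = 1,
                             iac_gap_counts_intervening = FALSE,
                             cluster_gap = 3,
                             matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1,
                             preset = c("default", "relaxed")) {
  preset <- match.arg(preset)
  if (preset == "relaxed" && missing(min_identity)) min_identity <- 40
  stopifnot(min_identity >= 0, min_coverage >= 0,
            max_cds_gap_iac >= 0, iad_adjacency_gap >= 0,
            cluster_gap >= 0, gap_open >= 0, gap_extend >= 0)
  if (max_cds_gap_iac < iad_adjacency_gap)
    stop("max_cds_gap_iac must be >= iad_adjacency_gap")
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 max_cds_gap_iac = max_cds_gap_iac,
                 iad_adjacency_gap = iad_adjacency_gap,
                 iac_gap_counts_intervening = iac_gap_counts_intervening,
                 cluster_gap = cluster_gap,
                 matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "threshold_config")
}

get_submat <- function(name) {
  key <- paste0("submat_", name)
  cached <- get0(key, envir = .iaaminer_cache)
  if (!is.null(cached)) return(cached)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  assign(key, m, envir = .iaaminer_cache)
  m
}

#' Local protein alignment with identity and coverage
#'
#' Smith-Waterman optimal local alignment under affine gap penalties
#' (via `Biostrings::pairwiseAlignment`). Identity is computed over
#' aligned columns only, with gap columns included in the denominator;
#' coverage is the fraction of the *template* (subject) spanned by the
#' local alignment. These are the conventions of BLAST-style protein
#' search tools.
#'
#' @param query Query protein string.
#' @param template Template (reference marker) protein string; coverage
#'   is measured on this sequence.
#' @param cfg A [threshold_config()] supplying the substitution matrix and
#'   gap penalties.
#' @return Named numeric vector with `identity` (%), `coverage` (%) and
#'   `score` (substitution-matrix units).
#' @examples
#' align_local("MKTAYVAKQR", "MKTAYIAKQR")
#' @export
align_local <- function(query, template, cfg = threshold_config()) {
  check_protein(query, "query")
  check_protein(template, "template")
  res <- align_many(query, template, cfg)
  c(identity = res$identity[1], coverage = res$coverage[1], score = res$score[1])
}

# Vectorized local alignment of many queries against one template,
# through the package's compiled Smith-Waterman kernel.
# Returns a data.frame with one row per query.
align_many <- function(queries, template, cfg = threshold_config()) {
  submat <- get_submat(cfg$matrix)
  alphabet <- rownames(submat)
  storage.mode(submat) <- "integer"
  .sw_align_batch(queries, template, submat, alphabet,
                  as.integer(cfg$gap_open), as.integer(cfg$gap_extend))
}

# identity > 60 -> high; 40 <= identity <= 60 -> moderate; else below
hit_tier <- function(identity) {
  ifelse(identity > 60, "high", ifelse(identity >= 40, "moderate", "below"))
}

#' Screen marker proteins against a genome
#'
#' Aligns each marker/template protein against every CDS protein of the
#' genome and retains the (marker, gene) pairs passing the identity and
#' coverage gates (both strict `>`). Each retained hit is tiered by
#' identity (`high` > 60%; `moderate` 40-60%; `below` otherwise) and, per
#' marker, the single best hit in the genome is flagged (highest score;
#' ties broken by lowest CDS ordinal, then lexicographic gene id). All
#' passing hits are kept for the downstream co-localization search.
#'
#' @param genome A `"genome"` object.
#' @param markers Named character vector or `AAStringSet` of marker
#'   proteins, or a path to a marker FASTA. Record IDs of the form
#'   `"<marker_id>|<source_strain>"` are parsed so that `marker_id` is the
#'   part before the bar; plain IDs are used as-is.
#' @param cfg A [threshold_config()].
#' @return A `data.frame` of class `"marker_hits"` with columns
#'   `genome_id`, `gene_id`, `marker_id`, `identity`, `coverage`, `score`,
#'   `tier`, `best`, plus `contig_id` and `ordinal` for convenience.
#' @export
screen_markers <- function(genome, markers, cfg = threshold_config()) {
  stopifnot(inherits(genome, "genome"))
  markers <- as_marker_set(markers)
  empty <- data.frame(genome_id = character(), gene_id = character(),
                      marker_id = character(), identity = numeric(),
                      coverage = numeric(), score = numeric(),
                      tier = character(), best = logical(),
                      contig_id = character(), ordinal = integer(),
                      stringsAsFactors = FALSE)
  if (length(markers) == 0) stop("markers must be non-empty")
  gn <- genome$genes
  if (nrow(gn) == 0L) return(structure(empty, class = c("marker_hits", "data.frame")))

  res <- lapply(names(markers), function(mid) {
    st <- align_many(gn$protein, markers[[mid]], cfg)
    keep <- st$identity > cfg$min_identity & st$coverage > cfg$min_coverage
    if (!any(keep)) return(NULL)
    hits <- data.frame(genome_id = genome$genome_id,
                       gene_id = gn$gene_id[keep],
                       marker_id = mid,
                       identity = st$identity[keep],
                       coverage = st$coverage[keep],
                       score = st$score[keep],
                       tier = hit_tier(st$identity[keep]),
                       best = FALSE,
                       contig_id = gn$contig_id[keep],
                       ordinal = gn$ordinal[keep],
                       stringsAsFactors = FALSE)
    ix <- order(-hits$score, hits$ordinal, hits$gene_id)
    hits$best[ix[1]] <- TRUE
    hits
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  structure(out, class = c("marker_hits", "data.frame"))
}

# Normalise marker input: FASTA path, AAStringSet or named character
# vector -> named list of protein strings keyed by marker_id (part of the
# record ID before the first "|").
as_marker_set <- function(markers) {
  if (is.character(markers) && length(markers) == 1L && file.exists(markers))
    markers <- Biostrings::readAAStringSet(markers)
  if (methods::is(markers, "AAStringSet"))
    markers <- setNames(as.character(markers), names(markers))
  if (is.null(names(markers)) || any(!nzchar(names(markers))))
    stop("marker sequences must be named")
  ids <- vapply(strsplit(names(markers), "|", fixed = TRUE), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate marker ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  as.list(setNames(unname(markers), ids))
}
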