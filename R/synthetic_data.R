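AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# Average amino-acid frequencies of bacterial proteomes (Swiss-Prot-style
# composition); decoy proteins are drawn from this model rather than from
# shuffled real proteins, which avoids accidental homology to the markers.
AA_FREQ <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86,
             G = 7.07, H = 2.27, I = 5.91, K = 5.80, L = 9.65,
             M = 2.41, N = 4.06, P = 4.74, Q = 3.93, R = 5.53,
             S = 6.64, T = 5.35, V = 6.86, W = 1.10, Y = 2.92)

# Run code under a local RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Deterministic sub-seed derivation (kept within 32-bit integer range).
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629 + 1)
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE, prob = AA_FREQ), collapse = "")
}

#' Synthetic iac/iad operon template proteins
#'
#' A deterministic set of synthetic template proteins standing in for the
#' reference operon gene products: the iac cluster genes iacA-iacI plus
#' the regulator iacR, and the iad cluster genes iadA-iadN plus iadR.
#' Sequences are drawn once from the random-composition model under a
#' fixed internal seed, so the set is identical in every session. They
#' are synthetic stand-ins with realistic lengths (250-500 residues), not
#' biological sequences; the pipeline treats them exactly as it would a
#' curated template FASTA.
#'
#' @return Named character vector of protein strings; names have the form
#'   `"<gene_label>|synthetic"`.
#' @export
synthetic_operon_templates <- function() {
  cached <- get0("templates", envir = .iaaminer_cache)
  if (!is.null(cached)) return(cached)
  labels <- c(paste0("iac", c(LETTERS[1:9], "R")),
              paste0("iad", c(LETTERS[1:14], "R")))
  out <- with_seed(104729, {
    lens <- sample(250:500, length(labels), replace = TRUE)
    setNames(vapply(lens, random_protein, character(1)),
             paste0(labels, "|synthetic"))
  })
  assign("templates", out, envir = .iaaminer_cache)
  out
}

.iaaminer_cache <- new.env(parent = emptyenv())

#' Synthetic anchor marker proteins
#'
#' The four anchor markers (iacA, iacE, iadD, iadE) from
#' [synthetic_operon_templates()].
#'
#' @return Named character vector of four protein strings.
#' @export
synthetic_markers <- function() {
  tpl <- synthetic_operon_templates()
  tpl[paste0(c("iacA", "iacE", "iadD", "iadE"), "|synthetic")]
}

#' Mutate a protein to a target percent identity
#'
#' Substitutes uniformly chosen positions with uniformly chosen different
#' residues until the identity measured by [align_local()] against the
#' template lies within +/- 2 percentage points of the target. Fully
#' deterministic for a given seed.
#'
#' @param template Template protein string.
#' @param target_identity Target percent identity in `[20, 100]`.
#' @param seed Integer seed.
#' @param cfg A [threshold_config()] (alignment settings used for the
#'   verification).
#' @return Mutated protein string.
#' @export
mutate_protein <- function(template, target_identity, seed,
                           cfg = threshold_config()) {
  check_protein(template, "template")
  if (target_identity < 20 || target_identity > 100)
    stop("target_identity must be in [20, 100]")
  if (target_identity == 100) return(template)
  n <- nchar(template)
  orig <- strsplit(template, "")[[1]]
  with_seed(seed, {
    perm <- sample.int(n)                       # substitution order
    repl <- vapply(orig, function(a)
      sample(setdiff(AA20, a), 1), character(1))
    k <- round((1 - target_identity / 100) * n)
    mutated <- function(k) {
      v <- orig
      if (k > 0) v[perm[seq_len(k)]] <- repl[perm[seq_len(k)]]
      paste(v, collapse = "")
    }
    result <- NULL
    for (iter in seq_len(n)) {
      cand <- mutated(k)
      id <- align_local(cand, template, cfg)[["identity"]]
      if (abs(id - target_identity) <= 2) {
        result <- cand
        break
      }
      k <- k + if (id > target_identity) 1L else -1L
      if (k < 0L || k > n)
        stop("cannot reach target identity ", target_identity)
    }
    if (is.null(result))
      stop("mutation search did not converge for target ", target_identity)
    result
  })
}

#' Specification of one planted operon
#'
#' Describes how a synthetic operon is planted into a genome: which
#' cluster, at what amino-acid identity to the templates, which genes
#' (fragmentation control), how many decoy CDS to insert between members,
#' and whether gene order is shuffled or strands flipped.
#'
#' @param operon_type `"iac"` or `"iad"`.
#' @param target_identity Planted percent identity to the templates
#'   (within the +/- 2 point band of [mutate_protein()]). Default 90.
#' @param gene_subset Template gene labels to plant; `NULL` (default)
#'   plants the full cluster including the regulator.
#' @param inter_gene_gap Number of decoy CDS inserted between consecutive
#'   planted genes. Default 0.
#' @param shuffle Shuffle the planted gene order. Default `FALSE`.
#' @param strand_flips Draw each planted gene's strand at random instead
#'   of all `"+"`. Default `FALSE`.
#' @return A list of class `"plant_spec"`.
#' @export
plant_spec <- function(operon_type = c("iac", "iad"), target_identity = 90,
                       gene_subset = NULL, inter_gene_gap = 0,
                       shuffle = FALSE, strand_flips = FALSE) {
  operon_type <- match.arg(operon_type)
  if (target_identity < 20 || target_identity > 100)
    stop("target_identity must be in [20, 100]")
  if (inter_gene_gap < 0) stop("inter_gene_gap must be >= 0")
  all_genes <- paste0(operon_type,
                      switch(operon_type, iac = c(LETTERS[1:9], "R"),
                             iad = c(LETTERS[1:14], "R")))
  if (is.null(gene_subset)) gene_subset <- all_genes
  bad <- setdiff(gene_subset, all_genes)
  if (length(bad) > 0)
    stop("unknown gene label(s) for ", operon_type, ": ",
         paste(bad, collapse = ", "))
  structure(list(operon_type = operon_type,
                 target_identity = target_identity,
                 gene_subset = gene_subset,
                 inter_gene_gap = inter_gene_gap,
                 shuffle = shuffle, strand_flips = strand_flips),
            class = "plant_spec")
}

# The degrader call this planted geometry should produce under `cfg`,
# given the mutation band of +/- 2 identity points around the target.
intended_type_of <- function(specs, member_tables, cfg) {
  pos <- c(iac = FALSE, iad = FALSE)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    mt <- member_tables[[i]]
    anchors <- paste0(sp$operon_type, switch(sp$operon_type,
                                             iac = c("A", "E"), iad = c("D", "E")))
    if (!all(anchors %in% mt$gene_label)) next
    if (sp$target_identity - 2 <= cfg$min_identity) next  # below/astride gate
    d <- abs(diff(mt$ordinal[match(anchors, mt$gene_label)]))
    ok <- if (sp$operon_type == "iac") d < cfg$max_cds_gap_iac
    else d <= cfg$iad_adjacency_gap
    if (ok) pos[sp$operon_type] <- TRUE
  }
  if (all(pos)) "both" else if (pos["iac"]) "iac" else if (pos["iad"]) "iad" else "none"
}

#' Generate a synthetic annotated genome with planted operons
#'
#' Builds a single-contig genome of decoy CDS (random-composition
#' proteins, lengths 150-450) into which zero or more operons are planted
#' according to [plant_spec()]s: template genes mutated to a controlled
#' identity, laid out with the requested spacing, order and strands.
#' Deterministic for a given seed, byte-identical files via
#' [write_genome()]. The returned truth table records every planted gene
#' and the degrader call the geometry implies.
#'
#' @param genome_id Genome identifier.
#' @param n_decoys Number of decoy CDS outside the planted blocks.
#' @param specs List of [plant_spec()] objects (possibly empty).
#' @param seed Integer seed.
#' @param cfg A [threshold_config()] used to derive the intended call
#'   recorded in the truth labels.
#' @param ... Metadata passed to [genome()].
#' @return A `"genome"` with attributes `truth` (a `data.frame`:
#'   `genome_id`, `operon_type`, `gene_label`, `gene_id`, `ordinal`,
#'   `target_identity`) and `intended_call` (`iac`/`iad`/`both`/`none`).
#' @export
generate_genome <- function(genome_id = "synth_1", n_decoys = 25,
                            specs = list(), seed = 1,
                            cfg = threshold_config(), ...) {
  if (inherits(specs, "plant_spec")) specs <- list(specs)
  templates <- as_marker_set(synthetic_operon_templates())

  entries <- with_seed(sub_seed(seed, 1), {
    decoys <- lapply(seq_len(n_decoys), function(i)
      list(protein = random_protein(sample(150:450, 1)),
           label = NA_character_, strand = "+", spec_idx = NA_integer_))
    blocks <- lapply(seq_along(specs), function(si) {
      sp <- specs[[si]]
      genes <- sp$gene_subset
      if (sp$shuffle) genes <- sample(genes)
      blk <- list()
      for (gi in seq_along(genes)) {
        g <- genes[gi]
        prot <- mutate_protein(templates[[g]], sp$target_identity,
                               sub_seed(seed, 100 * si + gi), cfg)
        strand <- if (sp$strand_flips) sample(c("+", "-"), 1) else "+"
        blk <- c(blk, list(list(protein = prot, label = g, strand = strand,
                                spec_idx = si)))
        if (gi < length(genes) && sp$inter_gene_gap > 0) {
          fillers <- lapply(seq_len(sp$inter_gene_gap), function(j)
            list(protein = random_protein(sample(150:450, 1)),
                 label = NA_character_, strand = "+", spec_idx = NA_integer_))
          blk <- c(blk, fillers)
        }
      }
      blk
    })
    # splice each block whole into the decoy sequence at a random point
    out <- decoys
    for (blk in blocks) {
      at <- sample(0:length(out), 1)
      out <- append(out, blk, after = at)
    }
    out
  })

  k <- length(entries)
  lens <- vapply(entries, function(e) nchar(e$protein), integer(1))
  starts <- cumsum(c(1L, utils::head(3L * lens + 3L + 100L, -1L)))
  genes <- data.frame(
    gene_id = sprintf("%s_g%04d", genome_id, seq_len(k)),
    contig_id = "ctg_1",
    start = starts,
    end = starts + 3L * lens + 2L,
    strand = vapply(entries, `[[`, character(1), "strand"),
    ordinal = seq_len(k) - 1L,
    protein = vapply(entries, `[[`, character(1), "protein"),
    stringsAsFactors = FALSE)

  labels <- vapply(entries, `[[`, character(1), "label")
  spec_idx <- vapply(entries, `[[`, integer(1), "spec_idx")
  planted <- which(!is.na(labels))
  truth <- if (length(planted) > 0) {
    data.frame(
      genome_id = genome_id,
      operon_type = substr(labels[planted], 1, 3),
      gene_label = labels[planted],
      gene_id = genes$gene_id[planted],
      ordinal = genes$ordinal[planted],
      target_identity = vapply(spec_idx[planted],
                               function(i) specs[[i]]$target_identity,
                               numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(genome_id = character(), operon_type = character(),
               gene_label = character(), gene_id = character(),
               ordinal = integer(), target_identity = numeric(),
               stringsAsFactors = FALSE)
  }

  member_tables <- lapply(seq_along(specs), function(si)
    truth[spec_idx[planted] == si, , drop = FALSE])
  g <- genome(genome_id, genes, ...)
  attr(g, "truth") <- truth
  attr(g, "intended_call") <- intended_type_of(specs, member_tables, cfg)
  g
}

#' Generate a habitat-stratified synthetic survey
#'
#' Emulates a habitat-stratified genome collection with known degrader
#' prevalence: for each stratum, exactly `round(n * prevalence)` genomes
#' carry an intact planted operon (deterministic allocation, not
#' Bernoulli draws); the rest are pure decoys. Completeness and
#' contamination are drawn from configurable ranges so that MAG quality
#' filtering can be exercised.
#'
#' @param strata A `data.frame` with columns `habitat`, `n`, `prevalence`
#'   and optionally `type` (`"iac"`, `"iad"` or `"mix"`, default mix:
#'   positives alternate between the two clusters).
#' @param seed Integer seed.
#' @param n_decoys Decoy CDS per genome. Default 20.
#' @param positive_identity Planted identity of positive genomes.
#'   Default 90.
#' @param completeness_range,contamination_range Ranges for the MAG
#'   quality metadata. Defaults `c(92, 99.5)` and `c(0, 3)` (all genomes
#'   pass the quality filter).
#' @param source_kind `"MAG"` (default) or `"isolate"`.
#' @param orders Taxonomic order labels cycled over genomes.
#' @return List with `genomes` (list of `"genome"`), `metadata`
#'   (`data.frame`: `genome_id`, `habitat`, `order`, `completeness`,
#'   `contamination`, `source_kind`) and `truth` (`data.frame`:
#'   `genome_id`, `habitat`, `intended_call`).
#' @export
generate_survey <- function(strata, seed = 1, n_decoys = 20,
                            positive_identity = 90,
                            completeness_range = c(92, 99.5),
                            contamination_range = c(0, 3),
                            source_kind = "MAG",
                            orders = c("Burkholderiales", "Sphingomonadales",
                                       "Pseudomonadales", "Rhizobiales")) {
  stopifnot(all(c("habitat", "n", "prevalence") %in% names(strata)))
  genomes <- list()
  meta <- truth <- list()
  idx <- 0L
  for (s in seq_len(nrow(strata))) {
    n <- strata$n[s]
    n_pos <- as.integer(round_half_up(n * strata$prevalence[s], 0))
    type_mode <- if ("type" %in% names(strata)) strata$type[s] else "mix"
    for (i in seq_len(n)) {
      idx <- idx + 1L
      gid <- sprintf("%s_%03d", strata$habitat[s], i)
      positive <- i <= n_pos
      ty <- if (!positive) NA_character_
      else if (type_mode == "mix") c("iac", "iad")[1 + (i %% 2)]
      else type_mode
      specs <- if (positive) list(plant_spec(ty, target_identity = positive_identity))
      else list()
      g <- generate_genome(gid, n_decoys = n_decoys, specs = specs,
                           seed = sub_seed(seed, idx),
                           habitat = strata$habitat[s],
                           source_kind = source_kind)
      qual <- with_seed(sub_seed(seed, 500000 + idx), c(
        stats::runif(1, completeness_range[1], completeness_range[2]),
        stats::runif(1, contamination_range[1], contamination_range[2])))
      g$completeness <- round(qual[1], 2)
      g$contamination <- round(qual[2], 2)
      genomes[[gid]] <- g
      meta[[gid]] <- data.frame(
        genome_id = gid, habitat = strata$habitat[s],
        order = orders[1 + (idx %% length(orders))],
        completeness = g$completeness, contamination = g$contamination,
        source_kind = source_kind, stringsAsFactors = FALSE)
      truth[[gid]] <- data.frame(genome_id = gid, habitat = strata$habitat[s],
                                 intended_call = attr(g, "intended_call"),
                                 stringsAsFactors = FALSE)
    }
  }
  list(genomes = genomes,
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Generate the mixed validation suite
#'
#' A fixed repertoire of genome classes cycled to the requested size:
#' intact iac/iad operons at high (85%) and moderate (70%) identity,
#' fragmented clusters that retain the anchor pair, marker pairs planted
#' beyond the co-localization limits, plants below the identity gate
#' (40%), pure-decoy genomes, and dual-operon genomes. Together these
#' cover every branch of the detection rule with known truth.
#'
#' @param n Number of genomes (>= 10 recommended; classes are cycled).
#' @param seed Integer seed.
#' @return List of `"genome"` objects, each carrying `truth` and
#'   `intended_call` attributes.
#' @export
generate_validation_suite <- function(n = 60, seed = 1) {
  classes <- list(
    list(specs = list(plant_spec("iac", 85))),
    list(specs = list(plant_spec("iad", 85))),
    list(specs = list(plant_spec("iac", 70))),
    list(specs = list(plant_spec("iad", 70, strand_flips = TRUE))),
    list(specs = list(plant_spec("iac", 80,
                                 gene_subset = c("iacA", "iacB", "iacE", "iacR")))),
    list(specs = list(plant_spec("iad", 80,
                                 gene_subset = c("iadC", "iadD", "iadE")))),
    list(specs = list(plant_spec("iac", 85, gene_subset = c("iacA", "iacE"),
                                 inter_gene_gap = 7))),   # distance 8: not co-localized
    list(specs = list(plant_spec("iad", 85, gene_subset = c("iadD", "iadE"),
                                 inter_gene_gap = 1))),   # distance 2: not adjacent
    list(specs = list(plant_spec("iac", 40))),            # below identity gate
    list(specs = list()),                                 # pure decoys
    list(specs = list(plant_spec("iac", 80), plant_spec("iad", 80)))
  )
  lapply(seq_len(n), function(i) {
    cls <- classes[[1 + (i - 1) %% length(classes)]]
    generate_genome(sprintf("val_%03d", i), n_decoys = 20,
                    specs = cls$specs, seed = sub_seed(seed, 1000 + i))
  })
}

#' Score scan calls against generator truth
#'
#' @param calls List of `"operon_call"` objects.
#' @param genomes The generated genomes the calls came from (carrying
#'   `intended_call` attributes).
#' @return List with `sensitivity` (fraction of truth-positive genomes
#'   called with exactly the intended type), `specificity` (fraction of
#'   truth-negative genomes called `none`), `n_positive`, `n_negative`,
#'   and the per-genome comparison table.
#' @export
score_against_truth <- function(calls, genomes) {
  truth <- unname(vapply(genomes, function(g) attr(g, "intended_call"), character(1)))
  called <- unname(vapply(calls, `[[`, character(1), "degrader_type"))
  ids <- unname(vapply(genomes, `[[`, character(1), "genome_id"))
  stopifnot(identical(ids, unname(vapply(calls, `[[`, character(1), "genome_id"))))
  tab <- data.frame(genome_id = ids, intended = truth, called = called,
                    stringsAsFactors = FALSE)
  pos <- truth != "none"
  list(sensitivity = if (any(pos)) mean(called[pos] == truth[pos]) else NA_real_,
       specificity = if (any(!pos)) mean(called[!pos] == "none") else NA_real_,
       n_positive = sum(pos), n_negative = sum(!pos), table = tab)
}
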