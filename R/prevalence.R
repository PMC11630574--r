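#' Round half-up to a fixed number of decimals
#'
#' Commercial ("half-up") rounding, used for all reported prevalence
#' percentages: 12.1323 -> 12.13, 3.785 -> 3.79. Base R's `round()` uses
#' banker's rounding and is not used for reported percentages.
#'
#' @param x Numeric vector.
#' @param digits Number of decimals (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Filter genome records by MAG quality criteria
#'
#' Retains metagenome-assembled genomes (MAGs) that are at least 90%
#' complete, at most 5% contaminated and have a quality score
#' `q = completeness - 5 * contamination` of at least 65 (all boundaries
#' inclusive). Isolates without completeness/contamination estimates are
#' not silently dropped: they pass by default and are flagged
#' (`quality_flag = "assumed_pass"`), since isolate screens are run
#' without MAG filters.
#'
#' @param records A `data.frame` with at least `genome_id`,
#'   `completeness`, `contamination` and `source_kind` columns
#'   (`"isolate"` or `"MAG"`).
#' @param min_completeness Minimum completeness (default 90, `>=`).
#' @param max_contamination Maximum contamination (default 5, `<=`).
#' @param min_quality Minimum quality score (default 65, `>=`).
#' @return The retained rows, with added columns `quality` (the score, NA
#'   when completeness/contamination are missing) and `quality_flag`
#'   (`"pass"` or `"assumed_pass"`). Applying the filter twice gives the
#'   same result as applying it once.
#' @export
filter_mags <- function(records, min_completeness = 90,
                        max_contamination = 5, min_quality = 65) {
  stopifnot(is.data.frame(records))
  c_ <- records$completeness
  x_ <- records$contamination
  if (any(c_ < 0, na.rm = TRUE) || any(x_ < 0, na.rm = TRUE))
    stop("negative completeness or contamination")
  is_mag <- records$source_kind == "MAG"
  if (any(is_mag & (is.na(c_) | is.na(x_))))
    stop("MAG record(s) missing completeness or contamination: ",
         paste(records$genome_id[is_mag & (is.na(c_) | is.na(x_))], collapse = ", "))
  q <- c_ - 5 * x_
  keep <- ifelse(is.na(c_) | is.na(x_),
                 TRUE,  # isolates without estimates: flagged pass
                 c_ >= min_completeness & x_ <= max_contamination & q >= min_quality)
  out <- records[keep, , drop = FALSE]
  out$quality <- q[keep]
  out$quality_flag <- ifelse(is.na(out$quality), "assumed_pass", "pass")
  rownames(out) <- NULL
  out
}

#' Degrader prevalence stratified by habitat or taxonomic order
#'
#' Counts genomes positive for the iac and/or iad operon per stratum and
#' reports the percentage of positives, with half-up rounding to two
#' decimals. `n_positive = n_iac + n_iad + n_both`; a TOTAL row summarises
#' the whole collection. Strata with zero screened genomes are never
#' emitted.
#'
#' @param records A `data.frame` with one row per screened genome,
#'   containing the stratification column and a `degrader_type` column
#'   (`"iac"`, `"iad"`, `"both"` or `"none"`), e.g. the result of merging
#'   [calls_table()] with a metadata table by `genome_id`.
#' @param stratify_on Column to stratify on: `"habitat"` or `"order"`
#'   (any column name present in `records` is accepted).
#' @return A `data.frame` of class `"prevalence_table"` with columns
#'   `stratum`, `n_screened`, `n_positive`, `n_iac`, `n_iad`, `n_both`,
#'   `percent_positive`.
#' @export
prevalence_by_stratum <- function(records, stratify_on = "habitat") {
  stopifnot(is.data.frame(records))
  if (!stratify_on %in% names(records))
    stop("stratification column not found: ", stratify_on)
  if (!"degrader_type" %in% names(records))
    stop("records must have a degrader_type column")
  bad <- setdiff(unique(records$degrader_type), c("iac", "iad", "both", "none"))
  if (length(bad) > 0)
    stop("unknown degrader_type value(s): ", paste(bad, collapse = ", "))

  one_row <- function(label, sub) {
    n_iac <- sum(sub$degrader_type == "iac")
    n_iad <- sum(sub$degrader_type == "iad")
    n_both <- sum(sub$degrader_type == "both")
    n_pos <- n_iac + n_iad + n_both
    data.frame(stratum = label, n_screened = nrow(sub), n_positive = n_pos,
               n_iac = n_iac, n_iad = n_iad, n_both = n_both,
               percent_positive = round_half_up(100 * n_pos / nrow(sub), 2),
               stringsAsFactors = FALSE)
  }
  strata <- sort(unique(as.character(records[[stratify_on]])))
  rows <- lapply(strata, function(s)
    one_row(s, records[records[[stratify_on]] == s, , drop = FALSE]))
  out <- rbind(do.call(rbind, rows), one_row("TOTAL", records))
  rownames(out) <- NULL
  structure(out, class = c("prevalence_table", "data.frame"))
}

#' Long-format per-type prevalence table
#'
#' Reshapes a [prevalence_by_stratum()] result into one row per
#' (stratum, degrader type) with counts and percentages, suitable for
#' stacked-bar plotting.
#'
#' @param tab A `"prevalence_table"`.
#' @return A `data.frame` with columns `stratum`, `degrader_type`,
#'   `n`, `percent`.
#' @export
prevalence_long <- function(tab) {
  stopifnot(inherits(tab, "prevalence_table"))
  types <- c(iac = "n_iac", iad = "n_iad", both = "n_both")
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    data.frame(stratum = tab$stratum[i],
               degrader_type = names(types),
               n = as.integer(unlist(tab[i, types])),
               percent = round_half_up(
                 100 * as.numeric(unlist(tab[i, types])) / tab$n_screened[i], 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Join operon calls with survey metadata
#'
#' Merges a call table with a metadata table by `genome_id`, yielding the
#' per-genome records consumed by [filter_mags()] and
#' [prevalence_by_stratum()].
#'
#' @param calls List of `"operon_call"` objects or a [calls_table()]
#'   `data.frame`.
#' @param metadata A metadata `data.frame` (see [read_metadata()]).
#' @return A `data.frame` with one row per genome present in both inputs.
#' @export
survey_records <- function(calls, metadata) {
  tab <- if (is.data.frame(calls)) calls else calls_table(calls)
  merge(metadata, tab[, c("genome_id", "degrader_type")],
        by = "genome_id", sort = TRUE)
}

#' Read a genome metadata table
#'
#' @param path TSV with columns `genome_id`, `habitat`, `order`,
#'   `completeness`, `contamination`, `source_kind`; `"."` denotes
#'   missing.
#' @return A `data.frame`.
#' @export
read_metadata <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", na.strings = ".",
                           stringsAsFactors = FALSE)
  need <- c("genome_id", "habitat", "order", "completeness",
            "contamination", "source_kind")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("metadata table lacks column(s): ", paste(miss, collapse = ", "))
  tab
}
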