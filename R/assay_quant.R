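#' Fit an IAA standard curve
#'
#' Ordinary least-squares line relating Salkowski OD530 readings to known
#' IAA concentrations (mM). The colorimetric response is linear in the
#' working range, so a straight line through the standards is fitted;
#' two standards give the exact interpolation line.
#'
#' @param concentration Known IAA concentrations (mM), length >= 2 with at
#'   least 2 distinct values.
#' @param od530 Matching OD530 readings.
#' @return List of class `"standard_curve"` with `slope` (OD per mM),
#'   `intercept` (OD at 0 mM) and `r_squared`.
#' @export
fit_standard_curve <- function(concentration, od530) {
  stopifnot(length(concentration) == length(od530))
  if (length(concentration) < 2)
    stop("need at least 2 standards")
  if (length(unique(concentration)) < 2)
    stop("degenerate design: all standard concentrations identical")
  fit <- stats::lm(od530 ~ concentration)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((od530 - mean(od530))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "standard_curve")
}

#' Convert OD530 readings to IAA concentrations
#'
#' Inverts the fitted standard curve. Inferred concentrations below zero
#' (blank-subtraction noise) are clipped to 0 and flagged rather than
#' raising an error.
#'
#' @param od530 Numeric OD530 readings.
#' @param curve A `"standard_curve"` from [fit_standard_curve()].
#' @param blank Optional blank OD530 subtracted from every reading
#'   (default `NULL`, no subtraction).
#' @return Numeric concentrations (mM) with attribute `clipped`, a
#'   logical vector marking readings that inverted below zero.
#' @export
od_to_concentration <- function(od530, curve, blank = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("standard curve has zero slope")
  if (!is.null(blank)) od530 <- od530 - blank
  conc <- (od530 - curve$intercept) / curve$slope
  clipped <- conc < 0
  conc[clipped] <- 0
  attr(conc, "clipped") <- clipped
  conc
}

#' Percent IAA degradation
#'
#' The fraction of the initial IAA consumed, as a percentage:
#' `D = 100 * (c0 - ct) / c0`. Remaining concentrations above the initial
#' one (measurement noise) clip D to 0 and are flagged; negative
#' concentrations are an input error.
#'
#' @param c0 Initial IAA concentration (mM); the screen uses 0.4 mM.
#' @param ct Remaining IAA concentration (mM), same length as `c0` or
#'   scalar-recyclable.
#' @return Percent degradation in `[0, 100]`, with attribute `clipped`
#'   marking values clipped from below zero.
#' @export
percent_degradation <- function(c0, ct) {
  if (any(c0 <= 0)) stop("initial concentration must be positive")
  if (any(ct < 0)) stop("remaining concentration must be non-negative")
  d <- 100 * (c0 - ct) / c0
  clipped <- d < 0
  d[clipped] <- 0
  attr(d, "clipped") <- clipped
  d
}

#' Screen strains for IAA degradation
#'
#' Applies the degrader cutoff to per-strain degradation percentages: a
#' strain is screen-positive when strictly more than 60% of the IAA was
#' consumed (exactly 60% is negative).
#'
#' @param measurements A `data.frame` with columns `strain_id` and
#'   `degradation_pct` (e.g. from [quantify_assay()]).
#' @param cutoff Percent cutoff, strict `>`. Default 60.
#' @return The input with an added logical `screen_positive` column.
#' @export
screen_degraders <- function(measurements, cutoff = 60) {
  stopifnot(is.data.frame(measurements),
            all(c("strain_id", "degradation_pct") %in% names(measurements)))
  measurements$screen_positive <- measurements$degradation_pct > cutoff
  measurements
}

#' Quantify a colorimetric degradation assay
#'
#' Full quantification of one plate: fits the standard curve, averages
#' replicate OD530 readings per strain, converts them to remaining IAA
#' concentrations, computes percent degradation from the initial
#' concentration and applies the screen cutoff.
#'
#' @param plate A `data.frame` with columns `strain_id` and `od530`
#'   (replicate rows allowed).
#' @param standards A `data.frame` with columns `concentration_mM` and
#'   `od530`.
#' @param c0 Initial IAA concentration (mM). Default 0.4.
#' @param blank Optional blank OD530 subtracted from plate readings.
#' @param cutoff Screen cutoff (percent, strict `>`). Default 60.
#' @return A `data.frame` with one row per strain: `strain_id`,
#'   `od530_mean`, `ct_mM`, `degradation_pct`, `screen_positive`.
#' @export
quantify_assay <- function(plate, standards, c0 = 0.4, blank = NULL,
                           cutoff = 60) {
  stopifnot(all(c("strain_id", "od530") %in% names(plate)),
            all(c("concentration_mM", "od530") %in% names(standards)))
  curve <- fit_standard_curve(standards$concentration_mM, standards$od530)
  od <- tapply(plate$od530, plate$strain_id, mean)
  ct <- od_to_concentration(as.numeric(od), curve, blank = blank)
  ct <- pmin(ct, c0)  # consumption cannot be negative
  d <- percent_degradation(c0, as.numeric(ct))
  out <- data.frame(strain_id = names(od), od530_mean = as.numeric(od),
                    ct_mM = as.numeric(ct),
                    degradation_pct = as.numeric(d),
                    stringsAsFactors = FALSE)
  out <- out[order(out$strain_id), , drop = FALSE]
  rownames(out) <- NULL
  screen_degraders(out, cutoff = cutoff)
}

#' Read plate and standards tables
#'
#' @param path TSV file. Plate files need `strain_id`, `od530` (optional
#'   `replicate`, `timepoint`); standards files need `concentration_mM`,
#'   `od530`.
#' @return A `data.frame`.
#' @export
read_plate <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("strain_id", "od530") %in% names(tab)))
    stop("plate table needs strain_id and od530 columns")
  tab
}

#' @rdname read_plate
#' @export
read_standards <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("concentration_mM", "od530") %in% names(tab)))
    stop("standards table needs concentration_mM and od530 columns")
  tab
}
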