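# MTT cytotoxicity arithmetic, screening summaries, disc-diffusion and
# broth-dilution antimicrobial logic.

#' Percent growth inhibition from MTT absorbances
#'
#' Standard blank-subtracted MTT arithmetic:
#' \deqn{\%GI = (1 - (OD_t - OD_b) / (OD_c - OD_b)) \times 100}
#' with treated, control and blank absorbances. The value is dimensionless
#' and invariant under a common affine rescaling of all three readings.
#'
#' @param od_treated,od_control,od_blank Absorbance readings (vectorised).
#' @return Percent growth inhibition; may fall outside `[0, 100]` with noisy
#'   readings.
#' @examples
#' percent_growth_inhibition(0.7, 1.2, 0.2) # 50
#' @export
percent_growth_inhibition <- function(od_treated, od_control, od_blank) {
  if (any(od_control <= od_blank)) {
    stop("od_control must exceed od_blank (no viable control signal)")
  }
  (1 - (od_treated - od_blank) / (od_control - od_blank)) * 100
}

#' Read a percent-growth-inhibition matrix
#'
#' Wide TSV, one row per extract and one column per cell line, cells of the
#' form `"67 ± 1"`. Only the mean enters downstream classification.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix (extracts x cell lines) with an `sd` attribute.
#' @export
read_inhibition_table <- function(path) {
  parsed <- read_assay_matrix(path)
  structure(parsed$value, sd = parsed$sd)
}

#' Cytotoxicity screen summary
#'
#' Counts extracts whose percent growth inhibition strictly exceeds
#' `threshold` on at least one tested cell line ("any-line active") and on
#' every line ("all-line active"), plus per-line counts.
#'
#' @param inhibition Numeric matrix of percent growth inhibition
#'   (extracts x cell lines).
#' @param threshold Activity threshold in percent (strict `>`); default 50.
#' @return List with counts, fractions and the active extract ids.
#' @export
cytotoxic_screen_summary <- function(inhibition, threshold = 50) {
  if (is.null(dim(inhibition)) || nrow(inhibition) == 0 || ncol(inhibition) == 0) {
    stop("empty inhibition matrix")
  }
  hits <- inhibition > threshold
  any_line <- rowSums(hits) >= 1
  all_line <- rowSums(hits) == ncol(hits)
  n <- nrow(inhibition)
  list(n_extracts = n, threshold = threshold,
       any_line_count = sum(any_line), any_line_fraction = sum(any_line) / n,
       all_line_count = sum(all_line), all_line_fraction = sum(all_line) / n,
       per_line_count = colSums(hits),
       any_line_active = rownames(inhibition)[any_line],
       all_line_active = rownames(inhibition)[all_line])
}

#' Read an IC50 table with censoring
#'
#' Wide TSV of IC50 values per extract x cell line; cells like
#' `"38.0 ± 0.08"` or the left-censored `"<10 ± 0.0"` convention (inhibition
#' already above 50\% at the lowest tested concentration).
#'
#' @param path Path to the TSV.
#' @return List of matrices `value` (ug/mL), `sd` and `censor`
#'   (`"none"`/`"lt"`/`"gt"`).
#' @export
read_ic50_table <- function(path) {
  parsed <- read_assay_matrix(path)
  parsed[c("value", "sd", "censor")]
}

#' Count extracts meeting an IC50 activity cutoff
#'
#' An extract is active on a line when its IC50 is strictly below `threshold`;
#' a left-censored value (`"<x"`) counts when its bound is below the
#' threshold. The default 20 ug/mL is the NCI criterion for crude-extract
#' cytotoxicity.
#'
#' @param ic50 A [read_ic50_table()] result, or a list with `value` and
#'   `censor` matrices.
#' @param threshold Cutoff in ug/mL.
#' @return List with per-line counts, the any-line count and active ids.
#' @export
ic50_activity_counts <- function(ic50, threshold = 20) {
  v <- ic50$value; cen <- ic50$censor
  if (is.null(dim(v)) || nrow(v) == 0) stop("empty IC50 table")
  active <- !is.na(v) & ((cen == "none" & v < threshold) |
                         (cen == "lt" & v <= threshold))
  any_line <- rowSums(active) >= 1
  list(n_extracts = nrow(v), threshold = threshold,
       per_line_count = colSums(active),
       any_line_count = sum(any_line),
       any_line_active = rownames(v)[any_line])
}

#' Read a zone-of-inhibition panel
#'
#' Wide TSV of disc-diffusion zone diameters (mm) per extract x pathogen;
#' `"-"` marks no recorded zone (inactive).
#'
#' @param path Path to the TSV.
#' @return Numeric matrix of mean diameters with an `sd` attribute; `NA`
#'   where no zone was recorded.
#' @export
read_zi_table <- function(path) {
  parsed <- read_assay_matrix(path)
  structure(parsed$value, sd = parsed$sd)
}

#' Disc-diffusion screen summary
#'
#' An extract is active against a pathogen iff a zone diameter was recorded;
#' overall activity means at least one recorded zone.
#'
#' @param zi Matrix from [read_zi_table()].
#' @return List with per-pathogen counts/fractions, the overall active count
#'   and ids, and the range of recorded diameters.
#' @export
zi_screen_summary <- function(zi) {
  active <- !is.na(zi)
  overall <- rowSums(active) >= 1
  n <- nrow(zi)
  list(n_extracts = n,
       per_pathogen_count = colSums(active),
       per_pathogen_fraction = colSums(active) / n,
       overall_active_count = sum(overall),
       overall_active_fraction = sum(overall) / n,
       overall_active = rownames(zi)[overall],
       zi_range = if (any(active)) range(zi[active]) else c(NA_real_, NA_real_))
}

#' MIC from a dilution-series growth pattern
#'
#' Applies the broth-dilution reading rule: the MIC is the lowest
#' concentration with no visible growth, provided growth is also absent at
#' every higher concentration. Growth at every concentration is
#' right-censored (`"> max"`); no growth even at the lowest is reported as
#' the lowest concentration with a left-censor note. A non-monotone pattern
#' (growth reappearing above a clear well) is flagged as an invalid well
#' series.
#'
#' @param growth Logical vector, `TRUE` = visible growth, ordered as
#'   `concentrations`.
#' @param concentrations Ascending tested concentrations (ug/mL), e.g.
#'   `c(12.5, 25, 50, 100)`.
#' @return List `(value, censor)` with censor one of `"exact"`,
#'   `"below_min"`, `"above_max"`.
#' @examples
#' mic_from_dilution(c(TRUE, FALSE, FALSE, FALSE), c(12.5, 25, 50, 100))
#' @export
mic_from_dilution <- function(growth, concentrations) {
  if (length(concentrations) == 0) stop("empty concentration series")
  if (length(growth) != length(concentrations)) {
    stop("growth and concentrations differ in length")
  }
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be sorted ascending")
  }
  if (all(growth)) {
    return(list(value = max(concentrations), censor = "above_max"))
  }
  first_clear <- which(!growth)[1]
  if (any(growth[first_clear:length(growth)])) {
    stop("non-monotone growth pattern: growth reappears above a clear well")
  }
  list(value = concentrations[first_clear],
       censor = if (first_clear == 1) "below_min" else "exact")
}

#' Read a MIC/MBC panel
#'
#' Wide TSV per extract x pathogen with entries like `"12.5"`, `">100"`
#' (right-censored: growth at every tested concentration) or
#' `"12.5 (MBC)"` (the concentration was also bactericidal).
#'
#' @param path Path to the TSV.
#' @return List of matrices `value` (ug/mL), `censor` and logical `mbc`.
#' @export
read_mic_table <- function(path) {
  parsed <- read_assay_matrix(path)
  parsed[c("value", "censor", "mbc")]
}

#' Broth-dilution screen summary
#'
#' Counts extracts with at least one uncensored MIC at or below `cutoff`,
#' plus per-pathogen counts. Right-censored entries (`">x"`) never count.
#'
#' @param mic A [read_mic_table()] result.
#' @param cutoff MIC cutoff in ug/mL; default 100 (the top of the usual
#'   crude-extract dilution series).
#' @return List with counts and active extract ids.
#' @export
mic_screen_summary <- function(mic, cutoff = 100) {
  if (cutoff <= 0) stop("cutoff must be positive")
  v <- mic$value; cen <- mic$censor
  active <- !is.na(v) & cen != "gt" & v <= cutoff
  overall <- rowSums(active) >= 1
  list(n_extracts = nrow(v), cutoff = cutoff,
       per_pathogen_count = colSums(active),
       overall_active_count = sum(overall),
       overall_active = rownames(v)[overall],
       mic_range = if (any(active)) range(v[active]) else c(NA_real_, NA_real_))
}
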