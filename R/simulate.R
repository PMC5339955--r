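# Synthetic-data generators. Each generator is a pure function of its
# specification and seed, and emits the same table dialects the analysis
# stages read, so every pipeline stage can be exercised end to end and
# parameter recovery asserted.

#' Simulate a cultured-isolate community
#'
#' Draws, for each tissue, a multinomial sample of isolates from a
#' tissue-specific taxon composition — the sampling structure assumed by the
#' culture-based survey design (isolates are independent draws from the
#' tissue's latent community). Isolate codes follow the `L`/`R`/`F` suffix
#' convention so the records round-trip through [read_isolate_table()]'s
#' tissue inference.
#'
#' @param composition Named list, one element per tissue (`leaf`, `root`,
#'   `flower`), each a named probability vector over taxa (summing to 1).
#' @param n_isolates Named integer vector of isolates to draw per tissue.
#' @param seed Optional integer seed; the same (spec, seed) pair always
#'   yields the identical record list.
#' @return Data frame of isolate records (code, tissue, taxon_label, genus).
#' @examples
#' sim <- simulate_community(list(leaf = c(A = 0.5, B = 0.5)),
#'                           c(leaf = 10), seed = 1)
#' table(sim$taxon_label)
#' @export
simulate_community <- function(composition, n_isolates, seed = NULL) {
  tissues <- names(composition)
  if (is.null(tissues) || !all(tissues %in% c("leaf", "root", "flower"))) {
    stop("composition must be a named list over tissues leaf/root/flower")
  }
  if (!all(tissues %in% names(n_isolates))) stop("n_isolates missing tissue(s)")
  for (t in tissues) {
    p <- composition[[t]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("composition for ", t, " must be named, non-negative and sum to 1")
    }
  }
  suffix <- c(leaf = "L", root = "R", flower = "F")
  with_seed(seed, {
    recs <- lapply(tissues, function(t) {
      n <- n_isolates[[t]]
      if (n == 0) return(NULL)
      draw <- stats::rmultinom(1, n, composition[[t]])[, 1]
      taxa <- rep(names(draw), draw)
      data.frame(isolate_code = paste0("SIM-", seq_along(taxa), suffix[[t]]),
                 tissue = t, taxon_label = taxa, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    if (is.null(out)) stop("no isolates requested")
    out$genus <- genus_of(out$taxon_label)
    rownames(out) <- NULL
    out
  })
}

#' Simulate an MTT plate read-out
#'
#' Generates a long-format optical-density table (treated, control and blank
#' wells) such that [percent_growth_inhibition()] recovers a four-parameter
#' logistic dose-response plus additive Gaussian noise. Noise is applied on
#' the percent-inhibition scale and back-transformed to OD, keeping the truth
#' expressible in the fitted model's units.
#'
#' @param truth Data frame with columns `extract_id`, `cell_line`, `lower`,
#'   `upper`, `hill`, `ic50` (true 4PL parameters per series).
#' @param concentrations Tested concentrations (ug/mL); default
#'   `c(10, 25, 50, 100)`, the usual crude-extract screening range.
#' @param noise_sd Gaussian noise SD on the percent-inhibition scale.
#' @param od_blank,od_signal Blank absorbance and control signal above blank.
#' @param seed Optional integer seed.
#' @return Long data frame: `extract_id`, `cell_line`, `concentration`,
#'   `od_treated`, `od_control`, `od_blank`.
#' @export
simulate_mtt_plate <- function(truth, concentrations = c(10, 25, 50, 100),
                               noise_sd = 0, od_blank = 0.05, od_signal = 1,
                               seed = NULL) {
  need <- c("extract_id", "cell_line", "lower", "upper", "hill", "ic50")
  missing <- setdiff(need, colnames(truth))
  if (length(missing)) stop("truth missing column(s): ", paste(missing, collapse = ", "))
  if (any(truth$ic50 <= 0)) stop("true IC50 must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      gi <- logistic4(concentrations, truth$lower[i], truth$upper[i],
                      truth$hill[i], truth$ic50[i]) +
            stats::rnorm(length(concentrations), 0, noise_sd)
      data.frame(extract_id = truth$extract_id[i], cell_line = truth$cell_line[i],
                 concentration = concentrations,
                 od_treated = od_blank + (1 - gi / 100) * od_signal,
                 od_control = od_blank + od_signal, od_blank = od_blank,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate broth-dilution growth outcomes
#'
#' Generates per-well growth flags from a latent true MIC: growth occurs iff
#' the concentration is below the true MIC (a true MIC of `Inf` grows at
#' every concentration), with an optional per-well misclassification rate.
#' On noise-free output [mic_from_dilution()] returns the true MIC exactly.
#'
#' @param truth Data frame with columns `extract_id`, `pathogen`, `mic`
#'   (true MIC in ug/mL, values from the tested series or `Inf`).
#' @param concentrations Ascending series; default `c(12.5, 25, 50, 100)`.
#' @param misclassification Per-well probability of flipping the growth flag.
#' @param seed Optional integer seed.
#' @return Long data frame: `extract_id`, `pathogen`, `concentration`,
#'   `growth` (logical).
#' @export
simulate_dilution_series <- function(truth, concentrations = c(12.5, 25, 50, 100),
                                     misclassification = 0, seed = NULL) {
  need <- c("extract_id", "pathogen", "mic")
  missing <- setdiff(need, colnames(truth))
  if (length(missing)) stop("truth missing column(s): ", paste(missing, collapse = ", "))
  if (misclassification < 0 || misclassification > 1) {
    stop("misclassification must be in [0, 1]")
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      growth <- concentrations < truth$mic[i]
      if (misclassification > 0) {
        flip <- stats::runif(length(growth)) < misclassification
        growth <- xor(growth, flip)
      }
      data.frame(extract_id = truth$extract_id[i], pathogen = truth$pathogen[i],
                 concentration = concentrations, growth = growth,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
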