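# Orchestration: isolate table -> diversity/similarity/beta; screening
# tables -> cytotoxicity and antimicrobial summaries; deterministic report
# files.

#' Run the full endophyte analysis pipeline
#'
#' Reads the input tables, builds the abundance matrix, computes the alpha
#' diversity table, pairwise similarity, the beta-diversity suite and — when
#' the corresponding screening tables are supplied — the cytotoxicity,
#' IC50, disc-diffusion and broth-dilution summaries.
#'
#' @param isolates Path to the isolate table (required).
#' @param taxonomy Optional path to a genus-level taxonomy map.
#' @param mtt Optional path to a percent-growth-inhibition matrix.
#' @param ic50 Optional path to an IC50 table.
#' @param zi Optional path to a zone-of-inhibition panel.
#' @param mic Optional path to a MIC/MBC panel.
#' @param mode Taxon resolution mode, see [build_abundance_matrix()].
#' @param gi_threshold Cytotoxicity screen threshold (percent, strict `>`).
#' @param nci_cutoff IC50 activity cutoff (ug/mL); 20 is the NCI
#'   crude-extract criterion.
#' @param mic_cutoff MIC activity cutoff (ug/mL).
#' @param gradient_order Optional tissue order for the gradient beta suite
#'   (default: column order of the abundance matrix).
#' @param past_compat Render the diversity table PAST-style (3 decimals,
#'   undefined Fisher's alpha as 0); default full precision.
#' @param verbose Log each stage with row counts.
#' @return An object of class `endodiv_report`: a list of all stage results.
#' @examples
#' rep <- run_pipeline(endodiv_example("monarda_isolates.tsv"),
#'                     taxonomy = endodiv_example("monarda_taxonomy.tsv"))
#' rep$diversity
#' @export
run_pipeline <- function(isolates, taxonomy = NULL, mtt = NULL, ic50 = NULL,
                         zi = NULL, mic = NULL,
                         mode = c("label", "label_per_tissue"),
                         gi_threshold = 50, nci_cutoff = 20, mic_cutoff = 100,
                         gradient_order = NULL, past_compat = FALSE,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(gi_threshold > 0, nci_cutoff > 0, mic_cutoff > 0)
  say <- function(...) if (verbose) message(...)

  records <- read_isolate_table(isolates)
  if (nrow(records) == 0) stop("no records in isolate table")
  say("isolates: ", nrow(records), " records")
  mat <- build_abundance_matrix(records, mode = mode)
  say("abundance matrix: ", nrow(mat), " taxa x ", ncol(mat), " tissues")

  out <- list(
    records = records, matrix = mat, mode = mode,
    diversity = diversity_table(mat, past_compat = past_compat),
    similarity = if (ncol(mat) >= 2) similarity_matrix(mat),
    beta = if (ncol(mat) >= 2) gradient_beta_suite(mat, order = gradient_order),
    params = list(gi_threshold = gi_threshold, nci_cutoff = nci_cutoff,
                  mic_cutoff = mic_cutoff, past_compat = past_compat))

  if (!is.null(taxonomy)) {
    out$class_composition <- class_composition(records, read_taxonomy_map(taxonomy))
  }
  if (!is.null(mtt)) {
    gi <- read_inhibition_table(mtt)
    say("cytotoxicity: ", nrow(gi), " extracts x ", ncol(gi), " cell lines")
    out$cytotoxicity <- cytotoxic_screen_summary(gi, threshold = gi_threshold)
  }
  if (!is.null(ic50)) {
    tab <- read_ic50_table(ic50)
    say("IC50 table: ", nrow(tab$value), " extracts")
    out$ic50 <- ic50_activity_counts(tab, threshold = nci_cutoff)
  }
  if (!is.null(zi)) {
    panel <- read_zi_table(zi)
    say("disc diffusion: ", nrow(panel), " extracts x ", ncol(panel), " pathogens")
    out$zone_inhibition <- zi_screen_summary(panel)
  }
  if (!is.null(mic)) {
    panel <- read_mic_table(mic)
    say("broth dilution: ", nrow(panel$value), " extracts")
    out$mic <- mic_screen_summary(panel, cutoff = mic_cutoff)
  }
  class(out) <- "endodiv_report"
  out
}

#' @export
print.endodiv_report <- function(x, ...) {
  cat("endodiv report —", nrow(x$records), "isolates,", nrow(x$matrix),
      "taxa, mode =", x$mode, "\n\n")
  print(round(as.matrix(x$diversity), 3))
  if (!is.null(x$similarity)) {
    cat("\nSimilarity (upper: Sorensen, lower: Jaccard):\n")
    print(round(x$similarity$grid, 2))
  }
  for (nm in c("cytotoxicity", "ic50", "zone_inhibition", "mic")) {
    if (!is.null(x[[nm]])) {
      s <- x[[nm]]
      cat("\n", nm, ": ",
          if (!is.null(s$all_line_count))
            paste0(s$any_line_count, " any-line / ", s$all_line_count, " all-line active")
          else if (!is.null(s$any_line_count)) paste0(s$any_line_count, " active")
          else paste0(s$overall_active_count, " active"),
          " of ", s$n_extracts, "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes the diversity table, similarity grid, beta summary and screening
#' summaries as tidy TSV files (and optionally a markdown report mirroring
#' the classic table layouts). Output is deterministic: fixed column order,
#' fixed rounding, no timestamps.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"`, `"markdown"` or both.
#' @param digits Decimal places for the rendered values (the TSV long tables
#'   always carry full precision).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, format = c("tsv", "markdown"), digits = 4) {
  stopifnot(inherits(report, "endodiv_report"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }

  if ("tsv" %in% format) {
    div <- report$diversity
    long <- data.frame(index = rep(rownames(div), ncol(div)),
                       tissue = rep(colnames(div), each = nrow(div)),
                       value = unlist(div, use.names = FALSE))
    wtsv(long, "diversity_indices.tsv")
    if (!is.null(report$similarity)) {
      g <- report$similarity
      pairs <- which(upper.tri(g$sorensen), arr.ind = TRUE)
      wtsv(data.frame(tissue_a = rownames(g$sorensen)[pairs[, 1]],
                      tissue_b = colnames(g$sorensen)[pairs[, 2]],
                      sorensen = g$sorensen[pairs], jaccard = g$jaccard[pairs]),
           "similarity.tsv")
    }
    if (!is.null(report$beta)) {
      b <- report$beta
      idx <- c("whittaker_bw", "cody_bc", "wilson_shmida_bt", "mourelle_bM",
               "harrison_b1", "harrison_b2", "williams_bW", "routledge_bR")
      wtsv(data.frame(index = idx, value = vapply(idx, function(f) b[[f]], numeric(1))),
           "beta_diversity.tsv")
    }
    screens <- list(cytotoxicity = report$cytotoxicity, ic50 = report$ic50,
                    zone_inhibition = report$zone_inhibition, mic = report$mic)
    screens <- Filter(Negate(is.null), screens)
    if (length(screens)) {
      rows <- lapply(names(screens), function(nm) {
        s <- screens[[nm]]
        num <- Filter(function(v) is.numeric(v) && length(v) == 1, s)
        data.frame(screen = nm, statistic = names(num),
                   value = unlist(num, use.names = FALSE))
      })
      wtsv(do.call(rbind, rows), "screening_summary.tsv")
    }
  }
  if ("markdown" %in% format) {
    p <- file.path(dir, "report.md")
    md <- c("# Endophyte diversity and bioactivity report", "",
            paste0("Isolates: ", nrow(report$records),
                   "; taxa: ", nrow(report$matrix),
                   "; resolution mode: ", report$mode), "",
            "## Tissue-wise diversity indices", "",
            md_table(round_half_up(as.matrix(report$diversity), digits)))
    if (!is.null(report$similarity)) {
      md <- c(md, "", "## Similarity (upper triangle Sorensen, lower Jaccard)", "",
              md_table(round_half_up(report$similarity$grid, 2)))
    }
    if (!is.null(report$beta)) {
      b <- report$beta
      idx <- c("whittaker_bw", "cody_bc", "wilson_shmida_bt", "mourelle_bM",
               "harrison_b1", "harrison_b2", "williams_bW", "routledge_bR")
      v <- rbind(value = round_half_up(vapply(idx, function(f) b[[f]], numeric(1)), digits))
      md <- c(md, "", "## Beta diversity", "", md_table(v))
    }
    writeLines(md, p, useBytes = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# Minimal markdown renderer for a numeric matrix with dimnames.
md_table <- function(m) {
  header <- c("", colnames(m))
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste0("| ", paste(c(rownames(m)[i], format(m[i, ], trim = TRUE)),
                       collapse = " | "), " |")
  }, character(1))
  c(paste0("| ", paste(header, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"),
    rows)
}
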