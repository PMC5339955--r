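#' Read a cultured-isolate table
#'
#' Parses a TSV/CSV table with one row per cultured endophyte isolate. The
#' required columns are `isolate_code` and `taxon_label`; `tissue`,
#' `accession`, `closest_match` and `identity_pct` are optional. When the
#' `tissue` column is absent, the tissue is inferred from the trailing letter
#' of the isolate code (the common `L`/`R`/`F` suffix convention for leaf,
#' root and flower).
#'
#' @param path Path to the isolate table.
#' @param sep Field separator; guessed from the file extension by default
#'   (`"\t"` for `.tsv`/`.txt`, `","` for `.csv`).
#' @return A data frame of isolate records with columns `isolate_code`,
#'   `tissue`, `taxon_label`, `genus` (first whitespace token of the label),
#'   and any optional columns present.
#' @examples
#' iso <- read_isolate_table(endodiv_example("monarda_isolates.tsv"))
#' table(iso$tissue)
#' @export
read_isolate_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("isolate table not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  required <- c("isolate_code", "taxon_label")
  missing <- setdiff(required, colnames(raw))
  if (length(missing)) {
    stop("isolate table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(data.frame(isolate_code = character(), tissue = character(),
                      taxon_label = character(), genus = character(),
                      stringsAsFactors = FALSE))
  }
  code <- trimws(raw$isolate_code)
  if (anyDuplicated(code)) {
    stop("duplicate isolate_code: ",
         paste(unique(code[duplicated(code)]), collapse = ", "))
  }
  label <- clean_label(raw$taxon_label)
  if (any(label == "")) stop("empty taxon_label in row(s): ",
                             paste(which(label == ""), collapse = ", "))
  tissue <- if ("tissue" %in% colnames(raw)) {
    tolower(trimws(raw$tissue))
  } else {
    infer_tissue_from_code(code)
  }
  bad <- !tissue %in% c("leaf", "root", "flower")
  if (any(bad)) {
    stop("unknown tissue value(s): ", paste(unique(tissue[bad]), collapse = ", "))
  }
  out <- data.frame(isolate_code = code, tissue = tissue, taxon_label = label,
                    genus = genus_of(label), stringsAsFactors = FALSE)
  for (col in c("accession", "closest_match")) {
    if (col %in% colnames(raw)) out[[col]] <- trimws(raw[[col]])
  }
  if ("identity_pct" %in% colnames(raw)) {
    idp <- suppressWarnings(as.numeric(raw$identity_pct))
    if (any(!is.na(idp) & (idp < 0 | idp > 100))) {
      stop("identity_pct outside [0, 100]")
    }
    out$identity_pct <- idp
  }
  out
}

# "MC-20R" -> "root", "MC-14 L" -> "leaf": trailing L/R/F letter convention.
infer_tissue_from_code <- function(code) {
  suffix <- toupper(sub("^.*?([A-Za-z])$", "\\1", trimws(code)))
  map <- c(L = "leaf", R = "root", F = "flower")
  out <- unname(map[suffix])
  if (anyNA(out)) {
    stop("cannot infer tissue from isolate code(s): ",
         paste(code[is.na(out)], collapse = ", "))
  }
  out
}

#' Read a genus-level taxonomy map
#'
#' A TSV with columns `genus`, `order`, `class`, `phylum`, used to roll
#' isolate counts up to higher ranks. Shipped as an editable file rather than
#' hard-coded so users can reproduce alternative genus-to-class readings.
#'
#' @param path Path to the taxonomy TSV.
#' @return A data frame keyed by genus.
#' @export
read_taxonomy_map <- function(path) {
  tm <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  need <- c("genus", "order", "class", "phylum")
  missing <- setdiff(need, colnames(tm))
  if (length(missing)) stop("taxonomy map missing column(s): ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(tm$genus)) stop("taxonomy map has duplicate genus entries")
  tm
}

#' Build a taxon-by-tissue abundance matrix
#'
#' Tabulates isolate records into an integer matrix of counts with one row per
#' taxon and one column per tissue. Taxon identity is controlled by
#' `mode`:
#'
#' * `"label"` (default): taxa are normalised species labels, so the same
#'   label observed in two tissues is one taxon. Label normalisation is
#'   case-insensitive, collapses internal whitespace and strips a trailing
#'   period except in the `sp.`/`spp.` qualifiers.
#' * `"label_per_tissue"`: a taxon is the pair (label, tissue); taxa are never
#'   shared across tissues. This is the resolution implied by software runs
#'   that keep each tissue's species list separate.
#'
#' @param records Data frame of isolate records (see [read_isolate_table()]).
#' @param mode Taxon resolution mode.
#' @return An integer matrix of class `abundance_matrix` with attribute
#'   `resolution_mode`. Column sums equal the per-tissue isolate counts.
#' @examples
#' iso <- read_isolate_table(endodiv_example("monarda_isolates.tsv"))
#' mat <- build_abundance_matrix(iso)
#' colSums(mat)
#' @export
build_abundance_matrix <- function(records, mode = c("label", "label_per_tissue")) {
  mode <- match.arg(mode)
  if (is.null(records) || nrow(records) == 0) stop("no records")
  label <- clean_label(records$taxon_label)
  key <- label_key(label)
  tissues <- unique(records$tissue)
  if (mode == "label_per_tissue") key <- paste(key, records$tissue, sep = "\r")
  # display name = first-seen cleaned label (plus tissue tag in split mode)
  first <- !duplicated(key)
  display <- label[first]
  if (mode == "label_per_tissue") {
    display <- paste0(display, " [", records$tissue[first], "]")
  }
  taxa <- key[first]
  counts <- table(factor(key, levels = taxa), factor(records$tissue, levels = tissues))
  m <- matrix(as.integer(counts), nrow = length(taxa),
              dimnames = list(display, tissues))
  structure(m, resolution_mode = mode, class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("Abundance matrix:", nrow(x), "taxa x", ncol(x), "tissues (",
      sum(x), "isolates ), mode =", attr(x, "resolution_mode"), "\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Relative proportion of one taxon
#'
#' The relative proportion \eqn{P_i = n_i / N} of a taxon: its isolate count
#' pooled over all tissues divided by the total number of isolates.
#'
#' @param matrix An [build_abundance_matrix()] result.
#' @param taxon Taxon label (matched after normalisation).
#' @return A fraction in `[0, 1]`.
#' @export
relative_proportion <- function(matrix, taxon) {
  idx <- match_taxon(matrix, taxon)
  sum(matrix[idx, , drop = FALSE]) / sum(matrix)
}

# Match a user-supplied label against matrix rownames (normalised; the
# per-tissue "[tissue]" tag is ignored so pooled queries work in both modes).
match_taxon <- function(matrix, taxon) {
  rn <- label_key(sub(" \\[[a-z]+\\]$", "", rownames(matrix)))
  idx <- which(rn == label_key(taxon))
  if (!length(idx)) stop("unknown taxon: ", sQuote(taxon))
  idx
}

#' Within-tissue genus frequency
#'
#' Fraction of a tissue's isolates whose genus (first whitespace-delimited
#' token of the taxon label) matches `genus` exactly. Anamorph/teleomorph
#' genera are not merged: `"Gibberella"` is not `"Fusarium"`.
#'
#' @inheritParams relative_proportion
#' @param tissue Tissue (column) name.
#' @param genus Genus name.
#' @return A fraction in `[0, 1]`.
#' @export
genus_frequency <- function(matrix, tissue, genus) {
  if (!tissue %in% colnames(matrix)) stop("unknown tissue: ", sQuote(tissue))
  g <- genus_of(sub(" \\[[a-z]+\\]$", "", rownames(matrix)))
  sum(matrix[tolower(g) == tolower(genus), tissue]) / sum(matrix[, tissue])
}

#' Class-level composition of an isolate collection
#'
#' Rolls isolate counts up to taxonomic class through a genus-level taxonomy
#' map and returns per-class fractions over all isolates (summing to 1).
#'
#' @param records Isolate records.
#' @param taxmap Taxonomy map (see [read_taxonomy_map()]). Every genus in
#'   `records` must be mapped, otherwise an error lists the offenders.
#' @return Named numeric vector of fractions, decreasing.
#' @export
class_composition <- function(records, taxmap) {
  if (nrow(records) == 0) stop("no records")
  genus <- genus_of(records$taxon_label)
  hit <- match(genus, taxmap$genus)
  if (anyNA(hit)) {
    stop("unmapped genus/genera: ", paste(sort(unique(genus[is.na(hit)])), collapse = ", "))
  }
  cls <- taxmap$class[hit]
  tab <- table(cls)
  out <- as.numeric(tab) / length(cls)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}

#' Presence set of a tissue
#'
#' Taxa with a positive count in the given tissue column.
#'
#' @inheritParams genus_frequency
#' @return Character vector of taxon names.
#' @export
presence_set <- function(matrix, tissue) {
  if (!tissue %in% colnames(matrix)) stop("unknown tissue: ", sQuote(tissue))
  rownames(matrix)[matrix[, tissue] > 0]
}
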