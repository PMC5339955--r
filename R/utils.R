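# Internal helpers shared across modules.

# Collapse runs of whitespace, trim, and drop a trailing period unless the
# label ends in the open-nomenclature qualifiers "sp." / "spp.".
clean_label <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  drop_dot <- grepl("\\.$", x) & !grepl("\\bspp?\\.$", x)
  x[drop_dot] <- sub("\\.$", "", x[drop_dot])
  x
}

# Case-insensitive key used for taxon identity under mode = "label".
label_key <- function(x) tolower(clean_label(x))

# First whitespace-delimited token of a (cleaned) taxon label.
genus_of <- function(taxon_label) {
  vapply(strsplit(clean_label(taxon_label), " ", fixed = TRUE),
         function(t) t[[1]], character(1))
}

# Round half away from zero (spreadsheet-style), used by the compat renderer;
# base round() rounds half to even.
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. With seed = NULL the stream is used as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Parse one assay-table cell. Handles "12 ± 0.5", "30", "<10 ± 0.0", ">100",
# "12.5 (MBC)" and the inactive marker "-" (or empty). Returns a list with
# value, sd, censor ("none"/"lt"/"gt") and mbc flag; value is NA for "-".
parse_assay_cell <- function(x) {
  x <- trimws(x)
  if (is.na(x) || x == "" || x == "-") {
    return(list(value = NA_real_, sd = NA_real_, censor = "none", mbc = FALSE))
  }
  mbc <- grepl("\\(MBC\\)", x)
  x <- trimws(gsub("\\(MBC\\)?", "", x))
  censor <- "none"
  if (startsWith(x, "<")) { censor <- "lt"; x <- sub("^<", "", x) }
  if (startsWith(x, ">")) { censor <- "gt"; x <- sub("^>", "", x) }
  parts <- strsplit(x, "±|\\+/-")[[1]]
  value <- suppressWarnings(as.numeric(trimws(parts[[1]])))
  sd <- if (length(parts) > 1) suppressWarnings(as.numeric(trimws(parts[[2]]))) else NA_real_
  if (is.na(value)) stop("cannot parse assay cell: ", sQuote(x), call. = FALSE)
  list(value = value, sd = sd, censor = censor, mbc = mbc)
}

# Read a wide assay table (first column = extract id, remaining columns one
# per cell line / pathogen) and return parallel matrices of parsed fields.
read_assay_matrix <- function(path, sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("assay table needs an id column plus at least one assay column")
  ids <- trimws(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicate extract ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- colnames(raw)[-1]
  parsed <- lapply(raw[-1], function(col) lapply(col, parse_assay_cell))
  pull <- function(field, mode) {
    m <- vapply(parsed, function(col)
      vapply(col, function(cell) cell[[field]], vector(mode, 1)), vector(mode, length(ids)))
    m <- matrix(m, nrow = length(ids), dimnames = list(ids, cols))
    m
  }
  list(value = pull("value", "double"), sd = pull("sd", "double"),
       censor = pull("censor", "character"), mbc = pull("mbc", "logical"))
}

#' Path to a bundled example data file
#'
#' The package ships the isolate survey, taxonomy map and the four screening
#' tables of its worked case study (endophytes of *Monarda citriodora*) as
#' plain TSV files.
#'
#' @param file File name, e.g. `"monarda_isolates.tsv"`. With no argument,
#'   lists the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' endodiv_example()
#' endodiv_example("monarda_isolates.tsv")
#' @export
endodiv_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "endodiv")))
  }
  path <- system.file("extdata", file, package = "endodiv")
  if (path == "") stop("no bundled file called ", sQuote(file))
  path
}
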