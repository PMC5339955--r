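# Presence/absence similarity between assemblages and the multi-sample
# beta-diversity suite (PAST / Koleff-compendium definitions).

#' Presence-overlap decomposition of two assemblages
#'
#' Counts the shared taxa `a = |A intersect B|` and the tissue-specific taxa
#' `b = |A \ B|`, `c = |B \ A|` that parameterise the classical
#' presence/absence similarity coefficients.
#'
#' @param setA,setB Character vectors of taxon names (see [presence_set()]).
#' @return Named integer vector `c(a = , b = , c = )`.
#' @export
pair_decomposition <- function(setA, setB) {
  A <- unique(setA); B <- unique(setB)
  c(a = length(intersect(A, B)), b = length(setdiff(A, B)),
    c = length(setdiff(B, A)))
}

#' Sorensen and Jaccard similarity
#'
#' `QS = 2a / (2a + b + c)` and `JS = a / (a + b + c)`; the identity
#' `JS = QS / (2 - QS)` holds algebraically.
#'
#' @param d A [pair_decomposition()] result (or any vector with elements
#'   `a`, `b`, `c`).
#' @return Named vector `c(sorensen = , jaccard = )`.
#' @export
similarity_indices <- function(d) {
  a <- d[["a"]]; b <- d[["b"]]; cc <- d[["c"]]
  if (a + b + cc == 0) stop("both assemblages are empty")
  c(sorensen = 2 * a / (2 * a + b + cc), jaccard = a / (a + b + cc))
}

#' Pairwise similarity matrices
#'
#' All pairwise Sorensen and Jaccard coefficients between the tissue columns
#' of an abundance matrix, plus a combined grid rendered the way such tables
#' are traditionally printed: Sorensen in the upper triangle, Jaccard in the
#' lower, unit diagonal.
#'
#' @param matrix An [build_abundance_matrix()] result with at least 2 columns.
#' @return List with symmetric matrices `sorensen` and `jaccard` and the
#'   combined `grid`.
#' @export
similarity_matrix <- function(matrix) {
  tissues <- colnames(matrix)
  if (length(tissues) < 2) stop("need at least 2 assemblages")
  k <- length(tissues)
  qs <- js <- diag(1, k)
  dimnames(qs) <- dimnames(js) <- list(tissues, tissues)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- similarity_indices(pair_decomposition(presence_set(matrix, tissues[i]),
                                                 presence_set(matrix, tissues[j])))
      qs[i, j] <- qs[j, i] <- s[["sorensen"]]
      js[i, j] <- js[j, i] <- s[["jaccard"]]
    }
  }
  grid <- js
  grid[upper.tri(grid)] <- qs[upper.tri(qs)]
  list(sorensen = qs, jaccard = js, grid = grid)
}

#' Whittaker's beta diversity
#'
#' \eqn{\beta_w = S/\bar\alpha - 1}, where S is the pooled taxon count under
#' the matrix's resolution mode and \eqn{\bar\alpha} the mean per-assemblage
#' richness. Zero when all assemblages are identical; invariant to sample
#' order.
#'
#' @param matrix An [build_abundance_matrix()] result; every column must
#'   contain at least one taxon.
#' @return Beta diversity (non-negative scalar).
#' @export
whittaker_beta <- function(matrix) {
  rich <- colSums(matrix > 0)
  if (any(rich == 0)) stop("empty assemblage column(s): ",
                           paste(colnames(matrix)[rich == 0], collapse = ", "))
  S <- sum(rowSums(matrix > 0) > 0)
  S / mean(rich) - 1
}

#' Multi-sample beta-diversity suite along a gradient
#'
#' Computes the classical presence/absence beta-diversity indices for `n >= 2`
#' assemblages. Gains `g(H)` and losses `l(H)` are accumulated between
#' consecutive assemblages in `order` (default: column order of the input).
#' Definitions follow the PAST / Koleff compendium:
#' Cody \eqn{\beta_c = (g + l)/2};
#' Wilson-Shmida \eqn{\beta_t = (g + l)/(2\bar\alpha)};
#' Mourelle \eqn{\beta_M = \beta_t/(n-1)};
#' Harrison \eqn{\beta_1 = (S/\bar\alpha - 1)/(n-1)};
#' Harrison 2 \eqn{\beta_2 = (S/\alpha_{max} - 1)/(n-1)};
#' Williams \eqn{\beta_W = 1 - \alpha_{max}/S};
#' Routledge \eqn{\beta_R = S^2/(2r + S) - 1} with `r` the number of
#' unordered taxon pairs co-occurring in at least one assemblage.
#'
#' @param matrix An [build_abundance_matrix()] result (or any non-negative
#'   taxon-by-sample matrix).
#' @param order Character vector: a permutation of the column names giving the
#'   gradient direction. Only the Cody/Wilson-Shmida/Mourelle family depends
#'   on it.
#' @return An object of class `beta_summary`.
#' @examples
#' m <- cbind(A = c(1, 1, 0), B = c(0, 1, 1))
#' rownames(m) <- c("x", "y", "z")
#' gradient_beta_suite(m)
#' @export
gradient_beta_suite <- function(matrix, order = NULL) {
  tissues <- colnames(matrix)
  n <- length(tissues)
  if (n < 2) stop("need at least 2 assemblages")
  if (is.null(order)) order <- tissues
  if (length(order) != n || !setequal(order, tissues) || anyDuplicated(order)) {
    stop("`order` must be a permutation of the sample names")
  }
  pres <- unclass(matrix)[, order, drop = FALSE] > 0
  pres <- pres[rowSums(pres) > 0, , drop = FALSE]
  rich <- colSums(pres)
  if (any(rich == 0)) stop("empty assemblage column(s)")
  S <- nrow(pres)
  abar <- mean(rich)
  amax <- max(rich)
  gl <- 0
  for (i in seq_len(n - 1)) {
    gl <- gl + sum(pres[, i + 1] & !pres[, i]) + sum(pres[, i] & !pres[, i + 1])
  }
  co <- tcrossprod(pres * 1)          # taxa x taxa co-occurrence counts
  r <- sum(co[upper.tri(co)] > 0)
  out <- list(
    S_total = S, alpha_bar = abar, alpha_max = amax, n_samples = n,
    gains_losses = gl, r_overlap = r,
    whittaker_bw = S / abar - 1,
    cody_bc = gl / 2,
    wilson_shmida_bt = gl / (2 * abar),
    mourelle_bM = gl / (2 * abar) / (n - 1),
    harrison_b1 = (S / abar - 1) / (n - 1),
    harrison_b2 = (S / amax - 1) / (n - 1),
    williams_bW = 1 - amax / S,
    routledge_bR = S^2 / (2 * r + S) - 1,
    order = order)
  class(out) <- "beta_summary"
  out
}

#' @export
print.beta_summary <- function(x, digits = 4, ...) {
  cat("Beta diversity over", x$n_samples, "assemblages (gradient:",
      paste(x$order, collapse = " -> "), ")\n")
  cat("  S_total =", x$S_total, ", mean richness =", round(x$alpha_bar, digits),
      ", max richness =", x$alpha_max, "\n")
  idx <- c("whittaker_bw", "cody_bc", "wilson_shmida_bt", "mourelle_bM",
           "harrison_b1", "harrison_b2", "williams_bW", "routledge_bR")
  print(round(vapply(idx, function(f) x[[f]], numeric(1)), digits), ...)
  invisible(x)
}
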