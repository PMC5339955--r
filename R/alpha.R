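# Per-assemblage (alpha) diversity indices. All entropies use natural logs;
# computations run at full precision and any rounding happens only in the
# report renderer.

check_counts <- function(counts) {
  if (length(counts) == 0) stop("empty count vector")
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != floor(counts))) stop("counts must be integers")
  if (sum(counts) == 0) stop("all-zero count vector")
  counts[counts > 0]
}

#' Shannon diversity H'
#'
#' \eqn{H' = -\sum p_i \ln p_i} over taxa with positive counts (natural log).
#'
#' @param counts Non-negative integer vector of per-taxon abundances.
#' @return Entropy in nats.
#' @examples
#' shannon_entropy(rep(1, 18)) # = log(18)
#' @export
shannon_entropy <- function(counts) {
  n <- check_counts(counts)
  p <- n / sum(n)
  -sum(p * log(p))
}

#' Simpson dominance D and diversity 1 - D
#'
#' The plug-in form \eqn{D = \sum p_i^2} (not the finite-sample unbiased
#' estimator), so two equally abundant taxa give exactly D = 0.5.
#'
#' @inheritParams shannon_entropy
#' @return Named vector `c(D = , one_minus_D = )`.
#' @export
simpson_dominance <- function(counts) {
  n <- check_counts(counts)
  p <- n / sum(n)
  D <- sum(p^2)
  c(D = D, one_minus_D = 1 - D)
}

#' Menhinick, Camargo and Margalef richness indices
#'
#' \eqn{D_{mn} = S/\sqrt{N}}, Camargo's species richness \eqn{1/D_{mn}}, and
#' \eqn{D_{mg} = (S-1)/\ln N} (0 when N = 1, by convention).
#'
#' @inheritParams shannon_entropy
#' @return Named vector `c(menhinick = , camargo = , margalef = )`.
#' @export
richness_indices <- function(counts) {
  n <- check_counts(counts)
  S <- length(n); N <- sum(n)
  dmn <- S / sqrt(N)
  dmg <- if (N == 1) 0 else (S - 1) / log(N)
  c(menhinick = dmn, camargo = 1 / dmn, margalef = dmg)
}

#' Brillouin index
#'
#' \eqn{HB = (\ln N! - \sum \ln n_i!)/N}, evaluated with log-gamma so large
#' samples cannot overflow the factorials.
#'
#' @inheritParams shannon_entropy
#' @return Index in nats; always `<=` Shannon H'.
#' @export
brillouin_index <- function(counts) {
  n <- check_counts(counts)
  N <- sum(n)
  (lgamma(N + 1) - sum(lgamma(n + 1))) / N
}

#' Evenness and equitability
#'
#' Evenness \eqn{e^{H'}/S} and Pielou's equitability \eqn{J = H'/\ln S}
#' (J defined as 1 when S = 1).
#'
#' @inheritParams shannon_entropy
#' @return Named vector `c(evenness = , equitability = )`, both in `(0, 1]`.
#' @export
evenness_measures <- function(counts) {
  n <- check_counts(counts)
  S <- length(n)
  H <- shannon_entropy(n)
  J <- if (S == 1) 1 else H / log(S)
  c(evenness = exp(H) / S, equitability = J)
}

#' Berger-Parker dominance
#'
#' \eqn{d = \max(n_i)/N}, the proportional abundance of the single most
#' abundant taxon.
#'
#' @inheritParams shannon_entropy
#' @export
berger_parker <- function(counts) {
  n <- check_counts(counts)
  max(n) / sum(n)
}

#' Chao-1 richness estimate
#'
#' Bias-corrected Chao-1, \eqn{S + F_1(F_1 - 1) / (2 (F_2 + 1))} with
#' \eqn{F_1} singletons and \eqn{F_2} doubletons; equals the observed richness
#' when there are no singletons.
#'
#' @inheritParams shannon_entropy
#' @return Named vector `c(chao1 = , F1 = , F2 = )`; `chao1 >= S` always.
#' @export
chao1_estimate <- function(counts) {
  n <- check_counts(counts)
  S <- length(n)
  F1 <- sum(n == 1); F2 <- sum(n == 2)
  c(chao1 = S + F1 * (F1 - 1) / (2 * (F2 + 1)), F1 = F1, F2 = F2)
}

#' Fisher's log-series alpha
#'
#' The unique \eqn{\alpha > 0} solving \eqn{S = \alpha \ln(1 + N/\alpha)},
#' found by bracketed root-finding and polished with Newton steps until the
#' residual is below 1e-9. When every individual is a distinct taxon
#' (\eqn{S = N}) the equation has no finite solution and `NA` is returned as
#' an explicit "undefined" marker; the compat report renderer prints it as 0,
#' matching the convention of the PAST desktop program.
#'
#' @param S Observed taxon count (`1 <= S <= N`).
#' @param N Number of individuals.
#' @return Alpha, or `NA_real_` when S = N.
#' @examples
#' fisher_alpha(6, 8)
#' fisher_alpha(18, 18) # undefined
#' @export
fisher_alpha <- function(S, N) {
  if (S < 1) stop("S must be at least 1")
  if (S > N) stop("S cannot exceed N")
  if (S == N) return(NA_real_)
  f <- function(a) a * log1p(N / a) - S
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  root <- stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
  # Newton polish: f'(a) = log1p(N/a) - N/(a + N)
  for (i in 1:8) {
    r <- f(root)
    if (abs(r) < 1e-12) break
    root <- root - r / (log1p(N / root) - N / (root + N))
  }
  root
}

#' Full alpha-diversity profile of one assemblage
#'
#' Computes every per-assemblage statistic in one pass: S, N, proportions,
#' Simpson's D and 1 - D, Shannon H', Brillouin, Menhinick, Camargo, Margalef,
#' evenness, equitability, Fisher's alpha, Berger-Parker dominance and the
#' bias-corrected Chao-1 with its singleton/doubleton counts.
#'
#' @inheritParams shannon_entropy
#' @return An object of class `alpha_profile` (a named list).
#' @examples
#' alpha_profile(c(3, 1, 1, 1, 1, 1))
#' @export
alpha_profile <- function(counts) {
  n <- check_counts(counts)
  S <- length(n); N <- sum(n)
  simp <- simpson_dominance(n)
  rich <- richness_indices(n)
  even <- evenness_measures(n)
  chao <- chao1_estimate(n)
  out <- list(
    S = S, N = N, p_i = n / N,
    simpson_D = unname(simp["D"]), simpson_1mD = unname(simp["one_minus_D"]),
    shannon_H = shannon_entropy(n), brillouin_HB = brillouin_index(n),
    menhinick_Dmn = unname(rich["menhinick"]),
    camargo_inv_Dmn = unname(rich["camargo"]),
    margalef_Dmg = unname(rich["margalef"]),
    evenness_eHS = unname(even["evenness"]),
    equitability_J = unname(even["equitability"]),
    fisher_alpha = fisher_alpha(S, N),
    berger_parker_d = berger_parker(n),
    chao1 = unname(chao["chao1"]), F1 = unname(chao["F1"]), F2 = unname(chao["F2"]))
  class(out) <- "alpha_profile"
  out
}

#' @export
print.alpha_profile <- function(x, digits = 4, ...) {
  cat("Alpha diversity profile: S =", x$S, ", N =", x$N, "\n")
  flds <- c("simpson_D", "simpson_1mD", "shannon_H", "brillouin_HB",
            "menhinick_Dmn", "camargo_inv_Dmn", "margalef_Dmg", "evenness_eHS",
            "equitability_J", "fisher_alpha", "berger_parker_d", "chao1")
  v <- vapply(flds, function(f) x[[f]], numeric(1))
  print(round(v, digits), ...)
  invisible(x)
}

#' Tissue-wise diversity index table
#'
#' Applies [alpha_profile()] to every column of an abundance matrix and lays
#' the indices out as a classic diversity-summary table (indices as rows,
#' assemblages as columns).
#'
#' @param matrix An [build_abundance_matrix()] result.
#' @param past_compat If `TRUE`, render like the PAST desktop program:
#'   undefined Fisher's alpha printed as 0 and values rounded half-away-
#'   from-zero to 3 decimals. Default is full precision.
#' @return A data frame with one row per index.
#' @export
diversity_table <- function(matrix, past_compat = FALSE) {
  profs <- apply(unclass(matrix), 2, alpha_profile, simplify = FALSE)
  rows <- c(Taxa_S = "S", Individuals = "N",
            "Simpson_D" = "simpson_D", "Simpson_1-D" = "simpson_1mD",
            "Shannon_H" = "shannon_H", "Evenness_e^H/S" = "evenness_eHS",
            Brillouin = "brillouin_HB", "Menhinick" = "menhinick_Dmn",
            "Margalef" = "margalef_Dmg", "Equitability_J" = "equitability_J",
            "Fisher_alpha" = "fisher_alpha", "Berger-Parker" = "berger_parker_d",
            "Chao-1" = "chao1")
  tab <- vapply(profs, function(p) vapply(rows, function(f) p[[f]], numeric(1)),
                numeric(length(rows)))
  tab <- matrix(tab, nrow = length(rows),
                dimnames = list(names(rows), colnames(matrix)))
  if (past_compat) {
    tab[is.na(tab)] <- 0
    tab <- round_half_up(tab, 3)
  }
  as.data.frame(tab)
}
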