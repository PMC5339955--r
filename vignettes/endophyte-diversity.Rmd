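---
title: "Methods: tissue-wise endophyte diversity and bioactivity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-wise endophyte diversity and bioactivity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endodiv)
```

## The problem

Culture-based endophyte surveys produce a small, fully enumerated community
sample: every isolate that grew from a surface-sterilised tissue fragment is
identified (typically to a species-level label via ITS sequencing) and
recorded with its tissue of origin. Two questions follow. First, how diverse
is the fungal assemblage of each tissue, and how strongly do tissues differ
in their communities? Second, which of the cultured isolates produce
extracts with cytotoxic or antimicrobial activity? This package implements
both analysis arms as a reusable, tested pipeline, together with a
synthetic-data module that emulates the sampling structure of each assay so
that the whole chain can be validated without any external data.

The bundled worked example is a survey of 28 fungal endophytes cultured from
leaf, root and flower tissue of the horsemint *Monarda citriodora*, with its
accompanying MTT cytotoxicity, IC50, disc-diffusion and broth-dilution
screening tables.

## Taxon identity: the one genuinely open design choice

Everything downstream of the isolate table depends on when two isolates
count as the same taxon. The package makes this explicit through a
resolution mode on `build_abundance_matrix()`:

* **`label`** (default): taxa are normalised species labels. Normalisation
  is case-insensitive, collapses internal whitespace and strips a trailing
  period except in the open-nomenclature qualifiers `sp.`/`spp.`. Under this
  mode a label observed in two tissues is a single taxon, which is the
  reading required by pairwise similarity (the bundled survey's leaf and
  root assemblages share exactly one taxon, *Cladosporium* sp., giving
  Sorensen 0.1 and Jaccard 0.05).
* **`label_per_tissue`**: a taxon is the pair (label, tissue), so taxa are
  never shared across tissues. Some published beta-diversity figures for
  surveys of this kind are only explicable if each tissue's species list was
  kept separate, so the mode is first-class rather than a hack.

Genus-level statistics always use the first whitespace-delimited token of
the label, and never merge anamorph/teleomorph pairs (*Gibberella* is not
*Fusarium*, *Neosartorya* is not *Aspergillus*). The genus-to-class map is
shipped as an editable TSV rather than hard-coded, because published class
tallies for such surveys are not always internally consistent and users must
be able to reproduce either reading; with the bundled map the example survey
splits 50% Sordariomycetes / 25% Dothideomycetes / 25% Eurotiomycetes.

## Alpha diversity

All indices are computed from a single integer count vector at full
precision, with natural logarithms throughout:

* Shannon \(H' = -\sum p_i \ln p_i\); evenness \(e^{H'}/S\); Pielou's
  equitability \(J = H'/\ln S\) (defined as 1 when \(S = 1\)).
* Simpson dominance in the plug-in form \(D = \sum p_i^2\), not the
  finite-sample estimator \(\sum n_i(n_i-1)/(N(N-1))\). The choice matters
  for tiny assemblages: two singleton taxa give \(D = 0.5\) under the
  plug-in form and 0 under the unbiased one; only the former matches the
  desktop-software convention this package renders.
* Brillouin \((\ln N! - \sum \ln n_i!)/N\) through `lgamma()`, so counts in
  the millions cannot overflow.
* Menhinick \(S/\sqrt N\), Camargo's richness \(1/D_{mn}\), Margalef
  \((S-1)/\ln N\) (0 at \(N = 1\) by convention), Berger–Parker
  \(\max n_i/N\).
* Chao-1 in the bias-corrected form \(S + F_1(F_1-1)/(2(F_2+1))\). With no
  doubletons this stays finite (the classic \(F_1^2/2F_2\) form does not),
  and it reproduces the estimate 171 for an assemblage of 18 singletons.
* Fisher's log-series \(\alpha\), the root of \(S = \alpha\ln(1+N/\alpha)\),
  found by bracketed `uniroot()` with Newton polishing to a residual below
  \(10^{-9}\) (the tests verify \(10^{-12}\) in practice and cross-check an
  independent bisection oracle and `vegan::fisher.alpha`). When \(S = N\)
  the equation has no finite root; the package returns `NA` as an explicit
  "undefined" marker rather than a large number.

`diversity_table()` lays the indices out in the classic summary layout. Its
`past_compat` mode mimics the PAST desktop program's rendering — undefined
Fisher's alpha printed as 0, values rounded half-away-from-zero to three
decimals — because that is the form in which reference values for such
surveys are usually published. Comparisons against published tables in the
test-suite allow one unit in the printed last decimal place, since printed
values of this provenance are sometimes truncated rather than rounded
(0.055 for 1/18, 0.346 for \(\ln 2/2\)).

## Similarity and beta diversity

Pairwise similarity uses the presence-overlap decomposition
\(a, b, c\) and the printed-formula coefficients
\(QS = 2a/(2a+b+c)\), \(JS = a/(a+b+c)\); the identity \(JS = QS/(2-QS)\) is
enforced by a property test. The rendered grid follows the traditional
layout with Sorensen in the upper triangle and Jaccard in the lower — the
assignment that is arithmetically consistent for the bundled survey.

The multi-sample suite follows the PAST/Koleff-compendium definitions:
Whittaker \(\beta_w = S/\bar\alpha - 1\); Cody \((g+l)/2\) and
Wilson–Shmida \((g+l)/(2\bar\alpha)\) accumulated along a declared gradient
order (default: the column order of the matrix, since surveys of this kind
rarely state a gradient); Mourelle \(\beta_t/(n-1)\); Harrison
\(\beta_w/(n-1)\); Harrison 2 \((S/\alpha_{max}-1)/(n-1)\); Williams
\(1-\alpha_{max}/S\); Routledge \(S^2/(2r+S)-1\) with \(r\) the number of
taxon pairs co-occurring in at least one sample (checked against a
brute-force double loop).

**Known limitation.** Published global beta-diversity listings for
small tissue surveys are frequently irreproducible from the accompanying
isolate table: the value sets are often mutually consistent only with a
taxon list in which cross-tissue duplicates were partially merged, and with
the taxon-by-tissue matrix fed to desktop software in transposed
orientation (taxa treated as the "samples" of the gradient). For the bundled
survey, the package's two resolution modes give Whittaker 1.6538 (`label`,
23 pooled taxa) and 2.0 (`label_per_tissue`, 26), bracketing the published
1.7692, which corresponds to a 24-taxon list no uniform resolution rule
produces. The beta suite is therefore validated against hand-enumerated
toys and internal invariants, not against published global values.

## Cytotoxicity screening

Percent growth inhibition uses blank-subtracted MTT arithmetic,
\(\%GI = (1-(OD_t-OD_b)/(OD_c-OD_b))\times 100\), which is invariant under a
common affine rescaling of the three readings. The activity screen applies a
strict `>` at 50% (an extract exactly at threshold is inactive), counting
extracts active on at least one and on all tested cell lines.

IC50 estimation fits the four-parameter logistic
\(y(c) = lower + (upper-lower)/(1+(IC50/c)^{hill})\) by Levenberg–Marquardt
least squares on log-concentration. The optimiser is called directly
(`minpack.lm::nls.lm`) because the `nls`-object wrapper cannot represent the
exactly determined, zero-residual fits that arise with four observations and
four parameters. Censoring is decided before fitting, from the data at the
extremes of the tested range (10–100 µg/mL by default): at least 50%
inhibition already at the lowest tested concentration reports "< min"
(`below_min`), below 50% at the highest reports "> max" (`above_max`) —
the conventions used in published screening tables. If the fit fails, the
estimate falls back to log-linear interpolation between the two points
bracketing 50%. Parameter bounds (hill in [0.05, 20], asymptotes in
[-100, 49] and [51, 250]) keep the optimiser away from degenerate plateaus
without constraining realistic curves. Activity counting uses the NCI
crude-extract criterion, IC50 < 20 µg/mL, with left-censored bounds counting
when the bound itself is under the cutoff.

## Antimicrobial screening

Disc-diffusion activity is purely presence-based: an extract is active
against a pathogen iff a zone diameter was recorded ("-" means no zone), and
"±" cells are parsed as mean ± sd with only the mean classified. The
broth-dilution reader implements the standard rule — MIC is the lowest
concentration with no visible growth provided all higher concentrations are
also clear; growth everywhere right-censors at the top of the series
("> 100"); clarity even at the bottom left-censors at the lowest tested
concentration; growth reappearing above a clear well is flagged as an
invalid series rather than silently interpreted. `"(MBC)"` annotations are
carried as a boolean flag without separate arithmetic. The screen counts
extracts with at least one uncensored MIC at or below the cutoff
(default 100 µg/mL, the top of the usual crude-extract series).

## The synthetic-data module

The generators are pure functions of (specification, seed) and emit exactly
the table dialects the analysis stages read:

* `simulate_community()` draws, per tissue, a multinomial sample from a
  tissue-specific taxon composition — the sampling model implicit in
  culture-based surveys (isolates as independent draws from a latent
  community). Isolate codes carry the `L`/`R`/`F` suffix so records
  round-trip through the reader's tissue inference.
* `simulate_mtt_plate()` generates OD triples whose
  `percent_growth_inhibition()` equals a chosen 4PL curve plus additive
  Gaussian noise on the percent scale (back-transformed to OD, keeping the
  truth in the fitted model's units). Default concentrations 10, 25, 50,
  100 µg/mL.
* `simulate_dilution_series()` produces growth flags from a latent true MIC
  over the series 12.5–100 µg/mL, with an optional per-well
  misclassification rate.

What the generators deliberately do **not** emulate: taxonomic
misidentification, culture bias (taxa that never grow on the isolation
medium), plate-position effects, or correlated noise across wells. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated sampling models, not robustness to those real-data pathologies.

Test problem sizes were chosen to make sampling noise negligible relative to
the asserted tolerances while keeping the default suite fast: 10,000
isolates per tissue for the multinomial-frequency check (3 binomial SEs),
5,000 isolates for end-to-end Shannon recovery within 2% of \(\ln 50\), 200
simulated dose-response curves at 2% noise for the IC50 recovery bound
(median relative error below 5%), and 1,000 wells for the misclassification
rate check.

## Numerical conventions

* Rounding for display uses half-away-from-zero (spreadsheet convention),
  never `round()`'s banker's rounding; all computation is full precision.
* Count screens use strict `>` for cytotoxicity (per the ">50%" phrasing
  such screens report) and `<=` for MIC cutoffs (MIC values are themselves
  "lowest concentration" statements).
* Degenerate inputs fail loudly: all-zero count vectors, empty assemblage
  columns, non-monotone dilution patterns, unmapped genera and unknown
  tissues are errors listing the offenders, not silent `NA`s.
* Reports are byte-deterministic: fixed column order, fixed rounding, no
  timestamps, and every stochastic stage takes an explicit seed.
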