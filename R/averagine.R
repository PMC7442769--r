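#' @include constants.R
NULL

#' Averagine composition and average mass
#'
#' The averagine model represents a peptide of `n` residues by `n` copies of
#' an "average" amino acid with elemental composition
#' C4.9384 H7.7583 N1.3577 O1.4773 S0.0417. The composition scales linearly
#' with residue count; no water term is added, since only the envelope shape
#' (not the absolute mass) is used downstream.
#'
#' @param n_residues Number of residues (non-negative).
#' @return `averagineComposition`: named numeric vector of (fractional)
#'   element counts. `averagineAverageMass`: average molecular mass in Da
#'   (one averagine unit is about 111.125 Da).
#' @examples
#' averagineComposition(1)
#' averagineAverageMass(1)
#' @export
averagineComposition <- function(n_residues) {
  if (length(n_residues) != 1L || is.na(n_residues) || n_residues < 0)
    stop("n_residues must be a single non-negative number")
  n_residues * AVERAGINE_COMPOSITION
}

#' @rdname averagineComposition
#' @export
averagineAverageMass <- function(n_residues) {
  comp <- averagineComposition(n_residues)
  sum(comp * AVERAGE_ATOMIC_MASS[names(comp)])
}

## linear convolution of two intensity vectors (offset polynomials)
.convolve <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

## distribution of n iid copies of `dist` via exponentiation by squaring
.convolvePower <- function(dist, n) {
  result <- 1
  base <- dist
  while (n > 0L) {
    if (n %% 2L == 1L) result <- .convolve(result, base)
    base <- .convolve(base, base)
    n <- n %/% 2L
  }
  result
}

#' Aggregate isotope distribution of an elemental composition
#'
#' Computes the isotope envelope over nominal mass offsets 0..K by
#' element-wise multinomial convolution using standard terrestrial isotope
#' abundances. Fractional element counts (as produced by
#' [averagineComposition()]) are rounded half-up to integers first. The full
#' distribution is computed, then truncated to `max_peaks` entries and
#' renormalized to sum 1.
#'
#' @param composition Named numeric vector of element counts (subset of
#'   C, H, N, O, S).
#' @param max_peaks Number of isotopologue peaks to return (default 5).
#' @return Numeric vector of length <= `max_peaks`; entry 1 is the
#'   monoisotopic peak; entries sum to 1.
#' @examples
#' isotopeDistribution(c(C = 2))           # binomial in the 13C abundance
#' isotopeDistribution(averagineComposition(10))
#' @export
isotopeDistribution <- function(composition, max_peaks = 5L) {
  if (max_peaks < 1L) stop("max_peaks must be at least 1")
  bad <- setdiff(names(composition), names(ISOTOPE_ABUNDANCE))
  if (length(bad))
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  if (any(composition < 0)) stop("element counts must be non-negative")
  counts <- floor(composition + 0.5)     # round half-up
  counts <- counts[counts > 0]
  if (!length(counts)) return(1)
  dist <- 1
  for (el in names(counts))
    dist <- .convolve(dist, .convolvePower(ISOTOPE_ABUNDANCE[[el]],
                                           as.integer(counts[el])))
  dist <- dist[seq_len(min(length(dist), max_peaks))]
  dist / sum(dist)
}

#' Pearson correlation of an observed envelope with a theoretical one
#'
#' Aligns the observed and theoretical envelopes by isotope index and
#' computes the Pearson correlation over the first
#' `min(length(observed), length(theoretical), max_peaks)` entries. Pearson
#' correlation is scale-invariant, so raw intensities are compared directly.
#' At least `min_peaks` aligned entries are required (r over 2 points is
#' always +-1 and carries no information) and the observed entries must not
#' be constant.
#'
#' @param observed Numeric vector of observed isotopologue intensities
#'   (monoisotopic first).
#' @param theoretical Numeric vector of theoretical intensities, e.g. from
#'   [isotopeDistribution()].
#' @param max_peaks Cap on compared peaks (default 5).
#' @param min_peaks Minimum aligned peaks (default 3).
#' @return Pearson r in `[-1, 1]`.
#' @examples
#' theo <- isotopeDistribution(averagineComposition(12))
#' ms1Correlation(theo * 1e6, theo)  # exactly 1
#' @export
ms1Correlation <- function(observed, theoretical, max_peaks = 5L,
                           min_peaks = 3L) {
  k <- min(length(observed), length(theoretical), max_peaks)
  if (k < min_peaks)
    stop("undefined correlation: fewer than ", min_peaks, " aligned peaks")
  obs <- observed[seq_len(k)]
  theo <- theoretical[seq_len(k)]
  if (stats::sd(obs) == 0 || stats::sd(theo) == 0)
    stop("undefined correlation: constant envelope")
  stats::cor(obs, theo)
}
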