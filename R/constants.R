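#' Physical constants and mass tables
#'
#' Monoisotopic residue masses of the 20 canonical amino acids (Da), the
#' monoisotopic mass of water and of a proton, standard average atomic
#' masses, the averagine elemental composition per residue, and standard
#' terrestrial isotope abundances. All values are the field-standard
#' constants used throughout bottom-up proteomics mass arithmetic.
#'
#' `AVERAGINE_COMPOSITION` is the model "average" amino acid
#' C4.9384 H7.7583 N1.3577 O1.4773 S0.0417 with an average molecular mass of
#' about 111.125 Da; theoretical isotope envelopes of a peptide are built
#' from its residue count alone by scaling this composition.
#'
#' @format Named numeric vectors (`RESIDUE_MONO_MASS`, `AVERAGE_ATOMIC_MASS`,
#'   `AVERAGINE_COMPOSITION`) and a named list of numeric vectors
#'   (`ISOTOPE_ABUNDANCE`, intensity per nominal mass offset 0, 1, 2, ...).
#' @name mass-constants
#' @aliases RESIDUE_MONO_MASS AVERAGE_ATOMIC_MASS AVERAGINE_COMPOSITION
#'   ISOTOPE_ABUNDANCE MASS_WATER MASS_PROTON
NULL

#' @rdname mass-constants
#' @export
RESIDUE_MONO_MASS <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @rdname mass-constants
#' @export
MASS_WATER <- 18.010565

#' @rdname mass-constants
#' @export
MASS_PROTON <- 1.007276

#' @rdname mass-constants
#' @export
AVERAGE_ATOMIC_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                         S = 32.06)

#' @rdname mass-constants
#' @export
AVERAGINE_COMPOSITION <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773,
                           S = 0.0417)

#' @rdname mass-constants
#' @export
ISOTOPE_ABUNDANCE <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9495, 0.0075, 0.0429, 0, 0.0001)
)

## valid protein database categories
PROTEIN_CATEGORIES <- c("host", "drug_substance", "standard_protein",
                        "standard_peptide", "trypsin", "protein_a",
                        "keratin_contaminant", "decoy")

## fraction labels used by run metadata
FRACTION_LEVELS <- c("direct", "flow_through", "wash")
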