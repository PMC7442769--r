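#' @include constants.R formats.R
NULL

#' In silico tryptic digestion
#'
#' Cleaves an amino-acid sequence after K or R except when the next residue
#' is P, and emits all fragments with up to `max_missed_cleavages` internal
#' uncleaved sites. The fragments with 0 missed cleavages partition the
#' sequence: their in-order concatenation reconstructs the input.
#'
#' @param sequence Single amino-acid string (canonical letters).
#' @param max_missed_cleavages Maximum internal missed cleavage sites
#'   (default 2).
#' @return data.frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`.
#' @examples
#' trypticDigest("AAAKCCCR", 0)$sequence
#' trypticDigest("AAAKPCCCR", 0)$sequence  # K before P is not cleaved
#' @export
trypticDigest <- function(sequence, max_missed_cleavages = 2L) {
  stopifnot(length(sequence) == 1L)
  if (is.na(sequence) || !nzchar(sequence)) stop("empty sequence")
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), names(RESIDUE_MONO_MASS))
  if (length(bad))
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  n <- length(res)
  ## cut after position i when residue i is K/R and i+1 is not P
  cuts <- which(res %in% c("K", "R"))
  cuts <- cuts[cuts < n & res[pmin(cuts + 1L, n)] != "P"]
  bounds <- c(0L, cuts, n)              # fragment i spans bounds[i]+1..bounds[i+1]
  nfrag <- length(bounds) - 1L
  out <- vector("list", max_missed_cleavages + 1L)
  for (mc in 0:max_missed_cleavages) {
    i <- seq_len(nfrag - mc)
    if (!length(i)) break
    start <- bounds[i] + 1L
    end <- bounds[i + mc + 1L]
    out[[mc + 1L]] <- data.frame(
      sequence = substring(sequence, start, end),
      start = start, end = end, missed_cleavages = mc,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass: sum of residue masses plus water plus any
#' modification mass deltas. Vectorized over sequences.
#'
#' @param sequence Character vector of peptide sequences.
#' @param modifications Either a numeric vector of total modification deltas
#'   (Da, recycled), a character vector of modification strings (see
#'   [parseMods()]), or `NULL` for unmodified.
#' @return Numeric vector of neutral monoisotopic masses (Da).
#' @examples
#' peptideMass("G")                        # 75.03203
#' peptideMass("C", "1:57.02146:Carbamidomethyl")
#' @export
peptideMass <- function(sequence, modifications = NULL) {
  delta <- if (is.null(modifications)) 0
           else if (is.character(modifications)) modsDelta(modifications)
           else as.numeric(modifications)
  base <- vapply(sequence, function(s) {
    res <- strsplit(s, "")[[1]]
    m <- RESIDUE_MONO_MASS[res]
    if (anyNA(m))
      stop("unknown residue letter(s) in '", s, "': ",
           paste(unique(res[is.na(m)]), collapse = ", "))
    sum(m) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
  base + rep_len(delta, length(base))
}

#' m/z from neutral mass
#'
#' Standard positive electrospray convention:
#' `(neutral_mass + charge * proton) / charge`, proton mass 1.007276 Da.
#'
#' @param neutral_mass Neutral mass (Da), vectorized.
#' @param charge Positive integer charge state, vectorized.
#' @return m/z in Th.
#' @examples
#' mzFromMass(1000, 2)  # 501.007276
#' @export
mzFromMass <- function(neutral_mass, charge) {
  if (any(charge < 1)) stop("charge must be at least 1")
  (neutral_mass + charge * MASS_PROTON) / charge
}

#' Map peptide uniqueness against a database
#'
#' A peptide is assigned to every database entry whose sequence contains it
#' as a contiguous substring; it is *unique* when exactly one entry matches.
#' Decoy entries are excluded unless `include_decoys = TRUE` (used during
#' target-decoy inference, where decoy peptides must map to decoy entries).
#'
#' @param peptides Character vector of peptide sequences.
#' @param database A [ProteinDatabase-class].
#' @param include_decoys Keep decoy entries in the mapping (default FALSE).
#' @return data.frame with columns `peptide`, `n_proteins`, `is_unique` and
#'   a list-column `proteins` of matching accessions. Peptides absent from
#'   all entries get an empty protein set.
#' @examples
#' db <- ProteinDatabase(c("A", "B"), c("XXPEPTKYY", "ZZPEPTKQQ"))
#' mapUniqueness(c("PEPTK", "XXPEPTK"), db)
#' @export
mapUniqueness <- function(peptides, database, include_decoys = FALSE) {
  stopifnot(is(database, "ProteinDatabase"))
  if (length(database) == 0L) stop("database is empty")
  keep <- if (include_decoys) rep(TRUE, length(database))
          else category(database) != "decoy"
  seqs <- as.character(sequences(database))[keep]
  accs <- accession(database)[keep]
  peptides <- as.character(peptides)
  prot <- lapply(peptides, function(p) {
    if (!nzchar(p)) return(character())
    accs[grepl(p, seqs, fixed = TRUE)]
  })
  data.frame(peptide = peptides, n_proteins = lengths(prot),
             is_unique = lengths(prot) == 1L,
             proteins = I(prot), stringsAsFactors = FALSE)
}

#' Unspecific-cleavage substring check
#'
#' TRUE iff the peptide occurs as a contiguous substring (any termini, no
#' tryptic constraint) of at least one of the given sequences. Used to
#' recognize peptides that could also arise from non-HCPs via unspecific
#' cleavage.
#'
#' @param peptide Character vector of peptides.
#' @param sequences Character vector of protein sequences.
#' @return Logical vector, one entry per peptide.
#' @examples
#' unspecificSubstring("PEPT", c("XXPEPTX"))  # TRUE
#' unspecificSubstring("PEPT", c("PEQT"))     # FALSE
#' @export
unspecificSubstring <- function(peptide, sequences) {
  vapply(peptide, function(p)
    nzchar(p) && any(grepl(p, sequences, fixed = TRUE)),
    logical(1), USE.NAMES = FALSE)
}
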