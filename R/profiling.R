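#' @include AllClasses.R digest.R
NULL

#' Split identified proteins by database category
#'
#' Separates inferred proteins into HCPs (host category), keratin
#' contaminants and non-HCPs (drug substance, spiked standards, trypsin,
#' protein A). Keratins are recognized by category
#' `"keratin_contaminant"` or, for host entries, by a case-insensitive
#' `"keratin"` in the database description (overridable via
#' `keratin_accessions`). Peptides contained as substrings in any non-HCP
#' sequence are stripped from the HCP evidence before tiers are computed, so
#' that peptides derived from non-HCPs are never used to identify HCPs;
#' proteins left without any supporting peptide are dropped (the
#' unspecific-cleavage rule).
#'
#' @param evidence Protein data.frame from [inferProteins()] (list-columns
#'   `unique_peptides`, `shared_peptides`, optionally `insilico_peptides`).
#' @param database The [ProteinDatabase-class] used for the search.
#' @param keratin_accessions Optional explicit accession vector treated as
#'   keratins.
#' @return List with data.frames `hcps` (peptide evidence stripped),
#'   `keratins`, `non_hcps`, and `removed` (HCP accessions removed by the
#'   unspecific-cleavage rule).
#' @export
filterCategories <- function(evidence, database, keratin_accessions = NULL) {
  stopifnot(is(database, "ProteinDatabase"))
  cats <- category(database)
  desc <- description(database)
  ev_cat <- cats[evidence$accession]
  ev_desc <- desc[evidence$accession]
  is_keratin <- evidence$accession %in% keratin_accessions |
    (!is.na(ev_cat) & ev_cat == "keratin_contaminant") |
    (!is.na(ev_cat) & ev_cat == "host" & grepl("keratin", ev_desc,
                                               ignore.case = TRUE))
  is_non_hcp <- !is.na(ev_cat) &
    ev_cat %in% c("drug_substance", "standard_protein", "standard_peptide",
                  "trypsin", "protein_a")
  is_hcp <- !is.na(ev_cat) & ev_cat == "host" & !is_keratin & !is_non_hcp

  hcps <- evidence[is_hcp, , drop = FALSE]
  non_hcp_seqs <- as.character(sequences(database))[
    cats %in% c("drug_substance", "standard_protein", "standard_peptide",
                "trypsin", "protein_a")]

  strip <- function(peps) peps[!unspecificSubstring(peps, non_hcp_seqs)]
  if (nrow(hcps) && length(non_hcp_seqs)) {
    for (col in intersect(c("unique_peptides", "shared_peptides",
                            "insilico_peptides"), names(hcps)))
      hcps[[col]] <- I(lapply(hcps[[col]], strip))
    hcps$n_unique_msms <- lengths(hcps$unique_peptides)
    hcps$n_shared_msms <- lengths(hcps$shared_peptides)
  }
  n_support <- lengths(hcps$unique_peptides) + lengths(hcps$shared_peptides) +
    (if ("insilico_peptides" %in% names(hcps))
       lengths(hcps$insilico_peptides) else 0L)
  removed <- hcps$accession[n_support == 0L]
  if (length(removed))
    message(length(removed),
            " HCP(s) removed: all supporting peptides attributable to ",
            "non-HCPs via unspecific cleavage")
  list(hcps = hcps[n_support > 0L, , drop = FALSE],
       keratins = evidence[is_keratin, , drop = FALSE],
       non_hcps = evidence[is_non_hcp, , drop = FALSE],
       removed = removed)
}

#' Unspecific-cleavage removal rule
#'
#' A provisional HCP identification is removed when every one of its
#' supporting peptides could also be generated from a non-HCP sequence via
#' unspecific cleavage (i.e. occurs as a contiguous substring of at least
#' one non-HCP sequence). A protein with zero supporting peptides is removed
#' vacuously.
#'
#' @param peptides Character vector of the protein's supporting peptides.
#' @param non_hcp_sequences Character vector of non-HCP protein sequences.
#' @return `TRUE` to keep the protein, `FALSE` to remove it.
#' @examples
#' unspecificCleavageFilter(c("AAAK", "CCCR"), "XXAAAKXX")  # kept: CCCR unique
#' unspecificCleavageFilter("AAAK", "XXAAAKXX")             # removed
#' @export
unspecificCleavageFilter <- function(peptides, non_hcp_sequences) {
  if (!length(peptides)) return(FALSE)
  !all(unspecificSubstring(peptides, non_hcp_sequences))
}

#' Credibility tier of a protein identification
#'
#' Ordinal evidence scale: 4 = MS/MS spectra of at least two unique
#' peptides; 3 = exactly one unique MS/MS peptide; 2 = only shared MS/MS
#' peptides (assigned by inference); 1 = in silico peptides only. The tier
#' is the best evidence class present; unique-peptide counting applies the
#' minimum-length rule.
#'
#' @param unique_peptides,shared_peptides,insilico_peptides List-columns (or
#'   lists) of supporting peptides per protein.
#' @param min_unique_peptide_length Minimum residues for a unique peptide to
#'   count (default 5).
#' @return Integer vector of tiers (NA when a protein has no evidence at
#'   all).
#' @examples
#' assignTiers(list(c("AAAAK", "CCCCR")), list(character()), list(character()))
#' @export
assignTiers <- function(unique_peptides, shared_peptides,
                        insilico_peptides = NULL,
                        min_unique_peptide_length = 5L) {
  n <- length(unique_peptides)
  if (is.null(insilico_peptides)) insilico_peptides <- rep(list(character()), n)
  n_uniq <- vapply(unique_peptides, function(p)
    sum(nchar(p) >= min_unique_peptide_length), integer(1))
  n_shared <- lengths(shared_peptides)
  n_insil <- lengths(insilico_peptides)
  tier <- rep(NA_integer_, n)
  tier[n_insil >= 1L] <- 1L
  tier[n_shared >= 1L] <- 2L
  tier[n_uniq == 1L] <- 3L
  tier[n_uniq >= 2L] <- 4L
  tier
}

#' Aggregate HCP profiles to a coarser level
#'
#' The profile of a fraction comprises all HCPs detected in at least one
#' replicate of that fraction; the profile of a drug product comprises all
#' HCPs detected in at least one of its fractions. Members are merged by
#' union and each member's tier is the maximum tier across children.
#'
#' @param profiles List of [HCPProfile-class] objects sharing the parent key
#'   for `to_level`.
#' @param to_level Target level: `"fraction"` or `"drug_product"`.
#' @return A single aggregated [HCPProfile-class].
#' @examples
#' p1 <- HCPProfile("replicate",
#'   c(drug_product = "DP1", fraction = "wash", replicate = "1"),
#'   c(A = 4L, B = 1L))
#' p2 <- HCPProfile("replicate",
#'   c(drug_product = "DP1", fraction = "wash", replicate = "2"),
#'   c(B = 3L, C = 2L))
#' members(aggregateProfiles(list(p1, p2), "fraction"))
#' @export
aggregateProfiles <- function(profiles, to_level = c("fraction",
                                                     "drug_product")) {
  to_level <- match.arg(to_level)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, is, TRUE, "HCPProfile")))
  parent_fields <- switch(to_level,
                          fraction = c("drug_product", "fraction"),
                          drug_product = "drug_product")
  keys <- vapply(profiles, function(p)
    paste(p@key[parent_fields], collapse = "\r"), "")
  if (length(unique(keys)) != 1L)
    stop("profiles have mixed parent keys: ",
         paste(unique(keys), collapse = " vs "))
  merged <- integer()
  for (p in profiles) {
    m <- members(p)
    new_acc <- setdiff(names(m), names(merged))
    merged <- c(merged, m[new_acc])
    common <- intersect(names(m), names(merged))
    common <- setdiff(common, new_acc)
    if (length(common))
      merged[common] <- pmax(merged[common], m[common])
  }
  HCPProfile(to_level, profiles[[1]]@key[parent_fields], merged)
}

#' Filter a profile by minimum credibility tier
#'
#' Tier thresholds are cumulative: a minimum-level query at tier `L` returns
#' all members with tier `>= L`, so profile size is non-increasing in `L`.
#'
#' @param profile An [HCPProfile-class].
#' @param min_tier Minimum credibility tier (1..4).
#' @return An [HCPProfile-class] restricted to members at or above
#'   `min_tier`.
#' @export
filterByTier <- function(profile, min_tier = 1L) {
  m <- members(profile)
  HCPProfile(profile@level, profile@key, m[m >= min_tier])
}

#' Top-3 relative quantification
#'
#' Per replicate, the mean area of the up-to-`top_n` most intense distinct
#' peptides of each protein is computed; these per-replicate values are then
#' averaged over the replicates of each (drug product, fraction) column, and
#' finally scaled to the maximum value in each column so that all values are
#' percent of the column maximum. Cumulative keratin and HCP rows sum the
#' per-protein means before scaling.
#'
#' @param peptide_areas data.frame with columns `run_id`, `accession`,
#'   `peptide`, `area` (feature areas linked to peptides, summed over
#'   charges).
#' @param meta Run metadata ([readRunMetadata()] layout).
#' @param categories Named character vector accession -> category (as from
#'   `category(database)`), used for the cumulative rows.
#' @param top_n Number of peptides per protein (default 3).
#' @return Matrix of percentages in `[0, 100]` with one row per protein plus
#'   `cumulative_keratins` and `cumulative_HCPs`, one column per
#'   `drug_product:fraction`; each column's maximum is 100. Proteins without
#'   any linked feature in a column are NA there.
#' @export
quantifyTop3 <- function(peptide_areas, meta, categories, top_n = 3L) {
  stopifnot(all(c("run_id", "accession", "peptide", "area") %in%
                names(peptide_areas)))
  dt <- data.table::as.data.table(peptide_areas)
  ## mean of the up-to-top_n most intense distinct peptides, per run
  per_run <- dt[, .(area = sum(area)), by = .(run_id, accession, peptide)][
    order(-area), .(top_mean = mean(head(area, top_n))),
    by = .(run_id, accession)]
  per_run <- merge(per_run,
                   data.table::as.data.table(meta[c("run_id", "drug_product",
                                                    "fraction")]),
                   by = "run_id")
  ## mean over technical replicates
  cell <- per_run[, .(value = mean(top_mean)),
                  by = .(drug_product, fraction, accession)]
  cell[, column := paste(drug_product, fraction, sep = ":")]
  cols <- sort(unique(cell$column))
  accs <- sort(unique(cell$accession))
  m <- matrix(NA_real_, nrow = length(accs), ncol = length(cols),
              dimnames = list(accs, cols))
  m[cbind(match(cell$accession, accs), match(cell$column, cols))] <- cell$value

  cat_of <- categories[accs]
  is_ker <- !is.na(cat_of) & cat_of == "keratin_contaminant"
  is_hcp <- !is.na(cat_of) & cat_of == "host"
  cum <- rbind(
    cumulative_keratins = colSums(m[is_ker, , drop = FALSE], na.rm = TRUE),
    cumulative_HCPs = colSums(m[is_hcp, , drop = FALSE], na.rm = TRUE))
  out <- rbind(cum, m)
  ## percent of column maximum
  colmax <- apply(out, 2, max, na.rm = TRUE)
  sweep(out, 2, colmax, "/") * 100
}
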