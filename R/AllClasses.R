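#' @include constants.R
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Protein sequence database
#'
#' An annotated protein sequence database: amino-acid sequences (stored as a
#' [Biostrings::AAStringSet]) plus a category per entry distinguishing host
#' proteins (potential HCPs) from annotated non-HCPs (drug substance, spiked
#' standards, trypsin, protein A), keratin contaminants and decoys.
#'
#' @slot sequences An `AAStringSet`; names are the accessions.
#' @slot category Character vector, one of `"host"`, `"drug_substance"`,
#'   `"standard_protein"`, `"standard_peptide"`, `"trypsin"`, `"protein_a"`,
#'   `"keratin_contaminant"`, `"decoy"`.
#' @slot description Character vector of free-text descriptions (may be
#'   empty strings).
#' @export
setClass("ProteinDatabase",
  representation(sequences = "AAStringSet", category = "character",
                 description = "character"))

setValidity("ProteinDatabase", function(object) {
  seqs <- object@sequences
  acc <- names(seqs)
  msgs <- character()
  if (is.null(acc) && length(seqs) > 0L)
    msgs <- c(msgs, "sequences must be named by accession")
  if (anyDuplicated(acc))
    msgs <- c(msgs, sprintf("duplicate accession(s): %s",
                            paste(unique(acc[duplicated(acc)]), collapse = ", ")))
  if (length(object@category) != length(seqs))
    msgs <- c(msgs, "category must have one entry per sequence")
  if (length(object@description) != length(seqs))
    msgs <- c(msgs, "description must have one entry per sequence")
  bad <- setdiff(unique(object@category), PROTEIN_CATEGORIES)
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown category: %s", paste(bad, collapse = ", ")))
  if (length(seqs) > 0L) {
    chars <- as.character(seqs)
    if (any(nchar(chars) == 0L))
      msgs <- c(msgs, "empty sequence(s) present")
    nonstd <- grepl("[^A-Z]", chars)
    if (any(nonstd))
      msgs <- c(msgs, sprintf(
        "sequence(s) with non-canonical residues: %s",
        paste(head(acc[nonstd], 3L), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a protein database
#'
#' @param accession Character vector of unique accessions.
#' @param sequence Character vector of uppercase amino-acid sequences
#'   (letter codes only; the 20 canonical residues are required wherever
#'   masses are computed).
#' @param category Category per entry (recycled); defaults to `"host"`.
#' @param description Free-text description per entry (recycled).
#' @return A [ProteinDatabase-class] object.
#' @examples
#' db <- ProteinDatabase(c("P1", "P2"), c("MKAAAR", "GGGK"),
#'                       category = c("host", "drug_substance"))
#' db
#' @export
ProteinDatabase <- function(accession = character(), sequence = character(),
                            category = "host", description = "") {
  stopifnot(length(accession) == length(sequence))
  n <- length(accession)
  sequence <- toupper(sequence)
  bad <- grepl("[^A-Z]", sequence)
  if (any(bad))
    stop("sequence(s) with non-canonical residues: ",
         paste(head(accession[bad], 3L), collapse = ", "))
  seqs <- Biostrings::AAStringSet(sequence)
  names(seqs) <- accession
  new("ProteinDatabase", sequences = seqs,
      category = rep_len(as.character(category), n),
      description = rep_len(as.character(description), n))
}

#' Pipeline configuration
#'
#' Holds the fixed parameters of the HCP discovery pipeline. Defaults mirror
#' the published protocol: PSM and protein FDR 1% with a 20-reverse-count
#' cap, unique peptides must have at least 5 residues, retention-time window
#' tolerance (FeatureCenterTolerance) 0.5 min, peak-width tolerance
#' (FeatureDurationTolerance) 0.1 min, mass-deviation percentile bounds
#' 2.5/97.5, MS1-correlation percentile 5, precursor tolerance 7 ppm, top-3
#' quantification, complete-linkage clustering.
#'
#' @slot psm_fdr,protein_fdr Target FDR fractions.
#' @slot max_reverse_count Cap on decoy proteins in the accepted list.
#' @slot min_unique_peptide_length Minimum residues for the unique-peptide
#'   identification rule.
#' @slot feature_center_tolerance Allowed retention-time shift beyond the
#'   MS/MS window edges, minutes (the "30 s" rule).
#' @slot feature_duration_tolerance Allowed change in chromatographic peak
#'   width, minutes.
#' @slot mass_dev_percentiles Lower/upper percentile bounds (in percent) of
#'   reference mass deviations.
#' @slot ms1_corr_percentile Percentile (in percent) of reference MS1
#'   correlations below which candidates are dismissed.
#' @slot precursor_tolerance_ppm Coarse m/z gate for candidate features.
#' @slot top_n_quant Number of most intense peptides used for relative
#'   quantification.
#' @slot linkage Hierarchical clustering linkage method.
#' @export
setClass("PipelineConfig",
  representation(
    psm_fdr = "numeric", protein_fdr = "numeric",
    max_reverse_count = "integer", min_unique_peptide_length = "integer",
    feature_center_tolerance = "numeric", feature_duration_tolerance = "numeric",
    mass_dev_percentiles = "numeric", ms1_corr_percentile = "numeric",
    precursor_tolerance_ppm = "numeric", top_n_quant = "integer",
    linkage = "character"))

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  pos <- c(psm_fdr = object@psm_fdr, protein_fdr = object@protein_fdr,
           feature_center_tolerance = object@feature_center_tolerance,
           feature_duration_tolerance = object@feature_duration_tolerance,
           precursor_tolerance_ppm = object@precursor_tolerance_ppm)
  if (any(pos <= 0))
    msgs <- c(msgs, sprintf("must be strictly positive: %s",
                            paste(names(pos)[pos <= 0], collapse = ", ")))
  p <- object@mass_dev_percentiles
  if (length(p) != 2L || any(p <= 0) || any(p >= 100) || p[1] >= p[2])
    msgs <- c(msgs, "mass_dev_percentiles must be an ordered pair in (0, 100)")
  pc <- object@ms1_corr_percentile
  if (pc <= 0 || pc >= 100)
    msgs <- c(msgs, "ms1_corr_percentile must lie in (0, 100)")
  if (object@max_reverse_count < 0L)
    msgs <- c(msgs, "max_reverse_count must be non-negative")
  if (object@top_n_quant < 1L)
    msgs <- c(msgs, "top_n_quant must be at least 1")
  if (length(msgs)) msgs else TRUE
})

#' Create a pipeline configuration
#'
#' @param psm_fdr,protein_fdr Target FDR fractions (default 0.01).
#' @param max_reverse_count Decoy cap at the protein level (default 20).
#' @param min_unique_peptide_length Minimum unique-peptide length in
#'   residues (default 5).
#' @param feature_center_tolerance Retention-time tolerance in minutes
#'   (default 0.5).
#' @param feature_duration_tolerance Peak-width tolerance in minutes
#'   (default 0.1).
#' @param mass_dev_percentiles Percentile pair for the mass-deviation filter
#'   (default `c(2.5, 97.5)`).
#' @param ms1_corr_percentile Percentile for the MS1-correlation filter
#'   (default 5).
#' @param precursor_tolerance_ppm Coarse precursor m/z gate (default 7).
#' @param top_n_quant Peptides per protein for quantification (default 3).
#' @param linkage Clustering linkage (default `"complete"`).
#' @return A [PipelineConfig-class] object.
#' @examples
#' hcpConfig()
#' hcpConfig(psm_fdr = 0.05, linkage = "average")
#' @export
hcpConfig <- function(psm_fdr = 0.01, protein_fdr = 0.01,
                      max_reverse_count = 20L,
                      min_unique_peptide_length = 5L,
                      feature_center_tolerance = 0.5,
                      feature_duration_tolerance = 0.1,
                      mass_dev_percentiles = c(2.5, 97.5),
                      ms1_corr_percentile = 5,
                      precursor_tolerance_ppm = 7,
                      top_n_quant = 3L, linkage = "complete") {
  new("PipelineConfig",
      psm_fdr = psm_fdr, protein_fdr = protein_fdr,
      max_reverse_count = as.integer(max_reverse_count),
      min_unique_peptide_length = as.integer(min_unique_peptide_length),
      feature_center_tolerance = feature_center_tolerance,
      feature_duration_tolerance = feature_duration_tolerance,
      mass_dev_percentiles = mass_dev_percentiles,
      ms1_corr_percentile = ms1_corr_percentile,
      precursor_tolerance_ppm = precursor_tolerance_ppm,
      top_n_quant = as.integer(top_n_quant), linkage = linkage)
}

#' HCP profile
#'
#' The set of HCP accessions detected at a given level (replicate, fraction
#' or drug product), each with its credibility tier: 4 = at least two unique
#' MS/MS peptides, 3 = exactly one unique MS/MS peptide, 2 = only shared
#' MS/MS peptides (assigned), 1 = in silico peptides only.
#'
#' @slot level `"replicate"`, `"fraction"` or `"drug_product"`.
#' @slot key Named character vector identifying the profile
#'   (`drug_product`, and depending on the level `fraction`, `replicate`).
#' @slot members Named integer vector: accession -> tier (1..4).
#' @export
setClass("HCPProfile",
  representation(level = "character", key = "character", members = "integer"))

setValidity("HCPProfile", function(object) {
  msgs <- character()
  if (!object@level %in% c("replicate", "fraction", "drug_product"))
    msgs <- c(msgs, "level must be replicate, fraction or drug_product")
  need <- switch(object@level,
                 replicate = c("drug_product", "fraction", "replicate"),
                 fraction = c("drug_product", "fraction"),
                 drug_product = "drug_product")
  if (!all(need %in% names(object@key)))
    msgs <- c(msgs, sprintf("key must contain: %s", paste(need, collapse = ", ")))
  m <- object@members
  if (length(m) && (is.null(names(m)) || any(!m %in% 1:4)))
    msgs <- c(msgs, "members must be a named integer vector with tiers in 1..4")
  if (anyDuplicated(names(m)))
    msgs <- c(msgs, "duplicate accessions in members")
  if (length(msgs)) msgs else TRUE
})

#' Construct an HCP profile
#'
#' @param level Profile level (`"replicate"`, `"fraction"`,
#'   `"drug_product"`).
#' @param key Named character vector identifying the profile.
#' @param members Named integer vector mapping accession to credibility tier.
#' @return An [HCPProfile-class] object.
#' @examples
#' HCPProfile("replicate",
#'            c(drug_product = "DP1", fraction = "wash", replicate = "1"),
#'            c(HCP_001 = 4L, HCP_007 = 1L))
#' @export
HCPProfile <- function(level, key, members = integer()) {
  if (length(members) && is.null(names(members)))
    stop("members must be named by accession")
  members <- setNames(as.integer(members), names(members))
  new("HCPProfile", level = level, key = key, members = members)
}

#' Simulation configuration
#'
#' Parameters of the synthetic bottom-up proteomics generator. The defaults
#' emulate the measurement structure of a protein A depletion study: a
#' highly abundant drug substance per drug product, host cell proteins
#' spread over 2-5 orders of magnitude below it, triplicate injections per
#' fraction, abundance-dependent MS/MS sampling (top-N data-dependent
#' acquisition), reproducible retention times with small jitter, noisy
#' isotope envelopes, decoy/false PSMs from a null score distribution and
#' planted wrong-mass "bait" features.
#'
#' @slot seed Base random seed.
#' @slot n_hcps Number of host cell proteins in the database.
#' @slot n_keratins Number of keratin contaminant entries.
#' @slot n_drug_products,n_fractions_per_dp,n_replicates Measurement layout.
#' @slot protein_length Mean protein length (residues).
#' @slot dp_abundance Drug substance abundance (arbitrary intensity units).
#' @slot hcp_log10_range Range (log10) of HCP abundances below the drug
#'   substance, default 2-5 decades.
#' @slot rt_jitter_sd Replicate retention-time jitter SD, minutes.
#' @slot gradient Retention-time window (minutes) peptides elute in.
#' @slot msms_mid,msms_scale Logistic MS/MS sampling: detection probability
#'   `plogis((log10(area) - msms_mid)/msms_scale)`.
#' @slot missingness Probability that a peptide's MS/MS event is dropped in
#'   a given run even though its feature is present.
#' @slot envelope_noise_cv Coefficient of variation of multiplicative
#'   isotope-envelope noise.
#' @slot feature_ppm_sd,psm_ppm_sd m/z error SD (ppm) of MS1 feature
#'   centroids (elution-averaged) and of single-scan PSM precursor readouts.
#' @slot true_score_shift Shift separating the true-PSM score distribution
#'   from the null (decoy) distribution; smaller values overlap more.
#' @slot false_psm_rate Expected number of false target PSMs per true PSM.
#' @slot shared_fraction Fraction of HCPs planted to share a tryptic peptide
#'   with another HCP.
#' @slot n_bait Number of wrong-mass bait features per run (> 20 ppm off any
#'   true peptide).
#' @slot dp_hcp_sets Optional named list: drug product -> HCP accessions
#'   present; empty means all HCPs present in all drug products.
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer", n_hcps = "integer", n_keratins = "integer",
    n_drug_products = "integer", n_fractions_per_dp = "integer",
    n_replicates = "integer", protein_length = "integer",
    dp_abundance = "numeric", hcp_log10_range = "numeric",
    rt_jitter_sd = "numeric", gradient = "numeric",
    msms_mid = "numeric", msms_scale = "numeric", missingness = "numeric",
    envelope_noise_cv = "numeric", feature_ppm_sd = "numeric",
    psm_ppm_sd = "numeric", true_score_shift = "numeric",
    false_psm_rate = "numeric", shared_fraction = "numeric",
    n_bait = "integer", dp_hcp_sets = "list"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  probs <- c(missingness = object@missingness,
             shared_fraction = object@shared_fraction)
  if (any(probs < 0 | probs > 1))
    msgs <- c(msgs, "missingness and shared_fraction must lie in [0, 1]")
  if (object@rt_jitter_sd <= 0)
    msgs <- c(msgs, "rt_jitter_sd must be positive")
  if (object@rt_jitter_sd >= 0.5)
    msgs <- c(msgs, "rt_jitter_sd must stay below the 0.5 min RT tolerance")
  if (length(object@hcp_log10_range) != 2L ||
      object@hcp_log10_range[1] > object@hcp_log10_range[2])
    msgs <- c(msgs, "hcp_log10_range must be an ordered pair")
  if (length(object@gradient) != 2L || object@gradient[1] >= object@gradient[2])
    msgs <- c(msgs, "gradient must be an ordered pair of minutes")
  if (object@n_fractions_per_dp < 1L || object@n_fractions_per_dp > 3L)
    msgs <- c(msgs, "n_fractions_per_dp must be 1, 2 or 3")
  if (length(msgs)) msgs else TRUE
})

#' Create a simulation configuration
#'
#' @param seed Base random seed (default 1).
#' @param n_hcps Number of HCPs (default 50).
#' @param n_keratins Keratin contaminant entries (default 2).
#' @param n_drug_products Drug products (default 2).
#' @param n_fractions_per_dp Fractions per drug product: 1 = direct,
#'   2 = flow-through + wash (default 2).
#' @param n_replicates Technical replicates per fraction (default 3).
#' @param protein_length Mean protein length in residues (default 240).
#' @param dp_abundance Drug substance intensity (default 1e9).
#' @param hcp_log10_range Decades below the drug substance spanned by HCP
#'   abundances (default `c(2, 5)`).
#' @param rt_jitter_sd Replicate RT jitter SD in minutes (default 0.05).
#' @param gradient Elution window in minutes (default `c(2, 80)`).
#' @param msms_mid,msms_scale Logistic MS/MS sampling parameters on
#'   log10(area) (defaults 4.5 and 0.4).
#' @param missingness MS/MS drop probability per run (default 0.1).
#' @param envelope_noise_cv Envelope noise CV (default 0.05).
#' @param feature_ppm_sd Feature centroid m/z error SD in ppm (default 2).
#' @param psm_ppm_sd PSM precursor m/z error SD in ppm (default 3).
#' @param true_score_shift Score-distribution separation (default 25).
#' @param false_psm_rate False target PSMs per true PSM (default 0.15).
#' @param shared_fraction Fraction of HCPs sharing a planted peptide
#'   (default 0.2).
#' @param n_bait Bait features per run (default 10).
#' @param dp_hcp_sets Optional named list of per-drug-product HCP sets.
#' @return A [SimulationConfig-class] object.
#' @examples
#' simConfig(seed = 7, n_hcps = 20)
#' @export
simConfig <- function(seed = 1L, n_hcps = 50L, n_keratins = 2L,
                      n_drug_products = 2L, n_fractions_per_dp = 2L,
                      n_replicates = 3L, protein_length = 240L,
                      dp_abundance = 1e9, hcp_log10_range = c(2, 5),
                      rt_jitter_sd = 0.05, gradient = c(2, 80),
                      msms_mid = 4.5, msms_scale = 0.4, missingness = 0.1,
                      envelope_noise_cv = 0.05, feature_ppm_sd = 2,
                      psm_ppm_sd = 3, true_score_shift = 25,
                      false_psm_rate = 0.15, shared_fraction = 0.2,
                      n_bait = 10L, dp_hcp_sets = list()) {
  new("SimulationConfig",
      seed = as.integer(seed), n_hcps = as.integer(n_hcps),
      n_keratins = as.integer(n_keratins),
      n_drug_products = as.integer(n_drug_products),
      n_fractions_per_dp = as.integer(n_fractions_per_dp),
      n_replicates = as.integer(n_replicates),
      protein_length = as.integer(protein_length),
      dp_abundance = dp_abundance, hcp_log10_range = hcp_log10_range,
      rt_jitter_sd = rt_jitter_sd, gradient = gradient,
      msms_mid = msms_mid, msms_scale = msms_scale,
      missingness = missingness, envelope_noise_cv = envelope_noise_cv,
      feature_ppm_sd = feature_ppm_sd, psm_ppm_sd = psm_ppm_sd,
      true_score_shift = true_score_shift, false_psm_rate = false_psm_rate,
      shared_fraction = shared_fraction, n_bait = as.integer(n_bait),
      dp_hcp_sets = dp_hcp_sets)
}
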