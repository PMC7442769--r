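#' @include AllClasses.R digest.R averagine.R inference.R
NULL

## residue sampling frequencies: ~11% K+R so tryptic peptides average 8-12
## residues; P kept low to limit missed cleavage blocking
.AA_FREQ <- local({
  f <- setNames(rep(0.85 / 17, 20), names(RESIDUE_MONO_MASS))
  f["K"] <- 0.055; f["R"] <- 0.055; f["P"] <- 0.04
  f / sum(f)
})

.randSeq <- function(n) paste(sample(names(.AA_FREQ), n, replace = TRUE,
                                     prob = .AA_FREQ), collapse = "")

## fixed carbamidomethylation of every cysteine as a modification string
.camMods <- function(peptide) {
  pos <- gregexpr("C", peptide, fixed = TRUE)[[1]]
  if (pos[1] == -1L) return("")
  paste(sprintf("%d:57.021464:Carbamidomethyl", pos), collapse = ";")
}

#' Simulate a protein sequence database
#'
#' Generates random protein sequences with realistic K/R frequency (about
#' 11%, so tryptic peptides average 8-12 residues): host cell proteins,
#' keratin contaminants, one drug substance per drug product, synthetic
#' stand-ins for porcine trypsin and protein A, two spiked standard
#' proteins, and a Hi3-type peptide standard as a single entry (six
#' concatenated peptides). A configurable fraction of HCP pairs is planted
#' to share one tryptic peptide, exercising shared-peptide inference.
#' Deterministic given the seed.
#'
#' @param config A [SimulationConfig-class].
#' @return List with `database` (a [ProteinDatabase-class]) and
#'   `shared_pairs` (data.frame: donor, acceptor, peptide).
#' @examples
#' sim <- simulateDatabase(simConfig(seed = 3, n_hcps = 5))
#' sim$database
#' @export
simulateDatabase <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  len <- function() max(60L, round(config@protein_length * runif(1, 0.8, 1.2)))

  acc <- character(); seqs <- character(); cats <- character()
  descs <- character()
  add <- function(a, s, c, d) {
    acc <<- c(acc, a); seqs <<- c(seqs, s); cats <<- c(cats, c)
    descs <<- c(descs, d)
  }
  for (i in seq_len(config@n_hcps))
    add(sprintf("HCP_%03d", i), .randSeq(len()), "host",
        sprintf("synthetic host cell protein %d", i))
  for (i in seq_len(config@n_keratins))
    add(sprintf("KER_%02d", i), .randSeq(len()), "keratin_contaminant",
        "Keratin, synthetic contaminant")
  for (d in seq_len(config@n_drug_products))
    add(sprintf("DS_DP%d", d), .randSeq(450L), "drug_substance",
        sprintf("synthetic drug substance of DP%d", d))
  add("TRYP_SYN", .randSeq(230L), "trypsin", "synthetic stand-in, trypsin")
  add("PROTA_SYN", .randSeq(300L), "protein_a",
      "synthetic stand-in, protein A")
  add("STD_BLG", .randSeq(160L), "standard_protein",
      "synthetic standard protein 1")
  add("STD_BGAL", .randSeq(300L), "standard_protein",
      "synthetic standard protein 2")
  hi3 <- paste(vapply(1:6, function(i)
    paste0(paste(sample(setdiff(names(.AA_FREQ), c("K", "R", "P")), 9,
                        replace = TRUE), collapse = ""), "K"), ""),
    collapse = "")
  add("HI3_STD", hi3, "standard_peptide",
      "synthetic Hi3-type peptide standard, six peptides, one entry")

  ## plant shared tryptic peptides between HCP pairs
  n_pairs <- round(config@shared_fraction * config@n_hcps)
  shared <- list()
  if (n_pairs > 0 && config@n_hcps >= 2L) {
    idx <- sample(config@n_hcps, min(2L * n_pairs, config@n_hcps))
    for (k in seq_len(length(idx) %/% 2L)) {
      don <- idx[2L * k - 1L]; acc_i <- idx[2L * k]
      peps <- trypticDigest(seqs[don], 0L)
      cand <- peps$sequence[nchar(peps$sequence) >= 8 &
                            nchar(peps$sequence) <= 14 &
                            !startsWith(peps$sequence, "P") &
                            grepl("[KR]$", peps$sequence)]
      if (!length(cand)) next
      pep <- sample(cand, 1L)
      target <- seqs[acc_i]
      res <- strsplit(target, "")[[1]]
      cuts <- which(res %in% c("K", "R"))
      cuts <- cuts[cuts < length(res) & res[cuts + 1L] != "P"]
      if (!length(cuts)) next
      at <- sample(cuts, 1L)
      seqs[acc_i] <- paste0(substr(target, 1L, at), pep,
                            substr(target, at + 1L, nchar(target)))
      shared[[length(shared) + 1L]] <- data.frame(
        donor = acc[don], acceptor = acc[acc_i], peptide = pep,
        stringsAsFactors = FALSE)
    }
  }
  list(database = ProteinDatabase(acc, seqs, cats, descs),
       shared_pairs = if (length(shared)) do.call(rbind, shared) else
         data.frame(donor = character(), acceptor = character(),
                    peptide = character()))
}

#' Simulate PSM score populations for FDR calibration
#'
#' Draws PSM scores from the generator's score model: true target PSMs from
#' a shifted gamma distribution, false target PSMs and decoy PSMs from the
#' same null gamma distribution (shape 4, rate 0.5), so that decoy counting
#' estimates the proportion of false targets.
#'
#' @param n_true,n_false,n_decoy Population sizes.
#' @param true_score_shift Shift of the true-score distribution (default 25).
#' @param seed Random seed.
#' @return data.frame with columns `score`, `decoy`, `is_false` (ground
#'   truth: TRUE for false target PSMs, NA for decoys).
#' @export
simulatePsmScores <- function(n_true, n_false, n_decoy = n_false,
                              true_score_shift = 25, seed = 1L) {
  set.seed(seed)
  data.frame(
    score = c(rgamma(n_true, 4, 0.5) + true_score_shift,
              rgamma(n_false, 4, 0.5), rgamma(n_decoy, 4, 0.5)),
    decoy = rep(c(FALSE, FALSE, TRUE), c(n_true, n_false, n_decoy)),
    is_false = rep(c(FALSE, TRUE, NA), c(n_true, n_false, n_decoy)))
}

#' Simulate LC-MS/MS runs with ground truth
#'
#' Emulates replicate bottom-up measurements of the database proteins: every
#' peptide of a present protein yields an MS1 feature in every run (area
#' proportional to protein abundance times a per-peptide ionization factor,
#' m/z with small centroid error, retention time from a reproducible
#' per-peptide base value plus replicate jitter, isotope envelope from the
#' averagine model with multiplicative noise). MS/MS identifications (PSMs)
#' are sampled with logistic probability in log10 abundance, thinned by
#' `missingness`; true PSM scores come from a shifted gamma distribution,
#' false target and decoy PSMs from the null distribution. Wrong-mass bait
#' features (> 20 ppm off every theoretical peptide ion of the same charge)
#' are planted per run as rescue negatives.
#'
#' @param db A [ProteinDatabase-class] from [simulateDatabase()].
#' @param config The same [SimulationConfig-class].
#' @return List with `meta`, `psms`, `features` (standard table layouts) and
#'   `truth`, a list holding `present` (dp, accession, abundance),
#'   `peptide_link` (accession, peptide), `peptide_attrs`, `detections`
#'   (per run and peptide: area, has_msms), `rescue_eligible` (feature-only
#'   detections with MS/MS support elsewhere in the same drug product),
#'   `bait` and `psm_class`.
#' @export
simulateRuns <- function(db, config) {
  stopifnot(is(db, "ProteinDatabase"), is(config, "SimulationConfig"))
  set.seed(config@seed + 1L)
  dps <- sprintf("DP%d", seq_len(config@n_drug_products))
  fracs <- switch(config@n_fractions_per_dp, "direct",
                  c("flow_through", "wash"),
                  c("direct", "flow_through", "wash"))
  meta <- expand.grid(replicate = seq_len(config@n_replicates),
                      fraction = fracs, drug_product = dps,
                      stringsAsFactors = FALSE)[3:1]
  meta$run_id <- sprintf("%s_%s_r%d", meta$drug_product, meta$fraction,
                         meta$replicate)
  meta <- meta[c("run_id", "drug_product", "fraction", "replicate")]

  cats <- category(db)
  all_seq <- as.character(sequences(db))

  ## --- which proteins are present per drug product, at which abundance ----
  present <- list()
  for (d in dps) {
    hcp_acc <- if (length(config@dp_hcp_sets)) config@dp_hcp_sets[[d]]
               else accession(db)[cats == "host"]
    ker_acc <- accession(db)[cats == "keratin_contaminant"]
    bg <- data.frame(
      accession = c(sprintf("DS_%s", d), "TRYP_SYN", "PROTA_SYN", "STD_BLG",
                    "STD_BGAL", "HI3_STD"),
      abundance = config@dp_abundance *
        c(1, 10^-2, 10^-3, 10^-2.5, 10^-2.5, 10^-2.5),
      stringsAsFactors = FALSE)
    hk <- data.frame(
      accession = c(hcp_acc, ker_acc),
      abundance = config@dp_abundance *
        10^-runif(length(hcp_acc) + length(ker_acc),
                  config@hcp_log10_range[1], config@hcp_log10_range[2]),
      stringsAsFactors = FALSE)
    pr <- rbind(bg, hk)
    pr$dp <- d
    present[[d]] <- pr
  }
  present <- do.call(rbind, present)
  rownames(present) <- NULL

  ## --- peptide universe (0 missed cleavages, detectable length) -----------
  non_decoy <- accession(db)[cats != "decoy"]
  link <- do.call(rbind, lapply(non_decoy, function(a) {
    p <- trypticDigest(all_seq[match(a, accession(db))], 0L)$sequence
    p <- unique(p[nchar(p) >= 6 & nchar(p) <= 30])
    if (!length(p)) return(NULL)
    data.frame(accession = a, peptide = p, stringsAsFactors = FALSE)
  }))

  peps <- unique(link$peptide)
  attrs <- data.frame(peptide = peps, stringsAsFactors = FALSE)
  attrs$mods <- vapply(peps, .camMods, "")
  attrs$z <- sample(2:4, length(peps), replace = TRUE,
                    prob = c(0.55, 0.33, 0.12))
  attrs$neutral_mass <- peptideMass(attrs$peptide, attrs$mods)
  attrs$theo_mz <- mzFromMass(attrs$neutral_mass, attrs$z)
  attrs$base_rt <- runif(length(peps), config@gradient[1], config@gradient[2])
  attrs$base_width <- runif(length(peps), 0.25, 0.35)
  attrs$ion <- 10^rnorm(length(peps), 0, 0.4)
  attrs$nres <- nchar(attrs$peptide)

  env_cache <- .averagineEnvelopes(attrs$nres, max_peaks = 5L)

  ## --- detections: (run x present peptide), vectorized ---------------------
  ldt <- data.table::as.data.table(link)
  pdt <- data.table::as.data.table(present)
  base <- merge(ldt, pdt, by = "accession", allow.cartesian = TRUE)
  ## shared peptides: feature intensity sums over all source proteins
  base <- base[, .(base_area = sum(abundance)), by = .(dp, peptide)]
  adt <- data.table::as.data.table(attrs)
  base <- merge(base, adt, by = "peptide")
  mdt <- data.table::as.data.table(meta)
  det <- merge(base, mdt[, .(run_id, dp = drug_product)], by = "dp",
               allow.cartesian = TRUE)
  n <- nrow(det)
  det[, area := base_area * ion * 10^rnorm(n, 0, 0.1)]
  det[, mz := theo_mz * (1 + rnorm(n, 0, config@feature_ppm_sd * 1e-6))]
  det[, rt_center := base_rt + rnorm(n, 0, config@rt_jitter_sd)]
  det[, rt_width := pmax(0.05, base_width + rnorm(n, 0, 0.015))]
  p_msms <- plogis((log10(det$area) - config@msms_mid) / config@msms_scale)
  det[, has_msms := rbinom(n, 1L, p_msms * (1 - config@missingness)) == 1L]

  ## isotope envelopes: averagine shape x area x multiplicative noise
  env <- matrix(0, nrow = n, ncol = 5L)
  theo_m <- do.call(rbind, lapply(as.character(det$nres), function(k) {
    v <- env_cache[[k]]; length(v) <- 5L; v[is.na(v)] <- 0; v
  }))
  noise <- matrix(1 + rnorm(5L * n, 0, config@envelope_noise_cv), nrow = n)
  env <- pmax(theo_m * det$area * noise, 0)
  env[env[, 1] == 0, 1] <- 1e-6       # envelope must not be all zero

  features <- data.frame(run_id = det$run_id, mz = det$mz, z = det$z,
                         rt_center_min = det$rt_center,
                         rt_width_min = det$rt_width, area = det$area,
                         stringsAsFactors = FALSE)
  features <- cbind(features, setNames(as.data.frame(env),
                                       paste0("iso", 0:4)))

  ## --- bait features: > 20 ppm off every theoretical ion of same charge ---
  baits <- list()
  if (config@n_bait > 0L) {
    mz_by_z <- split(attrs$theo_mz, attrs$z)
    for (r in meta$run_id) {
      rows <- which(det$run_id == r)
      take <- rows[sample.int(length(rows), min(config@n_bait, length(rows)))]
      for (i in take) {
        zz <- det$z[i]
        repeat {
          shift <- sample(c(-1, 1), 1L) * runif(1, 25e-6, 60e-6)
          bmz <- det$theo_mz[i] * (1 + shift)
          ref <- mz_by_z[[as.character(zz)]]
          if (min(abs(bmz - ref) / ref) * 1e6 > 20) break
        }
        benv <- env_cache[[as.character(det$nres[i])]]
        length(benv) <- 5L; benv[is.na(benv)] <- 0
        benv <- pmax(benv * det$area[i] * (1 + rnorm(5, 0, 0.3)), 1e-6)
        baits[[length(baits) + 1L]] <- data.frame(
          run_id = r, mz = bmz, z = zz,
          rt_center_min = det$base_rt[i] + rnorm(1, 0, config@rt_jitter_sd),
          rt_width_min = runif(1, 0.25, 0.35), area = det$area[i] * 0.5,
          iso0 = benv[1], iso1 = benv[2], iso2 = benv[3], iso3 = benv[4],
          iso4 = benv[5], stringsAsFactors = FALSE)
      }
    }
  }
  bait_df <- if (length(baits)) do.call(rbind, baits) else NULL
  if (!is.null(bait_df)) features <- rbind(features, bait_df)

  ## --- PSMs ----------------------------------------------------------------
  msms <- det[has_msms == TRUE]
  n_true <- nrow(msms)
  true_psms <- data.frame(
    run_id = msms$run_id, peptide = msms$peptide, mods = msms$mods,
    z = msms$z,
    mz_obs = msms$theo_mz * (1 + rnorm(n_true, 0, config@psm_ppm_sd * 1e-6)),
    rt_min = msms$rt_center + rnorm(n_true, 0, 0.02),
    score = rgamma(n_true, 4, 0.5) + config@true_score_shift,
    decoy = FALSE, stringsAsFactors = FALSE)

  n_false <- round(config@false_psm_rate * n_true)
  fi <- sample.int(nrow(attrs), n_false, replace = TRUE)
  false_psms <- data.frame(
    run_id = sample(meta$run_id, n_false, replace = TRUE),
    peptide = attrs$peptide[fi], mods = attrs$mods[fi], z = attrs$z[fi],
    mz_obs = attrs$theo_mz[fi] * (1 + rnorm(n_false, 0, 8e-6)),
    rt_min = runif(n_false, config@gradient[1], config@gradient[2]),
    score = rgamma(n_false, 4, 0.5), decoy = FALSE, stringsAsFactors = FALSE)

  decoy_db <- generateDecoys(db[cats != "decoy"])
  dec_link <- do.call(rbind, lapply(seq_len(length(decoy_db)), function(i) {
    p <- trypticDigest(as.character(sequences(decoy_db))[i], 0L)$sequence
    p <- unique(p[nchar(p) >= 6 & nchar(p) <= 30])
    if (!length(p)) return(NULL)
    data.frame(peptide = p, stringsAsFactors = FALSE)
  }))
  ## decoy peptides colliding with target peptides would not map to decoys
  dec_peps <- setdiff(unique(dec_link$peptide), attrs$peptide)
  n_decoy <- n_false
  di <- sample(dec_peps, n_decoy, replace = TRUE)
  d_mods <- vapply(di, .camMods, "")
  d_z <- sample(2:4, n_decoy, replace = TRUE, prob = c(0.55, 0.33, 0.12))
  d_neutral <- peptideMass(di, d_mods)
  decoy_psms <- data.frame(
    run_id = sample(meta$run_id, n_decoy, replace = TRUE),
    peptide = di, mods = d_mods, z = d_z,
    mz_obs = mzFromMass(d_neutral, d_z) * (1 + rnorm(n_decoy, 0, 8e-6)),
    rt_min = runif(n_decoy, config@gradient[1], config@gradient[2]),
    score = rgamma(n_decoy, 4, 0.5), decoy = TRUE, stringsAsFactors = FALSE)

  psms <- rbind(true_psms, false_psms, decoy_psms)
  rownames(psms) <- NULL
  psm_class <- rep(c("true", "false", "decoy"),
                   c(n_true, n_false, n_decoy))

  ## --- rescue eligibility ground truth -------------------------------------
  det[, n_msms_dp := sum(has_msms), by = .(dp, peptide)]
  eligible <- det[has_msms == FALSE & n_msms_dp >= 1L,
                  .(run_id, peptide, mods, z)]

  list(meta = meta, psms = psms, features = features,
       truth = list(
         present = present,
         peptide_link = link,
         peptide_attrs = attrs,
         detections = as.data.frame(det[, .(run_id, dp, peptide, mods, z,
                                            area, rt_center, has_msms)]),
         rescue_eligible = as.data.frame(eligible),
         bait = if (!is.null(bait_df))
           bait_df[c("run_id", "mz", "z")] else
           data.frame(run_id = character(), mz = numeric(), z = integer()),
         psm_class = psm_class))
}
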