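#' @include AllClasses.R digest.R averagine.R
NULL

#' Signed mass deviation in ppm
#'
#' `1e6 * (observed_neutral - theoretical_neutral) / theoretical_neutral`
#' with `observed_neutral = observed_mz * z - z * proton`.
#'
#' @param observed_mz Observed m/z (Th), vectorized.
#' @param charge Charge state, vectorized.
#' @param theoretical_neutral Theoretical neutral mass (Da), vectorized.
#' @return Signed deviation in ppm.
#' @examples
#' massDeviationPpm(mzFromMass(1000.007, 2), 2, 1000)  # +7 ppm
#' @export
massDeviationPpm <- function(observed_mz, charge, theoretical_neutral) {
  if (any(theoretical_neutral <= 0))
    stop("theoretical neutral mass must be positive")
  if (any(charge < 1)) stop("charge must be at least 1")
  obs_neutral <- observed_mz * charge - charge * MASS_PROTON
  1e6 * (obs_neutral - theoretical_neutral) / theoretical_neutral
}

#' Reference retention-time windows from MS/MS detections
#'
#' For every peptide ion (sequence, modifications, charge) detected on the
#' MS/MS level, collects the retention times of all its detections within
#' one drug product and spans the window `[min RT, max RT]`; a single
#' detection gives a zero-width window. The mean chromatographic peak width
#' of the matched MS1 features is carried along as the width reference.
#'
#' @param detections data.frame of MS/MS detections with columns
#'   `drug_product`, `peptide`, `mods`, `z`, `rt_min` and optionally `width`
#'   (feature FWHM, minutes; may contain NA).
#' @return data.frame with one row per (drug_product, peptide, mods, z):
#'   `rt_lo`, `rt_hi`, `mean_width`, `n_msms`.
#' @examples
#' det <- data.frame(drug_product = "DP1", peptide = "AAAK", mods = "",
#'                   z = 2L, rt_min = c(40.2, 40.6), width = c(0.3, 0.32))
#' buildRtWindows(det)
#' @export
buildRtWindows <- function(detections) {
  stopifnot(all(c("drug_product", "peptide", "mods", "z", "rt_min") %in%
                names(detections)))
  dt <- data.table::as.data.table(detections)
  if (!"width" %in% names(dt)) dt[, width := NA_real_]
  win <- dt[, .(rt_lo = min(rt_min), rt_hi = max(rt_min),
                mean_width = if (all(is.na(width))) NA_real_
                             else mean(width, na.rm = TRUE),
                n_msms = .N),
            by = .(drug_product, peptide, mods, z)]
  as.data.frame(win)
}

#' Candidate MS1 features for one retention-time window
#'
#' Applies the three coarse gates of the full-scan search to the features of
#' a single run: retention-time center within the MS/MS window widened by
#' `feature_center_tolerance` on each edge, peak width within
#' `feature_duration_tolerance` of the reference mean width (skipped when the
#' reference width is unknown), and m/z within `precursor_tolerance_ppm` of
#' the theoretical m/z at the matching charge. If several features qualify,
#' the one closest in m/z is retained.
#'
#' @param features Feature data.frame of one run ([readFeatureTable()]
#'   layout).
#' @param window One-row window as produced by [buildRtWindows()] (list or
#'   data.frame row with `rt_lo`, `rt_hi`, `mean_width`).
#' @param theoretical_mz Theoretical m/z of the peptide ion (Th).
#' @param charge Charge state of the peptide ion.
#' @param config A [PipelineConfig-class].
#' @return The selected candidate feature row (data.frame with added
#'   `ppm_dev_mz` column), or a zero-row data.frame when nothing qualifies.
#' @export
findCandidates <- function(features, window, theoretical_mz, charge,
                           config = hcpConfig()) {
  fct <- config@feature_center_tolerance
  fdt <- config@feature_duration_tolerance
  keep <- features$z == charge &
    features$rt_center_min >= window$rt_lo - fct &
    features$rt_center_min <= window$rt_hi + fct
  if (!is.na(window$mean_width))
    keep <- keep & abs(features$rt_width_min - window$mean_width) <= fdt
  cand <- features[keep, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  ppm <- 1e6 * (cand$mz - theoretical_mz) / theoretical_mz
  cand <- cand[abs(ppm) <= config@precursor_tolerance_ppm, , drop = FALSE]
  ppm <- ppm[abs(ppm) <= config@precursor_tolerance_ppm]
  if (!nrow(cand)) return(cand)
  sel <- which.min(abs(ppm))
  out <- cand[sel, , drop = FALSE]
  out$ppm_dev_mz <- ppm[sel]
  out
}

#' Percentile reference thresholds from the MS/MS population
#'
#' Empirical percentiles (linear interpolation between order statistics) of
#' the signed mass deviations and MS1 correlations of all precursor ions for
#' which a fragment ion spectrum was available. An in silico candidate is
#' dismissed when its deviation falls outside the 2.5th-97.5th percentile
#' band or its correlation falls below the 5th percentile.
#'
#' @param ppm_dev Numeric vector of signed reference deviations (ppm).
#' @param ms1_corr Numeric vector of reference MS1 correlations (NAs are
#'   dropped).
#' @param config A [PipelineConfig-class] (supplies the percentile levels).
#' @param min_reference Minimum reference population size (default 20).
#' @return List with `massdev_lo`, `massdev_hi`, `corr_lo`, `n_reference`.
#' @examples
#' percentileReference(rep(c(-2, -1, 0, 1, 2), 20), rep(0.99, 100))
#' @export
percentileReference <- function(ppm_dev, ms1_corr, config = hcpConfig(),
                                min_reference = 20L) {
  ppm_dev <- ppm_dev[!is.na(ppm_dev)]
  ms1_corr <- ms1_corr[!is.na(ms1_corr)]
  if (length(ppm_dev) < min_reference || length(ms1_corr) < min_reference)
    stop("fewer than ", min_reference, " reference precursors; ",
         "provide a larger MS/MS-identified population")
  p <- config@mass_dev_percentiles / 100
  bounds <- unname(quantile(ppm_dev, p, type = 7))
  corr_lo <- unname(quantile(ms1_corr, config@ms1_corr_percentile / 100,
                             type = 7))
  list(massdev_lo = bounds[1], massdev_hi = bounds[2], corr_lo = corr_lo,
       n_reference = length(ppm_dev))
}

#' Evaluate an in silico candidate against the percentile thresholds
#'
#' A candidate that already passed the retention-time gate is accepted when
#' its mass deviation lies within the percentile band, its envelope has at
#' least `min_peaks` usable isotopologue peaks, and its MS1 correlation
#' exceeds the correlation threshold. `rejection_reason` records the first
#' failed criterion (`mass_dev`, `low_information`, `correlation`).
#'
#' @param ppm_dev Signed mass deviation of the candidate (ppm).
#' @param ms1_corr MS1 correlation of the candidate (NA when undefined).
#' @param n_peaks Number of aligned envelope peaks.
#' @param thresholds List from [percentileReference()].
#' @param min_peaks Minimum aligned peaks (default 3).
#' @return List with `accepted` (logical) and `rejection_reason` (NA when
#'   accepted).
#' @export
acceptInSilico <- function(ppm_dev, ms1_corr, n_peaks, thresholds,
                           min_peaks = 3L) {
  if (ppm_dev < thresholds$massdev_lo || ppm_dev > thresholds$massdev_hi)
    return(list(accepted = FALSE, rejection_reason = "mass_dev"))
  if (n_peaks < min_peaks || is.na(ms1_corr))
    return(list(accepted = FALSE, rejection_reason = "low_information"))
  if (ms1_corr <= thresholds$corr_lo)
    return(list(accepted = FALSE, rejection_reason = "correlation"))
  list(accepted = TRUE, rejection_reason = NA_character_)
}

## theoretical averagine envelope per residue count, cached
.averagineEnvelopes <- function(nres_values, max_peaks = 5L) {
  env <- lapply(sort(unique(nres_values)), function(n)
    isotopeDistribution(averagineComposition(n), max_peaks))
  names(env) <- sort(unique(nres_values))
  env
}

## correlation of envelope rows against cached averagine envelopes;
## returns list(corr, n_peaks)
.envelopeCorrelations <- function(env_mat, nres, cache, min_peaks = 3L) {
  n <- nrow(env_mat)
  corr <- rep(NA_real_, n)
  npk <- integer(n)
  for (i in seq_len(n)) {
    obs <- env_mat[i, ]
    obs <- obs[seq_len(max(which(obs > 0), na.rm = TRUE))]  # trim zero tail
    theo <- cache[[as.character(nres[i])]]
    k <- min(length(obs), length(theo), 5L)
    npk[i] <- k
    if (k >= min_peaks && stats::sd(obs[seq_len(k)]) > 0)
      corr[i] <- stats::cor(obs[seq_len(k)], theo[seq_len(k)])
  }
  list(corr = corr, n_peaks = npk)
}

## nearest-mz feature per query within an RT interval, via non-equi join.
## queries: data.table with run_id, z, rt_a, rt_b, theo_mz, query_id
## returns data.table query_id, feat_row, ppm_dev_mz
.nearestFeature <- function(queries, feat_dt, tol_ppm, width_ref = NULL,
                            width_tol = NULL) {
  hits <- feat_dt[queries,
                  .(query_id = i.query_id, feat_row = x.feat_row,
                    f_mz = x.mz, f_width = x.rt_width_min,
                    theo_mz = i.theo_mz),
                  on = .(run_id, z, rt_c >= rt_a, rt_c <= rt_b),
                  nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(hits[, .(query_id, feat_row,
                                   ppm_dev_mz = numeric(0))])
  if (!is.null(width_ref)) {
    wref <- width_ref[hits$query_id]
    keep <- is.na(wref) | abs(hits$f_width - wref) <= width_tol
    hits <- hits[keep]
    if (!nrow(hits)) return(hits[, .(query_id, feat_row,
                                     ppm_dev_mz = numeric(0))])
  }
  hits[, ppm_dev_mz := 1e6 * (f_mz - theo_mz) / theo_mz]
  hits <- hits[abs(ppm_dev_mz) <= tol_ppm]
  if (!nrow(hits)) return(hits[, .(query_id, feat_row, ppm_dev_mz)])
  data.table::setorder(hits, query_id)
  hits[, .SD[which.min(abs(ppm_dev_mz))], by = query_id][
    , .(query_id, feat_row, ppm_dev_mz)]
}

#' Rescue peptides on the full-scan MS level
#'
#' The match-between-runs stage. For each peptide ion identified at least
#' once via MS/MS, a retention-time window is spanned per drug product; runs
#' of the same drug product lacking an MS/MS identification of that ion are
#' searched for MS1 features inside the widened window with a compatible
#' peak width and m/z. Each candidate is then accepted or dismissed by the
#' percentile filters: its mass deviation must fall within the
#' 2.5th-97.5th percentile band of the MS/MS reference deviations and its
#' averagine MS1 correlation must exceed the 5th percentile of the reference
#' correlations.
#'
#' @param psms FDR-accepted target PSM data.frame ([readPsmTable()] layout).
#' @param features Feature data.frame ([readFeatureTable()] layout) covering
#'   all runs.
#' @param meta Run metadata ([readRunMetadata()] layout).
#' @param config A [PipelineConfig-class].
#' @param scope `"global"` (default): percentile reference population is the
#'   whole processed dataset; `"drug_product"`: computed per drug product.
#' @param min_reference Minimum reference population size (default 20).
#' @return List with elements:
#'   \describe{
#'     \item{matches}{data.frame of all evaluated in silico candidates:
#'       `run_id`, `drug_product`, `peptide`, `mods`, `z`, `rt_center`,
#'       `mz`, `area`, `ppm_dev`, `ms1_corr`, `n_peaks`, `accepted`,
#'       `rejection_reason`.}
#'     \item{thresholds}{percentile thresholds used (list, or list per drug
#'       product).}
#'     \item{reference}{data.frame of the MS/MS reference population with
#'       `ppm_dev` and `ms1_corr` per PSM.}
#'   }
#' @export
rescuePeptides <- function(psms, features, meta, config = hcpConfig(),
                           scope = c("global", "drug_product"),
                           min_reference = 20L) {
  scope <- match.arg(scope)
  validateRunMetadata(meta)
  empty <- data.frame(run_id = character(), drug_product = character(),
                      peptide = character(), mods = character(),
                      z = integer(), rt_center = numeric(), mz = numeric(),
                      area = numeric(), ppm_dev = numeric(),
                      ms1_corr = numeric(), n_peaks = integer(),
                      accepted = logical(), rejection_reason = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(psms))
    return(list(matches = empty, thresholds = NULL,
                reference = data.frame()))

  fct <- config@feature_center_tolerance
  psm <- data.table::as.data.table(psms)
  psm <- merge(psm, data.table::as.data.table(meta[c("run_id", "drug_product")]),
               by = "run_id")
  psm[, neutral_mass := peptideMass(peptide, mods)]
  psm[, theo_mz := mzFromMass(neutral_mass, z)]
  psm[, ppm_dev := massDeviationPpm(mz_obs, z, neutral_mass)]
  psm[, nres := nchar(peptide)]

  feat <- data.table::as.data.table(features)
  feat[, feat_row := .I]
  feat[, rt_c := rt_center_min]
  env_mat <- envelopeMatrix(features)
  env_cache <- .averagineEnvelopes(psm$nres, max_peaks = 5L)

  ## --- reference population: match each PSM to its MS1 feature ------------
  psm[, query_id := .I]
  psm[, `:=`(rt_a = rt_min - fct, rt_b = rt_min + fct)]
  ref_hit <- .nearestFeature(psm, feat, config@precursor_tolerance_ppm)
  psm[, `:=`(ref_feat = NA_integer_, ms1_corr = NA_real_,
             feat_width = NA_real_, feat_area = NA_real_)]
  if (nrow(ref_hit)) {
    psm[ref_hit$query_id, ref_feat := ref_hit$feat_row]
    matched <- !is.na(psm$ref_feat)
    cc <- .envelopeCorrelations(env_mat[psm$ref_feat[matched], , drop = FALSE],
                                psm$nres[matched], env_cache)
    psm[matched, ms1_corr := cc$corr]
    psm[matched, feat_width := feat$rt_width_min[ref_feat]]
    psm[matched, feat_area := feat$area[ref_feat]]
  }

  reference <- as.data.frame(psm[, .(run_id, drug_product, peptide, mods, z,
                                     ppm_dev, ms1_corr, area = feat_area)])

  thresholds <- if (scope == "global") {
    percentileReference(psm$ppm_dev, psm$ms1_corr, config, min_reference)
  } else {
    dps <- unique(psm$drug_product)
    setNames(lapply(dps, function(d)
      percentileReference(psm$ppm_dev[psm$drug_product == d],
                          psm$ms1_corr[psm$drug_product == d],
                          config, min_reference)), dps)
  }

  ## --- retention-time windows and query pairs ------------------------------
  win <- data.table::as.data.table(
    buildRtWindows(as.data.frame(
      psm[, .(drug_product, peptide, mods, z, rt_min, width = feat_width)])))
  runs <- data.table::as.data.table(meta[c("run_id", "drug_product")])
  pairs <- merge(win, runs, by = "drug_product", allow.cartesian = TRUE)
  ## a run never holds both an MS/MS detection and an in silico match
  seen <- unique(psm[, .(run_id, peptide, mods, z)])
  pairs <- pairs[!seen, on = .(run_id, peptide, mods, z)]
  if (!nrow(pairs))
    return(list(matches = empty, thresholds = thresholds,
                reference = reference))

  pairs[, neutral_mass := peptideMass(peptide, mods)]
  pairs[, theo_mz := mzFromMass(neutral_mass, z)]
  pairs[, `:=`(rt_a = rt_lo - fct, rt_b = rt_hi + fct)]
  pairs[, query_id := .I]
  cand <- .nearestFeature(pairs, feat, config@precursor_tolerance_ppm,
                          width_ref = pairs$mean_width,
                          width_tol = config@feature_duration_tolerance)
  if (!nrow(cand))
    return(list(matches = empty, thresholds = thresholds,
                reference = reference))

  sel <- pairs[cand$query_id]
  frow <- cand$feat_row
  cc <- .envelopeCorrelations(env_mat[frow, , drop = FALSE],
                              nchar(sel$peptide), env_cache)
  dev <- massDeviationPpm(feat$mz[frow], sel$z, sel$neutral_mass)

  out <- data.frame(run_id = sel$run_id, drug_product = sel$drug_product,
                    peptide = sel$peptide, mods = sel$mods, z = sel$z,
                    rt_center = feat$rt_center_min[frow], mz = feat$mz[frow],
                    area = feat$area[frow], ppm_dev = dev,
                    ms1_corr = cc$corr, n_peaks = cc$n_peaks,
                    stringsAsFactors = FALSE)
  verdicts <- lapply(seq_len(nrow(out)), function(i) {
    th <- if (scope == "global") thresholds
          else thresholds[[out$drug_product[i]]]
    acceptInSilico(out$ppm_dev[i], out$ms1_corr[i], out$n_peaks[i], th)
  })
  out$accepted <- vapply(verdicts, `[[`, TRUE, "accepted")
  out$rejection_reason <- vapply(verdicts, `[[`, "", "rejection_reason")
  list(matches = out, thresholds = thresholds, reference = reference)
}
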