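#' @include formats.R inference.R rescue.R profiling.R compare.R
NULL

#' Run the full HCP discovery pipeline
#'
#' Executes all stages on one dataset: reversed-sequence decoy generation,
#' PSM-level FDR filtering, shared-peptide protein inference, protein-level
#' FDR with reverse-count cap, full-scan in silico peptide rescue, category
#' filtering with the unspecific-cleavage rule, credibility tiers, profile
#' construction per replicate / fraction / drug product, and top-3 relative
#' quantification.
#'
#' @param db The search [ProteinDatabase-class] (without decoys).
#' @param psms PSM table ([readPsmTable()] layout), targets and decoys.
#' @param features MS1 feature table ([readFeatureTable()] layout).
#' @param meta Run metadata ([readRunMetadata()] layout).
#' @param config A [PipelineConfig-class].
#' @param rescue_scope Percentile reference scope, `"global"` or
#'   `"drug_product"`.
#' @return List with:
#'   \describe{
#'     \item{psm_fdr}{PSM-level FDR result.}
#'     \item{proteins}{accepted protein evidence table, including
#'       list-column `insilico_peptides` and `tier`.}
#'     \item{insilico}{all evaluated in silico candidates.}
#'     \item{detections}{per-run peptide-level detections
#'       (`run_id`, `accession`, `peptide`, `type`).}
#'     \item{profiles}{lists of [HCPProfile-class] objects at `replicate`,
#'       `fraction` and `drug_product` level (named by key).}
#'     \item{abundance}{top-3 relative abundance matrix (percent of column
#'       maximum).}
#'     \item{keratins, non_hcps, removed}{category filtering results.}
#'     \item{thresholds}{rescue percentile thresholds.}
#'   }
#' @export
runHcpPipeline <- function(db, psms, features, meta, config = hcpConfig(),
                           rescue_scope = "global") {
  stopifnot(is(db, "ProteinDatabase"))
  validateRunMetadata(meta)
  full_db <- buildSearchDatabase(db, generateDecoys(db))

  ## --- PSM FDR ---------------------------------------------------------
  fdr <- psmFdrFilter(psms, config@psm_fdr)
  kept_all <- rbind(fdr$kept, fdr$kept_decoys)

  ## --- uniqueness map: decoys excluded for target-matching peptides -----
  pepmap <- mapUniqueness(unique(kept_all$peptide), full_db,
                          include_decoys = TRUE)
  has_target <- vapply(pepmap$proteins, function(p)
    any(!startsWith(p, "DECOY_")), TRUE)
  pepmap$proteins[has_target] <- lapply(pepmap$proteins[has_target],
                                        function(p)
                                          p[!startsWith(p, "DECOY_")])
  pepmap$n_proteins <- lengths(pepmap$proteins)
  pepmap$is_unique <- pepmap$n_proteins == 1L

  ## --- inference + protein FDR ------------------------------------------
  evidence <- inferProteins(kept_all, pepmap, config)
  proteins <- proteinFdrFilter(evidence, config@protein_fdr,
                               config@max_reverse_count)

  ## --- in silico rescue ---------------------------------------------------
  rescue <- rescuePeptides(fdr$kept, features, meta, config,
                           scope = rescue_scope)
  accepted <- rescue$matches[rescue$matches$accepted, , drop = FALSE]

  ## peptide -> protein assignment from the accepted protein list
  assign_map <- character()
  for (i in seq_len(nrow(proteins))) {
    p <- c(proteins$unique_peptides[[i]], proteins$shared_peptides[[i]])
    assign_map[p] <- proteins$accession[i]
  }
  proteins$insilico_peptides <- I(lapply(proteins$accession, function(a) {
    idx <- which(assign_map[accepted$peptide] == a)
    unique(accepted$peptide[idx])
  }))

  ## --- category filtering + unspecific-cleavage rule ----------------------
  split_ev <- filterCategories(proteins, db)
  hcps <- split_ev$hcps
  hcps$tier <- assignTiers(hcps$unique_peptides, hcps$shared_peptides,
                           hcps$insilico_peptides,
                           config@min_unique_peptide_length)
  hcps <- hcps[!is.na(hcps$tier), , drop = FALSE]

  ## --- per-run detections --------------------------------------------------
  detections <- .perRunDetections(fdr$kept, accepted, hcps, assign_map)

  ## --- profiles -------------------------------------------------------------
  profiles <- .buildProfiles(detections, meta,
                             config@min_unique_peptide_length)

  ## --- quantification -------------------------------------------------------
  ref <- rescue$reference
  quant_rows <- rbind(
    data.frame(run_id = ref$run_id, peptide = ref$peptide, mods = ref$mods,
               z = ref$z, area = ref$area, stringsAsFactors = FALSE),
    data.frame(run_id = accepted$run_id, peptide = accepted$peptide,
               mods = accepted$mods, z = accepted$z, area = accepted$area,
               stringsAsFactors = FALSE))
  quant_rows <- quant_rows[!is.na(quant_rows$area), , drop = FALSE]
  ## one area per (run, peptide ion); repeated PSMs of one ion count once
  quant_rows <- quant_rows[!duplicated(quant_rows[c("run_id", "peptide",
                                                    "mods", "z")]), ,
                           drop = FALSE]
  quant_rows$accession <- assign_map[quant_rows$peptide]
  quant_rows <- quant_rows[!is.na(quant_rows$accession), , drop = FALSE]
  abundance <- if (nrow(quant_rows))
    quantifyTop3(quant_rows[c("run_id", "accession", "peptide", "area")],
                 meta, category(db), config@top_n_quant) else NULL

  list(psm_fdr = fdr$result, proteins = hcps, all_proteins = proteins,
       insilico = rescue$matches, detections = detections,
       profiles = profiles, abundance = abundance,
       keratins = split_ev$keratins, non_hcps = split_ev$non_hcps,
       removed = split_ev$removed, thresholds = rescue$thresholds,
       config = config)
}

## per-run peptide-level detections for accepted HCPs
.perRunDetections <- function(kept_psms, accepted_insilico, hcps,
                              assign_map) {
  allowed <- setNames(
    lapply(seq_len(nrow(hcps)), function(i)
      list(unique = hcps$unique_peptides[[i]],
           shared = hcps$shared_peptides[[i]],
           insilico = hcps$insilico_peptides[[i]])),
    hcps$accession)
  rows <- list()
  addRows <- function(run, pep, acc, type) {
    rows[[length(rows) + 1L]] <<- data.frame(
      run_id = run, accession = acc, peptide = pep, type = type,
      stringsAsFactors = FALSE)
  }
  if (nrow(kept_psms)) {
    acc <- assign_map[kept_psms$peptide]
    ok <- !is.na(acc) & acc %in% names(allowed)
    if (any(ok)) {
      sub <- kept_psms[ok, , drop = FALSE]
      sacc <- acc[ok]
      type <- vapply(seq_len(nrow(sub)), function(i) {
        al <- allowed[[sacc[i]]]
        if (sub$peptide[i] %in% al$unique) "unique_msms"
        else if (sub$peptide[i] %in% al$shared) "shared_msms"
        else NA_character_
      }, "")
      keep <- !is.na(type)
      if (any(keep))
        addRows(sub$run_id[keep], sub$peptide[keep], sacc[keep], type[keep])
    }
  }
  if (nrow(accepted_insilico)) {
    acc <- assign_map[accepted_insilico$peptide]
    ok <- !is.na(acc) & acc %in% names(allowed)
    if (any(ok)) {
      sub <- accepted_insilico[ok, , drop = FALSE]
      sacc <- acc[ok]
      keep <- vapply(seq_len(nrow(sub)), function(i)
        sub$peptide[i] %in% allowed[[sacc[i]]]$insilico, TRUE)
      if (any(keep))
        addRows(sub$run_id[keep], sub$peptide[keep], sacc[keep], "insilico")
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(run_id = character(), accession = character(),
               peptide = character(), type = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## replicate/fraction/drug-product profiles from per-run detections
.buildProfiles <- function(detections, meta, min_unique_len = 5L) {
  reps <- list()
  for (i in seq_len(nrow(meta))) {
    r <- meta$run_id[i]
    d <- detections[detections$run_id == r, , drop = FALSE]
    mem <- integer()
    if (nrow(d)) {
      by_acc <- split(d, d$accession)
      mem <- vapply(by_acc, function(x) {
        u <- unique(x$peptide[x$type == "unique_msms"])
        s <- unique(x$peptide[x$type == "shared_msms"])
        ins <- unique(x$peptide[x$type == "insilico"])
        assignTiers(list(u), list(s), list(ins), min_unique_len)
      }, integer(1))
      mem <- mem[!is.na(mem)]
    }
    reps[[r]] <- HCPProfile("replicate",
                            c(drug_product = meta$drug_product[i],
                              fraction = meta$fraction[i],
                              replicate = as.character(meta$replicate[i])),
                            mem)
  }
  frac_key <- vapply(reps, function(p)
    paste(p@key["drug_product"], p@key["fraction"], sep = ":"), "")
  fracs <- lapply(split(reps, frac_key), aggregateProfiles, "fraction")
  dp_key <- vapply(fracs, function(p) unname(p@key["drug_product"]), "")
  dps <- lapply(split(fracs, dp_key), aggregateProfiles, "drug_product")
  list(replicate = reps, fraction = fracs, drug_product = dps)
}
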