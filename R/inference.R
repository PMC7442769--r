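#' @include AllClasses.R digest.R
NULL

#' Generate reversed-sequence decoys
#'
#' One decoy per target entry, with the full sequence reversed, the
#' accession prefixed `DECOY_` and category `"decoy"`. Palindromic sequences
#' (decoy identical to target) are reported via a message.
#'
#' @param database A [ProteinDatabase-class] without decoys.
#' @return A [ProteinDatabase-class] of decoy entries, same length as the
#'   input.
#' @examples
#' db <- ProteinDatabase("P1", "PEPTIDEK")
#' as.character(sequences(generateDecoys(db)))
#' @export
generateDecoys <- function(database) {
  stopifnot(is(database, "ProteinDatabase"))
  if (any(category(database) == "decoy"))
    stop("database already contains decoy entries")
  rev_seqs <- as.character(Biostrings::reverse(sequences(database)))
  pal <- rev_seqs == as.character(sequences(database))
  if (any(pal))
    message("palindromic sequence(s), decoy equals target: ",
            paste(accession(database)[pal], collapse = ", "))
  ProteinDatabase(paste0("DECOY_", accession(database)), rev_seqs,
                  "decoy", unname(description(database)))
}

#' PSM-level target-decoy FDR filter
#'
#' Finds the most permissive score threshold `t` such that the decoy-based
#' FDR estimate `#{decoy PSMs >= t} / #{target PSMs >= t}` stays at or below
#' `q`, and keeps the target PSMs scoring at least `t`. Decoy PSMs above the
#' threshold are returned separately so that decoy proteins can be ranked in
#' the subsequent protein-level filter.
#'
#' @param psms PSM data.frame with at least `score` and `decoy` columns.
#' @param q Target FDR fraction (default 0.01).
#' @return List with elements `kept` (target PSMs above threshold),
#'   `kept_decoys` (decoy PSMs above threshold) and `result`, a list with
#'   `score_threshold`, `n_target`, `n_decoy` and `fdr_estimate =
#'   n_decoy / max(n_target, 1)`.
#' @examples
#' psms <- data.frame(score = c(10, 9, 8, 1), decoy = c(FALSE, FALSE, FALSE, TRUE))
#' psmFdrFilter(psms, 0.01)$result
#' @export
psmFdrFilter <- function(psms, q = 0.01) {
  empty <- list(kept = psms[0, , drop = FALSE],
                kept_decoys = psms[0, , drop = FALSE],
                result = list(score_threshold = Inf, n_target = 0L,
                              n_decoy = 0L, fdr_estimate = 0))
  if (!nrow(psms)) return(empty)
  stopifnot(all(c("score", "decoy") %in% names(psms)))
  ord <- order(psms$score, decreasing = TRUE)
  dec <- psms$decoy[ord]
  cum_dec <- cumsum(dec)
  cum_tar <- cumsum(!dec)
  sc <- psms$score[ord]
  ## evaluate at the last index of each tied score block, so "score >= t"
  ## semantics hold
  block_end <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  ok <- cum_dec[block_end] / pmax(cum_tar[block_end], 1L) <= q
  if (!any(ok)) return(empty)
  idx <- block_end[max(which(ok))]
  t <- sc[idx]
  kept <- psms[psms$score >= t & !psms$decoy, , drop = FALSE]
  kept_dec <- psms[psms$score >= t & psms$decoy, , drop = FALSE]
  n_target <- nrow(kept); n_decoy <- nrow(kept_dec)
  list(kept = kept, kept_decoys = kept_dec,
       result = list(score_threshold = t, n_target = n_target,
                     n_decoy = n_decoy,
                     fdr_estimate = n_decoy / max(n_target, 1L)))
}

#' Protein inference with shared peptides
#'
#' Ranks proteins by their total evidence (sum over distinct peptides of
#' each peptide's best PSM score from unique peptides), assigns every shared
#' peptide to the highest-ranking of its candidate proteins (ties broken by
#' lexicographic accession), recomputes totals including assigned shared
#' peptides and re-ranks. A protein is reported if it has at least one
#' unique peptide of at least `min_unique_peptide_length` residues, or at
#' least one shared peptide assigned to it.
#'
#' @param psms PSM data.frame (target and above-threshold decoy PSMs) with
#'   columns `peptide` and `score`.
#' @param peptide_map Uniqueness mapping from [mapUniqueness()] covering the
#'   peptides in `psms` (computed with `include_decoys = TRUE` when decoy
#'   PSMs are present).
#' @param config A [PipelineConfig-class].
#' @return data.frame with one row per reported protein: `accession`,
#'   `rank`, `total_score`, `n_unique_msms`, `n_shared_msms`, `is_decoy`,
#'   plus list-columns `unique_peptides` and `shared_peptides`. Ordered by
#'   rank.
#' @export
inferProteins <- function(psms, peptide_map, config = hcpConfig()) {
  stopifnot(all(c("peptide", "score") %in% names(psms)))
  if (!nrow(psms))
    return(data.frame(accession = character(), rank = integer(),
                      total_score = numeric(), n_unique_msms = integer(),
                      n_shared_msms = integer(), is_decoy = logical(),
                      unique_peptides = I(list()), shared_peptides = I(list()),
                      stringsAsFactors = FALSE))
  ## best score per distinct peptide
  dt <- data.table::as.data.table(psms)[, .(best_score = max(score)),
                                        by = .(peptide)]
  map <- peptide_map[match(dt$peptide, peptide_map$peptide), ]
  orphan <- map$n_proteins == 0L | is.na(map$n_proteins)
  if (any(orphan)) {
    warning(sum(orphan), " peptide(s) map to no protein and are excluded")
    dt <- dt[!orphan]; map <- map[!orphan, ]
  }
  if (!nrow(dt))
    return(inferProteins(psms[0, , drop = FALSE], peptide_map, config))

  pep <- dt$peptide
  score <- dt$best_score
  prots <- map$proteins
  uniq <- map$n_proteins == 1L

  ## initial evidence from unique peptides
  uacc <- unlist(prots[uniq], use.names = FALSE)
  uscore <- score[uniq]
  base <- tapply(uscore, uacc, sum)
  all_acc <- sort(unique(unlist(prots, use.names = FALSE)))
  ev0 <- setNames(numeric(length(all_acc)), all_acc)
  ev0[names(base)] <- base
  ## initial rank: total evidence desc, ties by accession (all_acc sorted)
  rank0 <- setNames(rank(-ev0, ties.method = "first"), all_acc)

  ## assign each shared peptide to its highest-ranking candidate
  shared_idx <- which(!uniq)
  assigned <- vapply(shared_idx, function(i) {
    cand <- prots[[i]]
    cand[which.min(rank0[cand])]
  }, "")

  total <- ev0
  if (length(shared_idx))
    for (j in seq_along(shared_idx))
      total[assigned[j]] <- total[assigned[j]] + score[shared_idx[j]]

  min_len <- config@min_unique_peptide_length
  per_protein <- lapply(all_acc, function(a) {
    ui <- which(uniq & vapply(prots, function(p) a %in% p, TRUE))
    si <- shared_idx[assigned == a]
    list(unique = pep[ui], shared = pep[si])
  })
  names(per_protein) <- all_acc
  n_unique5 <- vapply(per_protein, function(x)
    sum(nchar(x$unique) >= min_len), integer(1))
  n_shared <- vapply(per_protein, function(x) length(x$shared), integer(1))
  identified <- n_unique5 >= 1L | n_shared >= 1L

  out <- data.frame(accession = all_acc, total_score = unname(total),
                    n_unique_msms = unname(vapply(per_protein, function(x)
                      length(x$unique), integer(1))),
                    n_shared_msms = unname(n_shared),
                    stringsAsFactors = FALSE)
  out$unique_peptides <- I(lapply(per_protein, `[[`, "unique"))
  out$shared_peptides <- I(lapply(per_protein, `[[`, "shared"))
  out$is_decoy <- startsWith(out$accession, "DECOY_")
  out <- out[identified, , drop = FALSE]
  out <- out[order(-out$total_score, out$accession), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[c("accession", "rank", "total_score", "n_unique_msms",
        "n_shared_msms", "is_decoy", "unique_peptides", "shared_peptides")]
}

#' Protein-level FDR filter with reverse-count cap
#'
#' Truncates the ranked protein list at the last position where both the
#' cumulative decoy/target ratio stays at or below `q` and the cumulative
#' decoy count stays at or below `max_reverse_count` ("1% or 20 reverse
#' count"). Decoy entries are removed from the output.
#'
#' @param proteins Ranked protein data.frame from [inferProteins()] with
#'   columns `accession` and `is_decoy`, ordered by decreasing evidence.
#' @param q Protein-level FDR fraction (default 0.01).
#' @param max_reverse_count Cap on accepted decoys (default 20).
#' @return The accepted target proteins (decoys removed), re-ranked.
#' @export
proteinFdrFilter <- function(proteins, q = 0.01, max_reverse_count = 20L) {
  if (!nrow(proteins)) return(proteins)
  stopifnot("is_decoy" %in% names(proteins))
  cum_dec <- cumsum(proteins$is_decoy)
  cum_tar <- cumsum(!proteins$is_decoy)
  ok <- (cum_dec / pmax(cum_tar, 1L) <= q) & (cum_dec <= max_reverse_count)
  if (!any(ok)) return(proteins[0, , drop = FALSE])
  keep <- seq_len(max(which(ok)))
  out <- proteins[keep, , drop = FALSE]
  out <- out[!out$is_decoy, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
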