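#' @include AllClasses.R profiling.R
NULL

#' Jaccard index of two accession sets
#'
#' `|a intersect b| / |a union b|`: 1 means exactly the same HCPs were
#' identified in two samples, 0 means no HCP is shared. Undefined when both
#' sets are empty.
#'
#' @param a,b Character vectors (sets; duplicates ignored).
#' @return Jaccard index in `[0, 1]`.
#' @examples
#' jaccardIndex(c("A", "B"), c("B", "C"))  # 1/3
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L)
    stop("Jaccard index undefined: both sets are empty")
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard matrix of profiles
#'
#' @param profiles Named list of [HCPProfile-class] objects or of character
#'   vectors (accession sets).
#' @param min_tier Minimum credibility tier applied to profile members
#'   (default 1, i.e. irrespective of credibility).
#' @return Symmetric matrix of Jaccard indices with unit diagonal. Pairs
#'   where both sets are empty yield NA with a warning.
#' @export
jaccardMatrix <- function(profiles, min_tier = 1L) {
  sets <- .profileSets(profiles, min_tier)
  n <- length(sets)
  labels <- names(sets)
  m <- diag(1, n)
  dimnames(m) <- list(labels, labels)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    v <- tryCatch(jaccardIndex(sets[[i]], sets[[j]]), error = function(e) {
      warning("undefined similarity for pair ", labels[i], " / ", labels[j])
      NA_real_
    })
    m[i, j] <- m[j, i] <- v
  }
  m
}

.profileSets <- function(profiles, min_tier = 1L) {
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be named")
  lapply(profiles, function(p) {
    if (is(p, "HCPProfile")) names(members(filterByTier(p, min_tier)))
    else unique(as.character(p))
  })
}

#' Repeatability of replicate HCP profiles by credibility level
#'
#' For each minimum credibility tier, profile members are filtered to that
#' tier and all pairs of replicates within each (drug product, fraction) are
#' compared by Jaccard index; with `f` fractions and `r` replicates each
#' this yields `f * choose(r, 2)` comparisons per level. Each level is
#' summarized by median, quartiles, interquartile range and whiskers
#' extending to the most extreme values no further than 1.5 IQR from the
#' quartiles.
#'
#' @param profiles List of replicate-level [HCPProfile-class] objects.
#' @param min_tiers Integer vector of minimum tiers to sweep (default 1:4).
#' @return List with `values` (data.frame: `min_tier`, `drug_product`,
#'   `fraction`, `replicate_a`, `replicate_b`, `jaccard`) and `summary`
#'   (data.frame per tier: `n_pairs`, `median`, `q1`, `q3`, `iqr`,
#'   `whisker_lo`, `whisker_hi`).
#' @export
repeatability <- function(profiles, min_tiers = 1:4) {
  stopifnot(all(vapply(profiles, is, TRUE, "HCPProfile")),
            all(vapply(profiles, profileLevel, "") == "replicate"))
  key <- vapply(profiles, function(p)
    paste(p@key["drug_product"], p@key["fraction"], sep = "\r"), "")
  groups <- split(seq_along(profiles), key)
  vals <- list()
  for (g in groups) {
    if (length(g) < 2L) {
      warning("fraction with a single replicate skipped: ",
              paste(profiles[[g[1]]]@key, collapse = "/"))
      next
    }
    prs <- combn(g, 2L)
    for (L in min_tiers) for (k in seq_len(ncol(prs))) {
      i <- prs[1, k]; j <- prs[2, k]
      a <- names(members(filterByTier(profiles[[i]], L)))
      b <- names(members(filterByTier(profiles[[j]], L)))
      jv <- if (length(a) == 0L && length(b) == 0L) {
        warning("pair with two empty profiles excluded at tier ", L)
        NA_real_
      } else jaccardIndex(a, b)
      vals[[length(vals) + 1L]] <- data.frame(
        min_tier = L,
        drug_product = unname(profiles[[i]]@key["drug_product"]),
        fraction = unname(profiles[[i]]@key["fraction"]),
        replicate_a = unname(profiles[[i]]@key["replicate"]),
        replicate_b = unname(profiles[[j]]@key["replicate"]),
        jaccard = jv, stringsAsFactors = FALSE)
    }
  }
  values <- if (length(vals)) do.call(rbind, vals) else
    data.frame(min_tier = integer(), drug_product = character(),
               fraction = character(), replicate_a = character(),
               replicate_b = character(), jaccard = numeric())
  summ <- do.call(rbind, lapply(min_tiers, function(L) {
    v <- values$jaccard[values$min_tier == L]
    v_ok <- v[!is.na(v)]
    if (!length(v_ok))
      return(data.frame(min_tier = L, n_pairs = length(v), median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
                        whisker_lo = NA_real_, whisker_hi = NA_real_))
    qs <- quantile(v_ok, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- qs[3] - qs[1]
    lo_lim <- qs[1] - 1.5 * iqr
    hi_lim <- qs[3] + 1.5 * iqr
    data.frame(min_tier = L, n_pairs = length(v), median = qs[2],
               q1 = qs[1], q3 = qs[3], iqr = iqr,
               whisker_lo = min(v_ok[v_ok >= lo_lim]),
               whisker_hi = max(v_ok[v_ok <= hi_lim]))
  }))
  list(values = values, summary = summ)
}

#' Hierarchical clustering of profiles on Jaccard distance
#'
#' Agglomerative clustering of profiles using Jaccard distance `1 - J` as
#' dissimilarity. Returns the merge tree, the leaf order for heatmap
#' rendering, the Jaccard matrix (fraction and percent) and a Newick string
#' of the dendrogram.
#'
#' @param profiles Named list of [HCPProfile-class] objects or accession
#'   sets (at least 2).
#' @param linkage Linkage method for [stats::hclust()] (default
#'   `"complete"`).
#' @param min_tier Minimum credibility tier (default 1).
#' @return List with `hclust`, `order` (leaf labels in dendrogram order),
#'   `jaccard` (matrix in `[0,1]`), `jaccard_percent`, `newick`.
#' @examples
#' sets <- list(r1 = c("A", "B", "C"), r2 = c("A", "B"), r3 = c("X", "Y"))
#' clusterProfiles(sets)$order
#' @export
clusterProfiles <- function(profiles, linkage = "complete", min_tier = 1L) {
  if (length(profiles) < 2L) stop("need at least 2 profiles to cluster")
  J <- jaccardMatrix(profiles, min_tier)
  if (anyNA(J)) {
    bad <- which(is.na(J), arr.ind = TRUE)[1, ]
    stop("undefined pairwise similarity between ",
         rownames(J)[bad[1]], " and ", colnames(J)[bad[2]])
  }
  hc <- hclust(as.dist(1 - J), method = linkage)
  list(hclust = hc, order = hc$labels[hc$order], jaccard = J,
       jaccard_percent = 100 * J,
       newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Write a Jaccard matrix as TSV (values in percent)
#'
#' @param J Jaccard matrix in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeJaccardMatrix <- function(J, path) {
  out <- data.frame(profile = rownames(J), round(100 * J, 2),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
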