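test_that("decoy generation reverses sequences one to one", {
  db <- ProteinDatabase(c("P1", "P2"), c("PEPTIDEK", "AAAK"))
  dec <- generateDecoys(db)
  expect_equal(length(dec), 2L)
  expect_equal(unname(as.character(sequences(dec))[1]), "KEDITPEP")
  expect_equal(accession(dec), c("DECOY_P1", "DECOY_P2"))
  expect_true(all(category(dec) == "decoy"))

  pal <- ProteinDatabase("P3", "AKA")
  expect_message(generateDecoys(pal), "palindromic")
})

test_that("PSM FDR filter reproduces the decoy-counting example", {
  psms <- data.frame(score = c(rep(10, 200), rep(10, 2), rep(1, 50)),
                     decoy = c(rep(FALSE, 200), rep(TRUE, 2), rep(TRUE, 50)))
  out <- psmFdrFilter(psms, q = 0.01)
  expect_equal(out$result$n_target, 200L)
  expect_equal(out$result$n_decoy, 2L)
  expect_equal(out$result$fdr_estimate, 0.01)
  expect_equal(nrow(out$kept), 200L)
})

test_that("PSM FDR filter handles degenerate inputs", {
  # all decoys below all targets: everything kept
  psms <- data.frame(score = c(5, 6, 7, 1, 2), decoy = c(F, F, F, T, T))
  out <- psmFdrFilter(psms, 0.01)
  expect_equal(out$result$n_target, 3L)
  # all decoys: nothing kept
  out2 <- psmFdrFilter(data.frame(score = 1:5, decoy = TRUE), 0.01)
  expect_equal(nrow(out2$kept), 0L)
  expect_equal(out2$result$score_threshold, Inf)
  # empty input
  out3 <- psmFdrFilter(data.frame(score = numeric(), decoy = logical()))
  expect_equal(out3$result$score_threshold, Inf)
})

test_that("PSM FDR threshold matches the exhaustive scan oracle", {
  set.seed(13)
  for (i in 1:15) {
    n <- 300
    scores <- c(rgamma(n, 4, 0.5) + 15, rgamma(n / 2, 4, 0.5))
    decoy <- c(rep(FALSE, n), rep(TRUE, n / 2))
    q <- sample(c(0.01, 0.05, 0.2), 1)
    got <- psmFdrFilter(data.frame(score = scores, decoy = decoy), q)
    want <- oracleFdrThreshold(scores, decoy, q)
    expect_equal(got$result$n_target, want$n_target)
    expect_equal(got$result$score_threshold, want$threshold)
  }
})

# small helper: uniqueness map from explicit peptide -> proteins pairs
fakeMap <- function(...) {
  prots <- list(...)
  data.frame(peptide = names(prots), n_proteins = lengths(prots),
             is_unique = lengths(prots) == 1L, proteins = I(unname(prots)),
             stringsAsFactors = FALSE)
}

test_that("shared peptides go to the highest-ranking protein", {
  psms <- data.frame(peptide = c("AAAAA", "CCCCC", "DDDDD", "SHARE"),
                     score = c(30, 30, 30, 20), stringsAsFactors = FALSE)
  map <- fakeMap(AAAAA = "A", CCCCC = "A", DDDDD = "A", SHARE = c("A", "B"))
  ev <- inferProteins(psms, map)
  expect_equal(ev$accession, "A")       # B has nothing assigned
  expect_equal(ev$shared_peptides[[1]], "SHARE")
  expect_equal(ev$total_score, 110)
})

test_that("evidence ties break lexicographically by accession", {
  psms <- data.frame(peptide = c("AAAAA", "CCCCC", "SHARE"),
                     score = c(30, 30, 20), stringsAsFactors = FALSE)
  map <- fakeMap(AAAAA = "ZPROT", CCCCC = "BPROT", SHARE = c("ZPROT", "BPROT"))
  ev <- inferProteins(psms, map)
  expect_equal(ev$shared_peptides[[which(ev$accession == "BPROT")]], "SHARE")
  expect_equal(length(ev$shared_peptides[[which(ev$accession == "ZPROT")]]), 0L)
})

test_that("a single short unique peptide does not identify a protein", {
  psms <- data.frame(peptide = c("GGGK", "LLLLLK"), score = c(50, 50),
                     stringsAsFactors = FALSE)
  map <- fakeMap(GGGK = "SHORT", LLLLLK = "LONG")
  ev <- inferProteins(psms, map)
  expect_equal(ev$accession, "LONG")
})

test_that("a shared-only protein is reported only when a peptide is assigned", {
  # B shares both its peptides with higher-ranking A: nothing assigned to B
  psms <- data.frame(peptide = c("AAAAA", "SHRDA", "SHRDB"),
                     score = c(30, 10, 10), stringsAsFactors = FALSE)
  map <- fakeMap(AAAAA = "A", SHRDA = c("A", "B"), SHRDB = c("A", "B"))
  ev <- inferProteins(psms, map)
  expect_equal(ev$accession, "A")
  # without A's unique peptide, B and A tie at 0; both shared go to A (lex)
  psms2 <- psms[-1, ]
  ev2 <- inferProteins(psms2, map[-1, ])
  expect_equal(ev2$accession, "A")
})

test_that("orphan peptides are excluded with a warning", {
  psms <- data.frame(peptide = c("AAAAA", "ORPHN"), score = c(30, 99),
                     stringsAsFactors = FALSE)
  map <- fakeMap(AAAAA = "A", ORPHN = character())
  expect_warning(ev <- inferProteins(psms, map), "no protein")
  expect_equal(ev$accession, "A")
})

test_that("including shared peptides never loses identifications", {
  set.seed(17)
  for (rep in 1:10) {
    n_prot <- 6
    accs <- sprintf("P%d", 1:n_prot)
    n_pep <- 15
    peps <- sprintf("PEPTIDE%02d", 1:n_pep)
    prots <- lapply(seq_len(n_pep), function(i)
      sample(accs, sample(1:2, 1, prob = c(0.7, 0.3))))
    map <- data.frame(peptide = peps, n_proteins = lengths(prots),
                      is_unique = lengths(prots) == 1L,
                      proteins = I(prots), stringsAsFactors = FALSE)
    psms <- data.frame(peptide = peps, score = runif(n_pep, 10, 50),
                       stringsAsFactors = FALSE)
    full <- inferProteins(psms, map)
    uniq_only <- inferProteins(psms[map$is_unique, , drop = FALSE],
                               map[map$is_unique, , drop = FALSE])
    expect_gte(nrow(full), nrow(uniq_only))
    # every kept shared peptide appears in exactly one protein
    shared_all <- unlist(full$shared_peptides)
    expect_equal(anyDuplicated(shared_all), 0L)
  }
})

test_that("protein FDR truncation follows the cumulative-ratio oracle", {
  mk <- function(decoy_pattern) {
    n <- length(decoy_pattern)
    data.frame(accession = sprintf("P%03d", seq_len(n)), rank = seq_len(n),
               total_score = rev(seq_len(n)), n_unique_msms = 1L,
               n_shared_msms = 0L, is_decoy = decoy_pattern,
               stringsAsFactors = FALSE)
  }
  # one decoy amid 600 targets stays below 1%
  prot <- mk(c(rep(FALSE, 300), TRUE, rep(FALSE, 300)))
  kept <- proteinFdrFilter(prot, 0.01, 20L)
  expect_equal(nrow(kept), 600L)
  expect_false(any(kept$is_decoy))

  # a top-ranked decoy blocks every target until the cumulative ratio
  # recovers below q; with too few targets nothing is ever accepted
  prot2 <- mk(c(TRUE, rep(FALSE, 50)))
  expect_equal(nrow(proteinFdrFilter(prot2, 0.01, 20L)), 0L)
  prot3 <- mk(c(TRUE, rep(FALSE, 150)))   # 1/150 < 1%: ratio recovers
  expect_equal(nrow(proteinFdrFilter(prot3, 0.01, 20L)), 150L)
})

test_that("the reverse-count cap truncates at 20 decoys even when the ratio allows more", {
  pattern <- rep(c(FALSE, TRUE), 30)      # alternating targets and decoys
  prot <- data.frame(accession = sprintf("P%03d", 1:60), rank = 1:60,
                     total_score = 60:1, n_unique_msms = 1L,
                     n_shared_msms = 0L, is_decoy = pattern,
                     stringsAsFactors = FALSE)
  kept <- proteinFdrFilter(prot, q = 1, max_reverse_count = 20L)
  # prefix may extend to the last target before the 21st decoy
  expect_equal(nrow(kept), 21L)
})
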