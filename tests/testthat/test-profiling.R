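# evidence table builder matching inferProteins() output columns
fakeEvidence <- function(accession, unique = list(), shared = list(),
                         insilico = NULL) {
  n <- length(accession)
  pad <- function(x) if (length(x) < n) c(x, rep(list(character()),
                                                 n - length(x))) else x
  out <- data.frame(accession = accession, rank = seq_len(n),
                    total_score = rev(seq_len(n)) * 10,
                    n_unique_msms = lengths(pad(unique)),
                    n_shared_msms = lengths(pad(shared)),
                    is_decoy = FALSE, stringsAsFactors = FALSE)
  out$unique_peptides <- I(pad(unique))
  out$shared_peptides <- I(pad(shared))
  if (!is.null(insilico)) out$insilico_peptides <- I(pad(insilico))
  out
}

test_that("category filtering separates HCPs, keratins and non-HCPs", {
  db <- ProteinDatabase(
    c("HCP_1", "KER_1", "KER_2", "DS_1", "TRYP"),
    c("MMMAAAKCCCR", "GGGKWWWR", "HHHKYYYR", "VVVKLLLR", "TTTKEEER"),
    category = c("host", "keratin_contaminant", "host", "drug_substance",
                 "trypsin"),
    description = c("some protein", "", "Keratin, type II synthetic",
                    "drug substance", "trypsin"))
  ev <- fakeEvidence(c("HCP_1", "KER_1", "KER_2", "DS_1", "TRYP"),
                     unique = list("AAAK", "GGGK", "HHHK", "VVVK", "TTTK"))
  out <- filterCategories(ev, db)
  expect_equal(out$hcps$accession, "HCP_1")
  expect_setequal(out$keratins$accession, c("KER_1", "KER_2"))
  expect_setequal(out$non_hcps$accession, c("DS_1", "TRYP"))
})

test_that("peptides contained in non-HCP sequences never support HCPs", {
  db <- ProteinDatabase(
    c("HCP_1", "HCP_2", "DS_1"),
    c("MMMAAAKCCCR", "QQQWWWKEEER", "ZZAAAKZZWWWKZZ"),
    category = c("host", "host", "drug_substance"))
  # HCP_1 has one peptide shared with the DS by substring and one clean one;
  # HCP_2 is supported only by a DS-contained peptide
  ev <- fakeEvidence(c("HCP_1", "HCP_2"),
                     unique = list(c("AAAK", "CCCR"), "WWWK"))
  expect_message(out <- filterCategories(ev, db), "unspecific cleavage")
  expect_equal(out$hcps$accession, "HCP_1")
  expect_equal(out$hcps$unique_peptides[[1]], "CCCR")
  expect_equal(out$removed, "HCP_2")
})

test_that("the unspecific-cleavage rule keeps proteins with any clean peptide", {
  ds <- "XXAAAKXXCCCRXX"
  expect_false(unspecificCleavageFilter(c("AAAK", "CCCR"), ds))
  expect_true(unspecificCleavageFilter(c("AAAK", "GGGGK"), ds))
  # four of five peptides unique to the protein: kept
  expect_true(unspecificCleavageFilter(
    c("AAAK", "DDDDK", "EEEEK", "FFFFK", "GGGGK"), ds))
  expect_false(unspecificCleavageFilter(character(), ds))  # vacuous removal
})

test_that("credibility tiers reflect the best evidence class", {
  expect_equal(assignTiers(list(c("AAAAA", "CCCCC")), list(character()),
                           list(character())), 4L)
  expect_equal(assignTiers(list("AAAAA"), list("SHARED"), list("INSIL")), 3L)
  expect_equal(assignTiers(list(character()), list(c("SH1", "SH2")),
                           list(character())), 2L)
  expect_equal(assignTiers(list(character()), list(character()),
                           list("INSIL")), 1L)
  # the >= 5 residue rule: a 4-residue unique peptide does not count
  expect_equal(assignTiers(list("GGGK"), list("SHARED"), list(character())),
               2L)
  expect_true(is.na(assignTiers(list(character()), list(character()),
                                list(character()))))
})

test_that("profile aggregation takes unions with max-tier merge", {
  p1 <- HCPProfile("replicate",
                   c(drug_product = "DP1", fraction = "wash", replicate = "1"),
                   c(A = 4L, B = 1L))
  p2 <- HCPProfile("replicate",
                   c(drug_product = "DP1", fraction = "wash", replicate = "2"),
                   c(B = 3L, C = 2L))
  f <- aggregateProfiles(list(p1, p2), "fraction")
  expect_equal(members(f), c(A = 4L, B = 3L, C = 2L))
  expect_equal(profileLevel(f), "fraction")

  # idempotence for a single replicate
  f1 <- aggregateProfiles(list(p1), "fraction")
  expect_equal(members(f1), members(p1))

  # mixed parent keys are an error
  p3 <- HCPProfile("replicate",
                   c(drug_product = "DP2", fraction = "wash", replicate = "1"),
                   c(A = 1L))
  expect_error(aggregateProfiles(list(p1, p3), "fraction"), "mixed parent")

  dp <- aggregateProfiles(list(f, HCPProfile("fraction",
        c(drug_product = "DP1", fraction = "flow_through"), c(D = 1L))),
        "drug_product")
  expect_equal(members(dp), c(A = 4L, B = 3L, C = 2L, D = 1L))
})

test_that("tier filtering is nested across minimum levels", {
  p <- HCPProfile("replicate",
                  c(drug_product = "DP1", fraction = "wash", replicate = "1"),
                  setNames(rep(1:4, each = 3),
                           sprintf("P%02d", 1:12)))
  sizes <- vapply(1:4, function(L) length(filterByTier(p, L)), integer(1))
  expect_equal(sizes, c(12L, 9L, 6L, 3L))
  for (L in 1:3)
    expect_true(all(names(members(filterByTier(p, L + 1L))) %in%
                    names(members(filterByTier(p, L)))))
})

test_that("top-3 quantification averages, aggregates and scales per column", {
  meta <- data.frame(run_id = c("r1", "r2"), drug_product = "DP1",
                     fraction = "wash", replicate = 1:2,
                     stringsAsFactors = FALSE)
  areas <- rbind(
    data.frame(run_id = "r1", accession = "A",
               peptide = sprintf("P%d", 1:4), area = c(100, 50, 30, 10)),
    data.frame(run_id = "r1", accession = "B",
               peptide = sprintf("Q%d", 1:2), area = c(80, 20)),
    data.frame(run_id = "r2", accession = "A",
               peptide = sprintf("P%d", 1:4), area = c(100, 50, 30, 10)),
    data.frame(run_id = "r2", accession = "B",
               peptide = sprintf("Q%d", 1:2), area = c(80, 20)))
  cats <- c(A = "host", B = "host")
  tab <- quantifyTop3(areas, meta, cats)
  # top-3 mean of A is 60, of B ("up to three") is 50; cumulative HCPs 110
  expect_equal(tab["cumulative_HCPs", 1], 100)
  expect_equal(tab["A", 1], 60 / 110 * 100)
  expect_equal(tab["B", 1], 50 / 110 * 100)
  expect_true(all(apply(tab, 2, max, na.rm = TRUE) == 100))
})

test_that("the drug substance dominates column scaling when most abundant", {
  meta <- data.frame(run_id = "r1", drug_product = "DP1", fraction = "direct",
                     replicate = 1L, stringsAsFactors = FALSE)
  areas <- data.frame(run_id = "r1",
                      accession = c("DS", "H1", "H1"),
                      peptide = c("DPEP", "HPEP1", "HPEP2"),
                      area = c(1e6, 1e4, 5e3), stringsAsFactors = FALSE)
  tab <- quantifyTop3(areas, meta, c(DS = "drug_substance", H1 = "host"))
  expect_equal(tab["DS", 1], 100)
  expect_equal(tab["H1", 1], mean(c(1e4, 5e3)) / 1e6 * 100)
})
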