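test_that("FASTA round trip preserves accessions, sequences and categories", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 a host protein", "MKAAAR", ">DS1 the drug substance",
               "GGGKCCCR"), fa)
  db <- readProteinDatabase(fa, c(DS1 = "drug_substance"))
  expect_equal(length(db), 2L)
  expect_equal(accession(db), c("P1", "DS1"))
  expect_equal(unname(category(db)), c("host", "drug_substance"))
  expect_equal(unname(description(db))[1], "a host protein")

  out <- withr::local_tempfile(fileext = ".fasta")
  writeProteinDatabase(db, out)
  db2 <- readProteinDatabase(out, c(DS1 = "drug_substance"))
  expect_equal(as.data.frame(db2), as.data.frame(db))
})

test_that("FASTA reader handles empty files and rejects duplicates", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  file.create(fa)
  expect_equal(length(readProteinDatabase(fa)), 0L)

  writeLines(c(">P1", "MK", ">P1", "GR"), fa)
  expect_error(readProteinDatabase(fa), "duplicate accession")
})

test_that("protein database validity enforces canonical uppercase sequences", {
  expect_error(ProteinDatabase("P1", "MKX123"), "non-canonical")
  expect_error(ProteinDatabase(c("P1", "P1"), c("MK", "GR")), "duplicate")
  expect_error(ProteinDatabase("P1", ""), "empty sequence")
})

test_that("search database assembly is additive in entry count", {
  host <- ProteinDatabase(c("H1", "H2", "H3"), c("MKAAAR", "GGGK", "CCCR"))
  adds <- ProteinDatabase(c("DS1", "TRYP"), c("WWWK", "YYYR"),
                          category = c("drug_substance", "trypsin"))
  expect_equal(length(buildSearchDatabase(host, adds)), 5L)
  expect_equal(length(buildSearchDatabase(host, ProteinDatabase())), 3L)

  clash <- ProteinDatabase(c("DS1", "H3"), c("WWWK", "YYYR"),
                           category = "drug_substance")
  expect_error(buildSearchDatabase(host, clash), "collision.*H3")
  host_cat <- ProteinDatabase("X1", "MK", category = "host")
  expect_error(buildSearchDatabase(host, host_cat), "non-host")
})

test_that("PSM tables round trip and report malformed input precisely", {
  psms <- data.frame(run_id = "r1", peptide = c("AAAK", "CCCR", "GGGK"),
                     mods = c("", "1:57.021464:Carbamidomethyl", ""),
                     z = 2L, mz_obs = c(500.1, 600.2, 700.3),
                     rt_min = c(10, 20, 30), score = c(30, 40, 50),
                     decoy = FALSE, stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePsmTable(psms, path)
  back <- readPsmTable(path)
  expect_equal(back, psms)

  # missing column
  broken <- psms; broken$score <- NULL
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(broken, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPsmTable(p2), "score")

  # non-numeric numeric field names the row
  bad <- psms; bad$mz_obs <- as.character(bad$mz_obs); bad$mz_obs[2] <- "oops"
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPsmTable(p3), "mz_obs.*row 2")
})

test_that("feature tables validate envelopes and widths", {
  feats <- data.frame(run_id = "r1", mz = 500.1, z = 2L,
                      rt_center_min = 10.5, rt_width_min = 0.3, area = 1e5,
                      iso0 = 10, iso1 = 5, iso2 = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTable(feats, path)
  expect_equal(readFeatureTable(path), feats)
  expect_equal(unname(envelopeMatrix(feats)[1, ]), c(10, 5, 1))

  bad <- feats; bad$rt_width_min <- 0
  expect_error(writeFeatureTable(bad, path), "rt_width_min")
  bad2 <- feats; bad2[c("iso0", "iso1", "iso2")] <- 0
  expect_error(writeFeatureTable(bad2, path), "all zero")
})

test_that("run metadata enforces unique replicate combinations", {
  meta <- data.frame(run_id = c("a", "b"), drug_product = "DP1",
                     fraction = "wash", replicate = 1:2,
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRunMetadata(meta, path)
  expect_equal(readRunMetadata(path), meta)

  dup <- meta; dup$replicate <- 1L
  expect_error(writeRunMetadata(dup, path), "duplicate")
  odd <- meta; odd$fraction <- "elution"
  expect_error(writeRunMetadata(odd, path), "fraction")
})

test_that("profiles round trip through JSON", {
  p <- HCPProfile("fraction", c(drug_product = "DP1", fraction = "wash"),
                  c(HCP_001 = 4L, HCP_002 = 1L, HCP_003 = 2L))
  path <- withr::local_tempfile(fileext = ".json")
  writeProfile(p, path)
  back <- readProfile(path)
  expect_equal(profileLevel(back), "fraction")
  expect_equal(profileKey(back), profileKey(p))
  expect_equal(members(back), members(p))
})

test_that("config files round trip and reject unknown keys", {
  cfg <- hcpConfig(psm_fdr = 0.05, mass_dev_percentiles = c(5, 95),
                   linkage = "average")
  path <- withr::local_tempfile(fileext = ".txt")
  writeConfigFile(cfg, path)
  back <- readConfigFile(path)
  for (s in slotNames(cfg))
    expect_equal(slot(back, s), slot(cfg, s), info = s)
  writeLines("bogus_key = 3", path)
  expect_error(readConfigFile(path), "bogus_key")
})

test_that("pipeline config validity rejects bad parameters", {
  expect_error(hcpConfig(feature_center_tolerance = 0), "positive")
  expect_error(hcpConfig(mass_dev_percentiles = c(97.5, 2.5)), "ordered")
  expect_error(hcpConfig(ms1_corr_percentile = 0), "corr_percentile")
})

test_that("modification strings parse and sum correctly", {
  m <- parseMods("3:57.021464:Carbamidomethyl;7:15.994915:Oxidation")
  expect_equal(m$position, c(3L, 7L))
  expect_equal(sum(m$delta), 57.021464 + 15.994915)
  expect_equal(modsDelta(c("", "3:57.021464:Carbamidomethyl")),
               c(0, 57.021464))
  expect_error(parseMods("3:57.02"), "malformed")
})
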