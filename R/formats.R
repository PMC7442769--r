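#' @include AllClasses.R
NULL

## ---- FASTA ----------------------------------------------------------------

#' Read a protein database from FASTA
#'
#' Reads a FASTA file into a [ProteinDatabase-class]. The accession is the
#' first whitespace-delimited token of each header; the remainder becomes
#' the description. Accessions not listed in `category_map` default to
#' category `"host"`.
#'
#' @param path FASTA file path.
#' @param category_map Named character vector mapping accession to category
#'   (e.g. `c(DS1 = "drug_substance")`).
#' @return A [ProteinDatabase-class]; entry order follows the file.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 some host protein", "MKAAAR", ">DS1", "GGGKCCCR"), fa)
#' readProteinDatabase(fa, c(DS1 = "drug_substance"))
#' @export
readProteinDatabase <- function(path, category_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L)
    return(ProteinDatabase())
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stop("FASTA parse error in ", path,
                                            ": ", conditionMessage(e)))
  headers <- names(seqs)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in ", path, ": ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  cats <- rep("host", length(acc))
  if (!is.null(category_map)) {
    hit <- match(acc, names(category_map))
    cats[!is.na(hit)] <- unname(category_map[hit[!is.na(hit)]])
  }
  ProteinDatabase(acc, as.character(seqs), cats, desc)
}

#' Write a protein database to FASTA
#'
#' @param db A [ProteinDatabase-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeProteinDatabase <- function(db, path) {
  stopifnot(is(db, "ProteinDatabase"))
  desc <- description(db)
  hdr <- ifelse(nzchar(desc), paste(accession(db), desc), accession(db))
  out <- db@sequences
  names(out) <- hdr
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Assemble the search database
#'
#' Concatenates the host proteome with the annotated non-HCP additions
#' (drug substance, spiked standards, trypsin, protein A, Hi3 standard as a
#' single entry). The entry count is exactly the sum of both parts, e.g. a
#' 23,885-entry host proteome plus 6 additions gives 23,891 entries.
#'
#' @param host_db [ProteinDatabase-class] of host entries.
#' @param additions [ProteinDatabase-class] of non-host entries.
#' @return Combined [ProteinDatabase-class].
#' @examples
#' host <- ProteinDatabase(c("H1", "H2"), c("MKAAAR", "GGGK"))
#' adds <- ProteinDatabase("DS1", "CCCR", category = "drug_substance")
#' length(buildSearchDatabase(host, adds))
#' @export
buildSearchDatabase <- function(host_db, additions) {
  stopifnot(is(host_db, "ProteinDatabase"), is(additions, "ProteinDatabase"))
  if (any(category(additions) == "host"))
    stop("additions must carry non-host categories")
  clash <- intersect(accession(host_db), accession(additions))
  if (length(clash))
    stop("accession collision between host database and additions: ",
         paste(clash, collapse = ", "))
  ProteinDatabase(c(accession(host_db), accession(additions)),
                  c(as.character(sequences(host_db)),
                    as.character(sequences(additions))),
                  c(unname(category(host_db)), unname(category(additions))),
                  c(unname(description(host_db)),
                    unname(description(additions))))
}

## ---- modification strings -------------------------------------------------

#' Peptide modification strings
#'
#' Modifications are encoded as `"position:delta:label"` triplets joined by
#' semicolons, e.g. `"3:57.021464:Carbamidomethyl"`; the empty string means
#' unmodified. `parseMods` expands one string into a data.frame;
#' `modsDelta` returns the summed mass delta (Da) for a vector of strings.
#'
#' @param mods Character vector of modification strings.
#' @return `parseMods`: data.frame with columns position, delta, label.
#'   `modsDelta`: numeric vector of total mass deltas.
#' @examples
#' parseMods("3:57.021464:Carbamidomethyl;7:15.994915:Oxidation")
#' modsDelta(c("", "3:57.021464:Carbamidomethyl"))
#' @export
parseMods <- function(mods) {
  stopifnot(length(mods) == 1L)
  if (is.na(mods) || !nzchar(mods))
    return(data.frame(position = integer(), delta = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  parts <- strsplit(strsplit(mods, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed modification string: ", mods)
  data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
             delta = as.numeric(vapply(parts, `[`, "", 2L)),
             label = vapply(parts, `[`, "", 3L), stringsAsFactors = FALSE)
}

#' @rdname parseMods
#' @export
modsDelta <- function(mods) {
  vapply(mods, function(m) {
    if (is.na(m) || !nzchar(m)) return(0)
    sum(parseMods(m)$delta)
  }, numeric(1), USE.NAMES = FALSE)
}

## ---- tabular IO -----------------------------------------------------------

PSM_COLUMNS <- c("run_id", "peptide", "mods", "z", "mz_obs", "rt_min",
                 "score", "decoy")
FEATURE_COLUMNS <- c("run_id", "mz", "z", "rt_center_min", "rt_width_min",
                     "area")
META_COLUMNS <- c("run_id", "drug_product", "fraction", "replicate")

.readTsv <- function(path, mandatory, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at row %d of %s",
                   col, bad[1], path))
    df[[col]] <- v
  }
  df
}

#' Read and write PSM tables
#'
#' Tab-separated peptide-spectrum-match tables with columns `run_id`,
#' `peptide`, `mods`, `z` (charge), `mz_obs` (Th), `rt_min` (minutes),
#' `score`, `decoy` (0/1). Write-then-read reproduces the table.
#'
#' @param path File path.
#' @param psms data.frame of PSMs.
#' @return `readPsmTable`: data.frame of PSMs with typed columns.
#' @export
readPsmTable <- function(path) {
  df <- .readTsv(path, PSM_COLUMNS, c("z", "mz_obs", "rt_min", "score"))
  df$z <- as.integer(df$z)
  df$decoy <- as.logical(as.integer(df$decoy))
  df$mods[is.na(df$mods)] <- ""
  validatePsms(df)
  df[PSM_COLUMNS]
}

#' @rdname readPsmTable
#' @export
writePsmTable <- function(psms, path) {
  validatePsms(psms)
  out <- psms[PSM_COLUMNS]
  out$decoy <- as.integer(out$decoy)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validatePsms <- function(psms) {
  missing <- setdiff(PSM_COLUMNS, names(psms))
  if (length(missing))
    stop("PSM table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(psms)) {
    if (any(psms$rt_min <= 0)) stop("PSM retention times must be positive")
    if (any(psms$mz_obs <= 0)) stop("PSM observed m/z must be positive")
  }
  invisible(TRUE)
}

#' Read and write MS1 feature tables
#'
#' Tab-separated full-scan feature tables with columns `run_id`, `mz` (Th),
#' `z` (charge), `rt_center_min`, `rt_width_min` (FWHM, minutes), `area`,
#' and isotope-envelope intensity columns `iso0`, `iso1`, ... (monoisotopic
#' peak first).
#'
#' @param path File path.
#' @param features data.frame of features.
#' @return `readFeatureTable`: data.frame with typed columns.
#' @export
readFeatureTable <- function(path) {
  df <- .readTsv(path, FEATURE_COLUMNS, NULL)
  iso_cols <- grep("^iso[0-9]+$", names(df), value = TRUE)
  if (!length(iso_cols))
    stop("missing mandatory column(s) in ", path, ": iso0")
  iso_cols <- iso_cols[order(as.integer(sub("iso", "", iso_cols)))]
  for (col in c("mz", "rt_center_min", "rt_width_min", "area", iso_cols)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at row %d of %s",
                   col, bad[1], path))
    df[[col]] <- v
  }
  df$z <- as.integer(df$z)
  df <- df[c(FEATURE_COLUMNS, iso_cols)]
  validateFeatures(df)
  df
}

#' @rdname readFeatureTable
#' @export
writeFeatureTable <- function(features, path) {
  validateFeatures(features)
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validateFeatures <- function(features) {
  missing <- setdiff(FEATURE_COLUMNS, names(features))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  iso_cols <- grep("^iso[0-9]+$", names(features), value = TRUE)
  if (!length(iso_cols))
    stop("feature table lacks isotope-envelope columns iso0..isoK")
  if (nrow(features)) {
    if (any(features$rt_width_min <= 0))
      stop("feature rt_width_min must be strictly positive")
    if (any(features$area < 0)) stop("feature areas must be non-negative")
    env <- as.matrix(features[iso_cols])
    if (any(env < 0)) stop("isotope envelope intensities must be non-negative")
    if (any(rowSums(env) == 0))
      stop("isotope envelopes must not be all zero")
  }
  invisible(TRUE)
}

#' Extract the isotope-envelope matrix of a feature table
#'
#' @param features Feature data.frame from [readFeatureTable()].
#' @return Numeric matrix, one row per feature, columns iso0..isoK.
#' @export
envelopeMatrix <- function(features) {
  iso_cols <- grep("^iso[0-9]+$", names(features), value = TRUE)
  iso_cols <- iso_cols[order(as.integer(sub("iso", "", iso_cols)))]
  as.matrix(features[iso_cols])
}

#' Read and write run metadata
#'
#' Tab-separated run metadata with columns `run_id`, `drug_product`,
#' `fraction` (`direct`, `flow_through` or `wash`) and `replicate`
#' (positive integer). The combination (drug_product, fraction, replicate)
#' must be unique.
#'
#' @param path File path.
#' @param meta data.frame of run metadata.
#' @return `readRunMetadata`: validated data.frame.
#' @export
readRunMetadata <- function(path) {
  df <- .readTsv(path, META_COLUMNS, "replicate")
  df$replicate <- as.integer(df$replicate)
  validateRunMetadata(df)
  df[META_COLUMNS]
}

#' @rdname readRunMetadata
#' @export
writeRunMetadata <- function(meta, path) {
  validateRunMetadata(meta)
  write.table(meta[META_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

validateRunMetadata <- function(meta) {
  missing <- setdiff(META_COLUMNS, names(meta))
  if (length(missing))
    stop("run metadata lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(meta)) {
    bad <- setdiff(unique(meta$fraction), FRACTION_LEVELS)
    if (length(bad))
      stop("unknown fraction label(s): ", paste(bad, collapse = ", "))
    if (any(meta$replicate < 1L)) stop("replicate must be a positive integer")
    key <- paste(meta$drug_product, meta$fraction, meta$replicate)
    if (anyDuplicated(key))
      stop("duplicate (drug_product, fraction, replicate) combination")
    if (anyDuplicated(meta$run_id)) stop("duplicate run_id")
  }
  invisible(TRUE)
}

## ---- profile and config IO ------------------------------------------------

#' Read and write HCP profiles as JSON
#'
#' Profiles are serialized as
#' `{"level": ..., "key": {...}, "members": [{"accession": ..., "tier": ...}]}`.
#'
#' @param profile An [HCPProfile-class].
#' @param path File path.
#' @return `readProfile`: an [HCPProfile-class].
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "HCPProfile"))
  obj <- list(level = profile@level, key = as.list(profile@key),
              members = data.frame(accession = names(profile@members),
                                   tier = unname(profile@members)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  members <- integer()
  if (length(obj$members) && NROW(obj$members) > 0)
    members <- setNames(as.integer(obj$members$tier), obj$members$accession)
  HCPProfile(obj$level, unlist(obj$key), members)
}

#' Read and write pipeline configuration files
#'
#' Flat `key = value` text files mirroring the [PipelineConfig-class] field
#' names; `mass_dev_percentiles` is a comma-separated pair.
#'
#' @param path File path.
#' @param config A [PipelineConfig-class].
#' @return `readConfigFile`: a [PipelineConfig-class].
#' @export
writeConfigFile <- function(config, path) {
  stopifnot(is(config, "PipelineConfig"))
  lines <- vapply(slotNames(config), function(s)
    sprintf("%s = %s", s, paste(slot(config, s), collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeConfigFile
#' @export
readConfigFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed config line in ", path)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  args <- list()
  for (i in seq_along(keys)) {
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    args[[keys[i]]] <- if (keys[i] == "linkage") v else as.numeric(v)
  }
  unknown <- setdiff(names(args), names(formals(hcpConfig)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(hcpConfig, args)
}
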