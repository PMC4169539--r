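# Genotype container and text-format I/O.  Dosages count the alternate
# allele (0/1/2) with NA_integer_ as the missing code; populations are a
# per-sample label vector, never inferred from file side effects.

#' Construct a genotype dataset
#'
#' The central container of the package: an integer dosage matrix (samples
#' in rows, SNPs in columns, entries 0/1/2 counting the alternate allele,
#' `NA` for missing genotypes) together with a SNP map and per-sample
#' population labels.
#'
#' @param dosages integer matrix, `n_samples x n_snps`, entries in
#'   `{0, 1, 2, NA}`.
#' @param sample_ids character vector of unique sample identifiers.
#' @param populations character vector of per-sample population labels
#'   (`"."` is reserved and rejected); may contain `NA` for unlabelled
#'   samples.
#' @param snps data.frame with columns `snp_id`, `chromosome`,
#'   `position_bp` (1-based, >= 1), `allele_ref`, `allele_alt`.
#' @return An object of class `geno_dataset`.
#' @seealso [read_genotypes()], [simulate_dataset()]
#' @export
geno_dataset <- function(dosages, sample_ids, populations, snps) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  ds <- structure(
    list(dosages = dosages,
         sample_ids = as.character(sample_ids),
         populations = as.character(populations),
         snps = as.data.frame(snps, stringsAsFactors = FALSE)),
    class = "geno_dataset")
  rownames(ds$dosages) <- ds$sample_ids
  colnames(ds$dosages) <- ds$snps$snp_id
  validate_geno_dataset(ds)
  ds
}

#' Validate a genotype dataset's invariants
#'
#' Checks dimensions, identifier uniqueness, dosage domain and the SNP map.
#' Called by every constructor; exported because readers of foreign files
#' may want to re-check after manual edits.
#'
#' @param ds a [geno_dataset()].
#' @return `ds`, invisibly; errors describe the first violated invariant.
#' @export
validate_geno_dataset <- function(ds) {
  stopifnot(inherits(ds, "geno_dataset"))
  n <- length(ds$sample_ids)
  m <- nrow(ds$snps)
  if (nrow(ds$dosages) != n)
    stop("dosage rows (", nrow(ds$dosages), ") != number of sample ids (", n, ")")
  if (ncol(ds$dosages) != m)
    stop("dosage columns (", ncol(ds$dosages), ") != number of SNPs (", m, ")")
  if (anyDuplicated(ds$sample_ids))
    stop("duplicate sample ids")
  if (anyDuplicated(ds$snps$snp_id))
    stop("duplicate SNP ids")
  if (length(ds$populations) != n)
    stop("populations must have one entry per sample")
  if (any(ds$populations == ".", na.rm = TRUE))
    stop("'.' is not allowed as a population name")
  bad <- !(ds$dosages %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA; found ",
         paste(unique(ds$dosages[bad]), collapse = ", "))
  req <- c("snp_id", "chromosome", "position_bp", "allele_ref", "allele_alt")
  miss <- setdiff(req, names(ds$snps))
  if (length(miss)) stop("SNP map lacks columns: ", paste(miss, collapse = ", "))
  if (m > 0) {
    if (any(ds$snps$position_bp < 1))
      stop("position_bp must be >= 1")
    if (any(ds$snps$allele_ref == ds$snps$allele_alt))
      stop("allele_ref must differ from allele_alt")
  }
  invisible(ds)
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat("<geno_dataset> ", length(x$sample_ids), " samples x ",
      nrow(x$snps), " SNPs\n", sep = "")
  pops <- table(x$populations, useNA = "ifany")
  cat("populations: ",
      paste(names(pops), " (", as.integer(pops), ")",
            sep = "", collapse = ", "), "\n", sep = "")
  nm <- sum(is.na(x$dosages))
  cat(sprintf("missing dosages: %d (%.2f%%)\n",
              nm, 100 * nm / max(1, length(x$dosages))))
  invisible(x)
}

#' Subset a genotype dataset by samples and/or SNPs
#'
#' @param ds a [geno_dataset()].
#' @param samples index vector (logical, integer or sample ids) of samples
#'   to keep; `NULL` keeps all.
#' @param snps index vector (logical, integer or snp ids) of SNPs to keep;
#'   `NULL` keeps all.
#' @return A `geno_dataset` restricted to the selection.
#' @export
subset_genotypes <- function(ds, samples = NULL, snps = NULL) {
  stopifnot(inherits(ds, "geno_dataset"))
  si <- seq_along(ds$sample_ids)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, ds$sample_ids) else si[samples]
    if (anyNA(si)) stop("unknown sample ids in subset")
  }
  mi <- seq_len(nrow(ds$snps))
  if (!is.null(snps)) {
    mi <- if (is.character(snps)) match(snps, ds$snps$snp_id) else mi[snps]
    if (anyNA(mi)) stop("unknown SNP ids in subset")
  }
  geno_dataset(ds$dosages[si, mi, drop = FALSE],
               ds$sample_ids[si], ds$populations[si],
               ds$snps[mi, , drop = FALSE])
}

#' Read a genotype dataset
#'
#' Reads either a PLINK1 binary triple (`<path>.bed/.bim/.fam`, SNP-major
#' only) or the package's TSV triple (`<path>.tsv` genotype matrix with
#' samples in rows and SNP ids in the header, `<path>.snps.tsv` SNP map,
#' and an optional panel file).  In both formats the dosage counts the
#' alternate allele; for PLINK1 the .bim allele-1 (A1) is the counted
#' allele, so A1 is stored as `allele_alt` and A2 as `allele_ref`.
#' Population labels come from a sidecar panel TSV
#' (`<path>.panel.tsv`, columns `sample_id`, `population`) when present;
#' for PLINK1, `fid_as_population = TRUE` falls back to the .fam FID
#' column instead.
#'
#' @param path file prefix (no extension).
#' @param format `"plink1"` or `"tsv"`.
#' @param fid_as_population use the .fam FID column as the population label
#'   when no panel file exists (PLINK1 only).
#' @return A [geno_dataset()].
#' @export
read_genotypes <- function(path, format = c("plink1", "tsv"),
                           fid_as_population = FALSE) {
  format <- match.arg(format)
  panel_path <- paste0(path, ".panel.tsv")
  if (format == "plink1") {
    ds <- read_plink1(path, fid_as_population = fid_as_population)
  } else {
    gf <- paste0(path, ".tsv"); sf <- paste0(path, ".snps.tsv")
    for (f in c(gf, sf)) if (!file.exists(f)) stop("file not found: ", f)
    g <- read.table(gf, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
    snps <- read.table(sf, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE,
                       colClasses = c(snp_id = "character",
                                      chromosome = "character",
                                      allele_ref = "character",
                                      allele_alt = "character"))
    sample_ids <- g[[1L]]
    dm <- as.matrix(g[, -1L, drop = FALSE])
    dosages <- matrix(suppressWarnings(as.integer(dm)), nrow = nrow(dm),
                      dimnames = dimnames(dm))
    if (nrow(snps) != ncol(dosages) ||
        !identical(colnames(dosages), snps$snp_id))
      stop("SNP map does not match genotype matrix header")
    ds <- geno_dataset(dosages, sample_ids,
                       rep(NA_character_, length(sample_ids)), snps)
  }
  if (file.exists(panel_path)) {
    panel <- read_sample_panel(panel_path)
    idx <- match(ds$sample_ids, panel$sample_id)
    if (anyNA(idx)) stop("panel file lacks entries for some samples")
    ds$populations <- panel$population[idx]
    validate_geno_dataset(ds)
  }
  ds
}

#' Write a genotype dataset
#'
#' Inverse of [read_genotypes()]; `read_genotypes(write_genotypes(ds))`
#' round-trips dosages (including missing cells), sample ids, the SNP map
#' and population labels bit-exactly.  Labels are written to a sidecar
#' panel TSV; they are never encoded in the .fam FID column.
#'
#' @param ds a [geno_dataset()].
#' @param path file prefix (no extension); parent directory must exist.
#' @param format `"plink1"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(ds, path, format = c("plink1", "tsv")) {
  format <- match.arg(format)
  validate_geno_dataset(ds)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory not writable: ", dir)
  if (format == "plink1") {
    write_plink1(ds, path)
  } else {
    g <- data.frame(sample_id = ds$sample_ids, check.names = FALSE,
                    stringsAsFactors = FALSE)
    g <- cbind(g, as.data.frame(ds$dosages, check.names = FALSE))
    write.table(g, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    write.table(ds$snps, paste0(path, ".snps.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  if (!all(is.na(ds$populations))) {
    write.table(data.frame(sample_id = ds$sample_ids,
                           population = ds$populations),
                paste0(path, ".panel.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a sample-to-population panel
#'
#' @param path TSV file with header columns `sample_id`, `population`.
#' @return data.frame with those two character columns.
#' @export
read_sample_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  p <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!all(c("sample_id", "population") %in% names(p)))
    stop("panel must have columns sample_id, population")
  if (anyDuplicated(p$sample_id)) stop("duplicate sample_id in panel")
  if (any(p$population == ".")) stop("'.' is not allowed as a population name")
  p[, c("sample_id", "population")]
}

#' Read a population geographic-centre panel
#'
#' One row per population with the latitude/longitude (decimal degrees) of
#' the population's geographic centre, e.g. the midpoint of the country the
#' samples were drawn from.
#'
#' @param path TSV file with header columns `population`, `latitude`,
#'   `longitude`.
#' @return data.frame of class `geo_panel` with columns `population`,
#'   `latitude`, `longitude`.
#' @export
read_geo_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  geo_panel(g$population, g$latitude, g$longitude)
}

#' Construct and validate a geographic panel
#'
#' @param population character vector of unique population names.
#' @param latitude latitudes in degrees, within `[-90, 90]`.
#' @param longitude longitudes in degrees, within `[-180, 180]`.
#' @return data.frame of class `geo_panel`.
#' @export
geo_panel <- function(population, latitude, longitude) {
  if (is.null(population) || is.null(latitude) || is.null(longitude))
    stop("geo panel needs population, latitude, longitude")
  g <- data.frame(population = as.character(population),
                  latitude = as.numeric(latitude),
                  longitude = as.numeric(longitude),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(g$population))
    stop("duplicate population in geo panel")
  if (any(is.na(g$latitude)) || any(abs(g$latitude) > 90))
    stop("latitude outside [-90, 90]")
  if (any(is.na(g$longitude)) || any(abs(g$longitude) > 180))
    stop("longitude outside [-180, 180]")
  if (any(g$population == ".")) stop("'.' is not allowed as a population name")
  class(g) <- c("geo_panel", "data.frame")
  g
}

#' Write a geographic panel to TSV
#'
#' @param geo a [geo_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geo_panel <- function(geo, path) {
  write.table(as.data.frame(geo), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Combine two genotype datasets sample-wise
#'
#' Row-binds two datasets over an identical SNP map (same ids, same
#' order), e.g. to pool a reference and a test split for frequency or
#' Fst computations.
#'
#' @param a,b [geno_dataset()]s with identical SNP maps.
#' @return A `geno_dataset` holding the samples of both.
#' @export
bind_genotypes <- function(a, b) {
  stopifnot(inherits(a, "geno_dataset"), inherits(b, "geno_dataset"))
  if (!identical(a$snps$snp_id, b$snps$snp_id))
    stop("datasets must share an identical SNP map")
  geno_dataset(rbind(a$dosages, b$dosages),
               c(a$sample_ids, b$sample_ids),
               c(a$populations, b$populations), a$snps)
}
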