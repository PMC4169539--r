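# PLINK1 binary (.bed/.bim/.fam) codec, SNP-major dialect only.
#
# On-disk encoding: three magic bytes 0x6C 0x1B 0x01, then ceil(n/4) bytes
# per SNP.  Each sample occupies two bits, least-significant pair first:
#   0 = homozygous A1, 1 = missing, 2 = heterozygous, 3 = homozygous A2.
# A1 (.bim column 5) is the counted allele, so dosage = 2, NA, 1, 0
# respectively, and A1/A2 map to allele_alt/allele_ref.

PLINK_MAGIC <- as.raw(c(0x6C, 0x1B, 0x01))
# two-bit code -> dosage of A1
.plink_code_to_dosage <- c(2L, NA_integer_, 1L, 0L)

read_plink1 <- function(prefix, fid_as_population = FALSE) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("file not found: ", f)

  read6 <- function(path, classes) {
    if (file.size(path) == 0)
      return(as.data.frame(lapply(classes, function(cl)
        vector(if (is.na(cl)) "integer" else cl, 0L))))
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = classes)
  }
  fam_df <- read6(fam, c("character", "character", rep(NA, 4)))
  bim_df <- read6(bim, c("character", "character", NA, NA,
                         "character", "character"))
  n <- nrow(fam_df)
  m <- nrow(bim_df)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:2], PLINK_MAGIC[1:2]))
    stop("not a PLINK1 .bed file (bad magic bytes)")
  if (raw[3L] != PLINK_MAGIC[3L])
    stop("individual-major .bed files are not supported ",
         "(third magic byte must be 0x01)")
  bps <- ceiling(n / 4)                      # bytes per SNP
  payload <- raw[-(1:3)]
  if (length(payload) != bps * m)
    stop(".bed payload has ", length(payload), " bytes; expected ",
         bps * m, " for ", n, " samples x ", m, " SNPs")

  ints <- matrix(as.integer(payload), nrow = bps, ncol = m)
  dos <- matrix(NA_integer_, n, m)
  for (k in 0:3) {                           # k-th sample within each byte
    if (k + 1L > n) next
    rows <- seq.int(k + 1L, n, by = 4L)
    byte_rows <- seq_along(rows)
    codes <- bitwAnd(bitwShiftR(ints[byte_rows, , drop = FALSE], 2L * k), 3L)
    dos[rows, ] <- .plink_code_to_dosage[codes + 1L]
  }

  snps <- data.frame(snp_id = bim_df[[2]], chromosome = bim_df[[1]],
                     position_bp = as.integer(bim_df[[4]]),
                     allele_alt = bim_df[[5]],   # A1, the counted allele
                     allele_ref = bim_df[[6]],
                     stringsAsFactors = FALSE)
  pops <- if (fid_as_population) fam_df[[1]] else rep(NA_character_, n)
  geno_dataset(dos, fam_df[[2]], pops,
               snps[, c("snp_id", "chromosome", "position_bp",
                        "allele_ref", "allele_alt")])
}

write_plink1 <- function(ds, prefix) {
  n <- length(ds$sample_ids)
  m <- nrow(ds$snps)
  fam <- data.frame(ds$sample_ids, ds$sample_ids, rep(0L, n), rep(0L, n),
                    rep(0L, n), rep(-9L, n))
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(ds$snps$chromosome, ds$snps$snp_id, rep(0L, m),
                    ds$snps$position_bp, ds$snps$allele_alt,
                    ds$snps$allele_ref)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  bps <- ceiling(n / 4)
  # dosage -> two-bit code (0/1/2/NA -> 3/2/0/1)
  code <- matrix(1L, n, m)
  ok <- !is.na(ds$dosages)
  code[ok] <- c(3L, 2L, 0L)[ds$dosages[ok] + 1L]
  bytes <- matrix(0L, bps, m)
  for (k in 0:3) {
    if (k + 1L > n) next
    rows <- seq.int(k + 1L, n, by = 4L)
    byte_rows <- seq_along(rows)
    bytes[byte_rows, ] <- bytes[byte_rows, , drop = FALSE] +
      bitwShiftL(code[rows, , drop = FALSE], 2L * k)
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
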