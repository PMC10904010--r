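# Genotype input/output: PLINK 1 binary (.bed/.bim/.fam) and a single-file
# TSV dosage dialect (#CHROM POS ID A1 A2 <IID...>), both round-tripping
# hard calls bit-exactly.

# PLINK 1 .bed 2-bit codes (SNP-major): 00 = hom A1 (dosage 2), 01 = missing,
# 10 = het, 11 = hom A2 (dosage 0).
.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))
.code_of_dosage <- c(`0` = 3L, `1` = 2L, `2` = 0L)  # NA -> 1L
.dosage_of_code <- c(2, NA, 1, 0)                   # index by code + 1

#' Read genotypes
#'
#' @param path for `plink-bed`, the path prefix (without extension) of a
#'   `.bed`/`.bim`/`.fam` trio; for `tsv-dosage`, a TSV file whose header is
#'   `#CHROM POS ID A1 A2` followed by one column per sample.
#' @param dialect `"plink-bed"` or `"tsv-dosage"`.
#' @return An [sv_genotypes] object. `A1` is the counted allele.
#' @export
read_genotypes <- function(path, dialect = c("plink-bed", "tsv-dosage")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         "plink-bed" = read_plink(path),
         "tsv-dosage" = read_tsv_dosage(path))
}

#' Write genotypes
#'
#' @param gm an [sv_genotypes] object.
#' @inheritParams read_genotypes
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, dialect = c("plink-bed", "tsv-dosage")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         "plink-bed" = write_plink(gm, path),
         "tsv-dosage" = write_tsv_dosage(gm, path))
  invisible(path)
}

read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stopf("missing file: %s", f)

  bimtab <- utils::read.table(bim, header = FALSE, colClasses = "character",
                              col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  if (anyDuplicated(bimtab$id))
    stopf("%s: duplicated SNP id(s): %s", bim,
          paste(unique(bimtab$id[duplicated(bimtab$id)]), collapse = ", "))
  famtab <- utils::read.table(fam, header = FALSE, colClasses = "character")
  samples <- famtab[[2]]
  n <- length(samples)
  m <- nrow(bimtab)

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:2], .bed_magic[1:2]))
    stopf("%s: bad magic bytes at offset 0 (not a PLINK v1 .bed file)", bed)
  if (raw[3] != .bed_magic[3])
    stopf("%s: unsupported mode byte at offset 2 (need SNP-major 0x01)", bed)
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) - 3L != bps * m)
    stopf("%s: expected %d data bytes for %d samples x %d SNPs, found %d",
          bed, bps * m, n, m, length(raw) - 3L)

  bytes <- as.integer(raw[-(1:3)])
  # expand each byte into its 4 two-bit codes (sample order = low bits first)
  codes <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                 (bytes %/% 16L) %% 4L, bytes %/% 64L)
  dim(codes) <- c(4L * bps, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(.dosage_of_code[codes + 1L], nrow = n, ncol = m)

  snps <- data.frame(id = bimtab$id, chrom = bimtab$chrom,
                     pos = as.integer(bimtab$pos),
                     a1 = bimtab$a1, a2 = bimtab$a2,
                     stringsAsFactors = FALSE)
  sv_genotypes(dos, snps, samples)
}

write_plink <- function(gm, prefix) {
  n <- length(gm$samples)
  m <- nrow(gm$snps)
  bim <- data.frame(gm$snps$chrom, gm$snps$id, 0L, gm$snps$pos,
                    gm$snps$a1, gm$snps$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(gm$samples, gm$samples, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)

  codes <- matrix(1L, nrow = 4L * ceiling(n / 4), ncol = m)
  d <- gm$dosages
  cd <- matrix(1L, nrow = n, ncol = m)
  ok <- !is.na(d)
  cd[ok] <- .code_of_dosage[as.character(d[ok])]
  codes[seq_len(n), ] <- cd
  dim(codes) <- c(4L, length(codes) / 4L)
  bytes <- codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] + 64L * codes[4, ]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

read_tsv_dosage <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  need <- c("#CHROM", "POS", "ID", "A1", "A2")
  if (length(header) < 6 || !identical(header[1:5], need))
    stopf("%s: header must start with '%s'", path, paste(need, collapse = " "))
  tab <- utils::read.table(path, header = FALSE, sep = "\t", skip = 1L,
                           colClasses = "character", na.strings = "NA")
  if (ncol(tab) != length(header))
    stopf("%s: rows have %d fields, header has %d", path, ncol(tab), length(header))
  samples <- header[-(1:5)]
  vals <- as.matrix(tab[, -(1:5), drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!(is.na(vals)) & (is.na(num) | !(num %in% c(0, 1, 2))), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("%s: invalid dosage '%s' at SNP row %d (id %s), sample column %s",
          path, vals[bad[1, 1], bad[1, 2]], bad[1, 1], tab[bad[1, 1], 3],
          samples[bad[1, 2]])
  snps <- data.frame(id = tab[[3]], chrom = tab[[1]], pos = as.integer(tab[[2]]),
                     a1 = tab[[4]], a2 = tab[[5]], stringsAsFactors = FALSE)
  sv_genotypes(t(num), snps, samples)
}

write_tsv_dosage <- function(gm, path) {
  header <- c("#CHROM", "POS", "ID", "A1", "A2", gm$samples)
  body <- cbind(gm$snps$chrom, gm$snps$pos, gm$snps$id, gm$snps$a1, gm$snps$a2,
                t(gm$dosages))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  utils::write.table(body, con, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a cohort to disk
#'
#' Emits PLINK `.bed`/`.bim`/`.fam` plus `covariates.tsv` / `phenotypes.tsv`
#' (sample id column `IID`) under `dir`.
#'
#' @param cohort an [sv_cohort].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(cohort$genotypes, file.path(dir, cohort$label))
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  utils::write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(dir)
}
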