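#' Read a PLINK fileset
#'
#' Reads either a binary fileset (`prefix.bed` / `.bim` / `.fam`, SNP-major)
#' or a text fileset (`prefix.ped` / `.map`).  Dosages count copies of the
#' second .bim allele (the "alt" allele of the returned dataset); for text
#' filesets, which carry no allele columns, the two observed alleles are
#' assigned ref/alt alphabetically.  Population labels are taken from the
#' family-ID column unless overridden.
#'
#' @param prefix filesystem prefix of the fileset (no extension).
#' @param population optional single label applied to every sample, replacing
#'   the family-ID column.
#' @return a [genotype_dataset()] with `phased = FALSE`.
#' @export
read_plink <- function(prefix, population = NULL) {
  if (file.exists(paste0(prefix, ".bed"))) {
    ds <- read_plink_binary(prefix)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    ds <- read_plink_text(prefix)
  } else {
    stop("no PLINK fileset found at prefix '", prefix,
         "' (need .bed/.bim/.fam or .ped/.map)")
  }
  if (!is.null(population)) ds$samples$population <- as.character(population)
  ds
}

.require_file <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  path
}

read_fam <- function(path) {
  fam <- utils::read.table(.require_file(path), header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 2) stop("format error in ", path, ": expected >= 2 columns")
  data.frame(id = fam[[2]], population = fam[[1]],
             stringsAsFactors = FALSE)
}

read_bim <- function(path) {
  bim <- utils::read.table(.require_file(path), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos_bp",
                                         "a1", "a2"))
  data.frame(id = as.character(bim$id), chrom = as.character(bim$chrom),
             pos_bp = as.integer(bim$pos_bp),
             ref = as.character(bim$a1), alt = as.character(bim$a2),
             stringsAsFactors = FALSE)
}

read_map <- function(path) {
  map <- utils::read.table(.require_file(path), header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(map) < 4) stop("format error in ", path, ": expected 4 columns")
  data.frame(id = as.character(map[[2]]), chrom = as.character(map[[1]]),
             pos_bp = as.integer(map[[4]]), stringsAsFactors = FALSE)
}

# 2-bit PLINK genotype codes, LSB-first within each byte:
# 00 = hom first (.bim A1) allele, 01 = missing, 10 = het, 11 = hom second.
# Dosage counts the second allele, so codes map to 0, NA, 1, 2.
.bed_decode_table <- local({
  tab <- matrix(NA_integer_, nrow = 256, ncol = 4)
  codes <- c(0L, NA_integer_, 1L, 2L)
  for (b in 0:255)
    for (k in 0:3)
      tab[b + 1L, k + 1L] <- codes[bitwAnd(bitwShiftR(b, 2L * k), 3L) + 1L]
  tab
})

read_plink_binary <- function(prefix) {
  bed_path <- .require_file(paste0(prefix, ".bed"))
  variants <- read_bim(paste0(prefix, ".bim"))
  samples <- read_fam(paste0(prefix, ".fam"))
  n <- nrow(samples)
  L <- nrow(variants)

  raw <- readBin(bed_path, what = "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("format error in ", bed_path, ": bad magic number")
  if (raw[3] != as.raw(0x01))
    stop("format error in ", bed_path, ": not SNP-major")
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) - 3L != bps * L)
    stop("format error: ", bed_path, " holds ",
         floor((length(raw) - 3L) / max(bps, 1L)),
         " SNP records for a .fam of ", n, " samples and a .bim of ",
         L, " SNPs (sample/SNP count mismatch)")
  body <- as.integer(raw[-(1:3)]) + 1L
  geno <- .bed_decode_table[body, , drop = FALSE]   # (bps * L) bytes x 4 slots
  # unroll slots byte by byte, then fold into (4 * bps) slots x L SNPs;
  # the first n slots of each SNP are its samples, in .fam order
  geno <- matrix(t(geno), nrow = 4L * bps)
  calls <- geno[seq_len(n), , drop = FALSE]         # samples x SNPs
  genotype_dataset(calls, variants, samples, phased = FALSE)
}

read_plink_text <- function(prefix) {
  ped_path <- .require_file(paste0(prefix, ".ped"))
  variants0 <- read_map(paste0(prefix, ".map"))
  ped <- utils::read.table(ped_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  L <- nrow(variants0)
  if (ncol(ped) != 6 + 2L * L)
    stop("format error in ", ped_path, ": expected ", 6 + 2L * L,
         " columns for ", L, " map entries, found ", ncol(ped))
  samples <- data.frame(id = ped[[2]], population = ped[[1]],
                        stringsAsFactors = FALSE)
  n <- nrow(ped)
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(L) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(L), drop = FALSE])
  ref <- character(L); alt <- character(L)
  calls <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    al <- sort(setdiff(unique(c(a1[, j], a2[, j])), "0"))
    if (length(al) > 2)
      stop("format error in ", ped_path, ": marker ", variants0$id[j],
           " has more than two alleles")
    ref[j] <- if (length(al) >= 1) al[1] else "A"
    alt[j] <- if (length(al) == 2) al[2] else
      setdiff(c("A", "C", "G", "T"), ref[j])[1]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    d <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    d[miss] <- NA_integer_
    calls[, j] <- as.integer(d)
  }
  variants <- data.frame(id = variants0$id, chrom = variants0$chrom,
                         pos_bp = variants0$pos_bp, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  genotype_dataset(calls, variants, samples, phased = FALSE)
}

#' Read genotypes from a VCF file
#'
#' Retains biallelic SNP records only (single-base REF and ALT); multi-allelic
#' and non-SNP records are dropped with a message.  Dosages count ALT copies.
#' The dataset is flagged phased only when every retained genotype uses the
#' phased `|` separator, in which case haplotypes are carried through.
#'
#' @param path VCF file (plain or gzipped, un-indexed).
#' @param population label applied to all samples; defaults to the file name
#'   without extension.
#' @return a [genotype_dataset()].
#' @export
read_vcf <- function(path, population = NULL) {
  .require_file(path)
  if (is.null(population)) {
    population <- tools::file_path_sans_ext(basename(path))
    population <- sub("\\.vcf$", "", population)
  }
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("format error in VCF ", path, ": ",
                         conditionMessage(e)))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) stop("format error: ", path,
                                           " contains no variant records")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("read_vcf: dropped ", n_drop,
            " multi-allelic or non-SNP record(s)")
  if (!any(keep)) stop("no biallelic SNP records in ", path)

  gt <- vcfR::extract.gt(vcf, element = "GT")       # variants x samples
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  gt[is.na(gt)] <- "./."
  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  miss <- a1 == "." | a2 == "." | a2 == ""
  phased <- all(sep[!miss] == "|") && any(!miss)
  d <- (a1 == "1") + (a2 == "1")
  d[miss] <- NA_integer_
  calls <- t(matrix(as.integer(d), nrow = nrow(gt)))  # samples x variants

  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  variants <- data.frame(id = ids, chrom = fix[, "CHROM"],
                         pos_bp = as.integer(fix[, "POS"]),
                         ref = ref[keep], alt = alt[keep],
                         stringsAsFactors = FALSE)
  samples <- data.frame(id = colnames(gt), population = population,
                        stringsAsFactors = FALSE)

  haplotypes <- NULL
  if (phased) {
    h1 <- matrix(as.integer(a1 == "1"), nrow = nrow(gt))
    h2 <- matrix(as.integer(a2 == "1"), nrow = nrow(gt))
    h1[miss] <- NA_integer_; h2[miss] <- NA_integer_
    haplotypes <- matrix(NA_integer_, 2L * ncol(gt), nrow(gt))
    haplotypes[seq(1, nrow(haplotypes), 2), ] <- t(h1)
    haplotypes[seq(2, nrow(haplotypes), 2), ] <- t(h2)
  }
  genotype_dataset(calls, variants, samples, haplotypes = haplotypes,
                   phased = phased)
}

#' Write a genotype dataset to a standard format
#'
#' `write_fixture()` materialises a dataset as a text PLINK, binary PLINK, or
#' (plain-text) VCF fileset that round-trips through [read_plink()] /
#' [read_vcf()].  Phased datasets written to VCF use the `|` separator so
#' phase survives the round trip; the PLINK formats are genotype-only.
#'
#' @param ds a [genotype_dataset()].
#' @param format one of `"plink_text"`, `"plink_binary"`, `"vcf"`.
#' @param path output prefix (PLINK) or file path (VCF).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(ds, format = c("plink_text", "plink_binary", "vcf"),
                          path) {
  format <- match.arg(format)
  switch(format,
         plink_text = write_plink_text(ds, path),
         plink_binary = write_plink_binary(ds, path),
         vcf = write_vcf(ds, path))
}

write_plink_text <- function(ds, prefix) {
  .check_writable(dirname(prefix))
  v <- ds$variants
  map <- data.frame(v$chrom, v$id, 0, v$pos_bp)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- nrow(ds$calls); L <- ncol(ds$calls)
  al <- matrix("0", n, 2L * L)
  for (j in seq_len(L)) {
    d <- ds$calls[, j]
    a1 <- ifelse(is.na(d), "0", ifelse(d == 2, v$alt[j], v$ref[j]))
    a2 <- ifelse(is.na(d), "0", ifelse(d >= 1, v$alt[j], v$ref[j]))
    al[, 2L * j - 1L] <- a1
    al[, 2L * j] <- a2
  }
  ped <- cbind(ds$samples$population, ds$samples$id, "0", "0", "0", "-9", al)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(paste0(prefix, c(".ped", ".map")))
}

write_plink_binary <- function(ds, prefix) {
  .check_writable(dirname(prefix))
  v <- ds$variants
  bim <- data.frame(v$chrom, v$id, 0, v$pos_bp, v$ref, v$alt)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  fam <- data.frame(ds$samples$population, ds$samples$id, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- nrow(ds$calls); L <- ncol(ds$calls)
  bps <- ceiling(n / 4)
  # dosage -> 2-bit code: 0 -> 00, 1 -> 10, 2 -> 11, NA -> 01
  code <- matrix(0L, 4L * bps, L)  # pad slots are zero bits, as in PLINK
  code_map <- c(`0` = 0L, `1` = 2L, `2` = 3L)
  d <- ds$calls
  cd <- matrix(1L, n, L)
  cd[!is.na(d)] <- code_map[as.character(d[!is.na(d)])]
  code[seq_len(n), ] <- cd
  shifts <- rep(c(0L, 2L, 4L, 6L), bps)
  byte_vals <- colSums(matrix(code * 2^shifts, nrow = 4L))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(byte_vals), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

write_vcf <- function(ds, path) {
  .check_writable(dirname(path))
  v <- ds$variants
  n <- nrow(ds$calls); L <- ncol(ds$calls)
  header <- c("##fileformat=VCFv4.2",
              "##source=popld",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ds$samples$id), collapse = "\t"))
  if (ds$phased && !is.null(ds$haplotypes)) {
    h1 <- ds$haplotypes[seq(1, 2 * n, 2), , drop = FALSE]
    h2 <- ds$haplotypes[seq(2, 2 * n, 2), , drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), n, L)
    gt[is.na(h1) | is.na(h2)] <- ".|."
  } else {
    gt <- matrix("./.", n, L)
    gt[!is.na(ds$calls) & ds$calls == 0] <- "0/0"
    gt[!is.na(ds$calls) & ds$calls == 1] <- "0/1"
    gt[!is.na(ds$calls) & ds$calls == 2] <- "1/1"
  }
  body <- vapply(seq_len(L), function(j)
    paste(c(v$chrom[j], v$pos_bp[j], v$id[j], v$ref[j], v$alt[j], ".",
            "PASS", ".", "GT", gt[, j]), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

.check_writable <- function(dir) {
  if (!dir.exists(dir)) stop("cannot write to '", dir, "': no such directory")
  invisible(dir)
}

#' Restrict datasets to their common markers
#'
#' Marker identity is the triple (id, chromosome, position).  Every returned
#' dataset carries exactly the intersection marker set, in the map order of
#' the first dataset, so cross-population statistics line up pair for pair.
#' Allele coding is *not* reconciled here; run [align_alleles()] before any
#' signed cross-population statistic.
#'
#' @param datasets list of two or more [genotype_dataset()] objects.
#' @return list of datasets with identical variant tables.
#' @export
intersect_on_common_markers <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2)
    stop("need a list of at least two datasets")
  keys <- lapply(datasets, function(d)
    paste(d$variants$id, d$variants$chrom, d$variants$pos_bp, sep = "\r"))
  common <- Reduce(intersect, keys)
  if (length(common) == 0)
    stop("the datasets share no markers; check that they were genotyped on ",
         "a common map (same ids, chromosomes and positions)")
  ref_order <- keys[[1]][keys[[1]] %in% common]
  lapply(seq_along(datasets), function(k) {
    j <- match(ref_order, keys[[k]])
    subset_dataset(datasets[[k]], j = j)
  })
}
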