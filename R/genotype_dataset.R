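#' Construct a genotype dataset
#'
#' The universal input container of the package: diploid SNP genotypes for one
#' or more labelled populations, with a physical marker map and (optionally)
#' phased haplotypes.  Dosages count copies of the *alternate* allele
#' (`variants$alt`, i.e. the second PLINK .bim allele or the VCF ALT allele);
#' missing genotypes are `NA`.
#'
#' @param calls integer matrix, samples x variants, values in `{0, 1, 2, NA}`;
#'   entry `(i, j)` is the number of copies of `variants$alt[j]` carried by
#'   sample `i`.
#' @param variants data frame with columns `id`, `chrom`, `pos_bp`, `ref`,
#'   `alt`.  Positions are 1-based physical base pairs and must be unique
#'   within a chromosome.
#' @param samples data frame with columns `id` and `population` (non-empty
#'   labels).
#' @param haplotypes optional integer matrix of phased alleles in `{0, 1}`
#'   (1 = alternate allele), two consecutive rows per sample, required when
#'   `phased = TRUE`.
#' @param phased logical; `TRUE` when `haplotypes` carry known gametic phase.
#' @param sort_variants sort markers by (chromosome, position)?  Chromosomes
#'   order numerically where possible, with non-numeric labels (e.g. "X") last.
#' @param validate run consistency checks (dimensions, allele and dosage
#'   ranges, haplotype/dosage agreement)?
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `calls`, `variants`, `samples`, `haplotypes`, `phased`, `counted_allele`.
#' @examples
#' calls <- rbind(c(0L, 1L), c(2L, 1L), c(1L, 0L))
#' v <- data.frame(id = c("s1", "s2"), chrom = "1", pos_bp = c(100L, 200L),
#'                 ref = "A", alt = "C")
#' s <- data.frame(id = paste0("ind", 1:3), population = "popA")
#' ds <- genotype_dataset(calls, v, s)
#' ds
#' @export
genotype_dataset <- function(calls, variants, samples, haplotypes = NULL,
                             phased = FALSE, sort_variants = TRUE,
                             validate = TRUE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants$chrom <- as.character(variants$chrom)
  samples$population <- as.character(samples$population)

  if (sort_variants) {
    ord <- order_chromosomes(variants$chrom, variants$pos_bp)
    if (!identical(ord, seq_len(nrow(variants)))) {
      variants <- variants[ord, , drop = FALSE]
      calls <- calls[, ord, drop = FALSE]
      if (!is.null(haplotypes)) haplotypes <- haplotypes[, ord, drop = FALSE]
    }
  }
  rownames(variants) <- NULL
  dimnames(calls) <- list(samples$id, variants$id)

  ds <- structure(list(calls = calls, variants = variants, samples = samples,
                       haplotypes = haplotypes, phased = isTRUE(phased),
                       counted_allele = "alt"),
                  class = "genotype_dataset")
  if (validate) validate_genotype_dataset(ds)
  ds
}

#' @rdname genotype_dataset
#' @param ds a `genotype_dataset`
#' @export
validate_genotype_dataset <- function(ds) {
  v <- ds$variants
  need <- c("id", "chrom", "pos_bp", "ref", "alt")
  if (!all(need %in% names(v)))
    stop("variants must have columns ", paste(need, collapse = ", "))
  if (!all(c("id", "population") %in% names(ds$samples)))
    stop("samples must have columns id, population")
  if (nrow(ds$calls) != nrow(ds$samples))
    stop("calls has ", nrow(ds$calls), " rows but there are ",
         nrow(ds$samples), " samples")
  if (ncol(ds$calls) != nrow(v))
    stop("calls has ", ncol(ds$calls), " columns but there are ",
         nrow(v), " variants")
  if (any(!is.na(v$ref) & !is.na(v$alt) & v$ref == v$alt))
    stop("ref and alt alleles must differ for every variant")
  if (any(v$pos_bp < 0)) stop("positions must be >= 0")
  dup <- duplicated(paste(v$chrom, v$pos_bp))
  if (any(dup))
    stop("duplicate positions within a chromosome: ",
         paste(utils::head(v$id[dup], 5), collapse = ", "))
  bad <- !is.na(ds$calls) & !(ds$calls %in% 0:2)
  if (any(bad)) stop("dosages must be in {0, 1, 2} or NA")
  if (any(!nzchar(ds$samples$population)) || anyNA(ds$samples$population))
    stop("population labels must be non-empty")
  if (ds$phased) {
    h <- ds$haplotypes
    if (is.null(h)) stop("phased = TRUE requires haplotypes")
    if (nrow(h) != 2L * nrow(ds$calls) || ncol(h) != ncol(ds$calls))
      stop("haplotypes must be (2 x n samples) x (n variants)")
    if (any(!is.na(h) & !(h %in% 0:1))) stop("haplotype alleles must be 0/1")
    dos <- h[seq(1, nrow(h), by = 2), , drop = FALSE] +
      h[seq(2, nrow(h), by = 2), , drop = FALSE]
    ok <- is.na(ds$calls) | (!is.na(dos) & dos == ds$calls)
    if (!all(ok))
      stop("haplotype pairs disagree with dosages at ", sum(!ok), " cells")
  }
  invisible(ds)
}

# Ordering rank for chromosome labels: numeric labels first in numeric order,
# then non-numeric labels (X, Y, MT, ...) alphabetically.
order_chromosomes <- function(chrom, pos_bp) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom, pos_bp)
}

# Is a chromosome label the X chromosome?  The bovine-mapped buffalo array
# labels BTA X as chromosome "30", so both spellings alias to X by default;
# override via options(popld.x_chromosomes = ...).
is_x_chromosome <- function(chrom,
                            x_labels = getOption("popld.x_chromosomes",
                                                 c("X", "30"))) {
  chrom %in% x_labels
}

# internal subset: i = sample index, j = variant index (both optional)
subset_dataset <- function(ds, i = NULL, j = NULL) {
  if (!is.null(i)) {
    ds$calls <- ds$calls[i, , drop = FALSE]
    ds$samples <- ds$samples[i, , drop = FALSE]
    rownames(ds$samples) <- NULL
    if (!is.null(ds$haplotypes)) {
      hrows <- as.vector(rbind(2L * i - 1L, 2L * i))
      ds$haplotypes <- ds$haplotypes[hrows, , drop = FALSE]
    }
  }
  if (!is.null(j)) {
    ds$calls <- ds$calls[, j, drop = FALSE]
    ds$variants <- ds$variants[j, , drop = FALSE]
    rownames(ds$variants) <- NULL
    if (!is.null(ds$haplotypes))
      ds$haplotypes <- ds$haplotypes[, j, drop = FALSE]
  }
  ds
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "samples x",
      nrow(x$variants), "variants",
      if (x$phased) "(phased)" else "(unphased)", "\n")
  tab <- table(x$samples$population)
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  cat("chromosomes:", length(unique(x$variants$chrom)),
      " missing calls:", sum(is.na(x$calls)), "\n")
  invisible(x)
}

#' @export
summary.genotype_dataset <- function(object, ...) {
  v <- object$variants
  sp <- split(v$pos_bp, v$chrom)
  chrom_tab <- data.frame(
    chrom = names(sp),
    n_snps = vapply(sp, length, 0L),
    span_mb = vapply(sp, function(p) diff(range(p)) / 1e6, 0),
    mean_spacing_kb = vapply(sp, function(p)
      if (length(p) > 1) mean(diff(sort(p))) / 1e3 else NA_real_, 0),
    row.names = NULL)
  chrom_tab <- chrom_tab[order_chromosomes(chrom_tab$chrom,
                                           seq_len(nrow(chrom_tab))), ]
  rownames(chrom_tab) <- NULL
  out <- list(n_samples = nrow(object$samples),
              n_variants = nrow(v),
              phased = object$phased,
              populations = table(object$samples$population),
              missing_rate = mean(is.na(object$calls)),
              chromosomes = chrom_tab)
  class(out) <- "summary.genotype_dataset"
  out
}

#' @export
print.summary.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", x$n_samples, "samples x", x$n_variants,
      "variants", if (x$phased) "(phased)" else "(unphased)", "\n")
  cat("missing call rate:", format(x$missing_rate, digits = 4), "\n")
  print(x$chromosomes)
  invisible(x)
}
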