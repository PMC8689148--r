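#' Pool populations into labelled groups
#'
#' Concatenates the samples of several datasets under group labels (e.g.
#' pooling closely related breeds from one country).  All inputs must share
#' an identical, allele-aligned marker map; the pooled sample count becomes
#' the `n` of the finite-sample correction downstream.
#'
#' @param datasets list of [genotype_dataset()] objects with identical
#'   variant tables.
#' @param pooling named character vector mapping each dataset's population
#'   label to its group label; datasets whose label is absent keep their own.
#' @return named list of pooled [genotype_dataset()] objects, one per group.
#' @examples
#' \dontrun{
#' pooled <- pool_populations(list(azi, khu, maz),
#'                            c(AZI = "IRI", KHU = "IRI", MAZ = "IRI"))
#' }
#' @export
pool_populations <- function(datasets, pooling) {
  if (inherits(datasets, "genotype_dataset")) datasets <- list(datasets)
  key0 <- with(datasets[[1]]$variants, paste(id, chrom, pos_bp, ref, alt))
  for (d in datasets)
    if (!identical(with(d$variants, paste(id, chrom, pos_bp, ref, alt)), key0))
      stop("datasets do not share an identical aligned marker set; run ",
           "intersect_on_common_markers() and align_alleles() first")
  labels <- vapply(datasets, function(d) d$samples$population[1], "")
  groups <- ifelse(labels %in% names(pooling), pooling[labels], labels)
  out <- lapply(unique(groups), function(g) {
    members <- datasets[groups == g]
    calls <- do.call(rbind, lapply(members, function(d) d$calls))
    samples <- do.call(rbind, lapply(members, function(d) d$samples))
    samples$population <- g
    rownames(samples) <- NULL
    phased <- all(vapply(members, function(d) d$phased, TRUE))
    hap <- if (phased)
      do.call(rbind, lapply(members, function(d) d$haplotypes)) else NULL
    genotype_dataset(calls, members[[1]]$variants, samples,
                     haplotypes = hap, phased = phased,
                     sort_variants = FALSE)
  })
  names(out) <- unique(groups)
  out
}

#' Pipeline configuration
#'
#' Bundles every setting of [run_ld_pipeline()].  `populations` maps labels
#' to inputs: each element is either a [genotype_dataset()] or a file
#' reference (PLINK prefix or VCF path).
#'
#' @param populations named list of inputs, one per population.
#' @param thresholds a [qc_thresholds()].
#' @param phased force the phased (`TRUE`) or dosage (`FALSE`) LD path;
#'   `NULL` follows each dataset's phase flag.
#' @param bin_bp,max_bp LD-decay binning (defaults 100 kb bins to 15 Mb).
#' @param ld_thresholds adjusted-r2 thresholds for adjacent-LD fractions.
#' @param pldp_pairs list of label pairs for phase-persistence; `NULL` means
#'   all pairs of (pooled) groups.
#' @param pldp_max_bp largest distance for phase persistence (default 1 Mb).
#' @param pooling optional named vector mapping population labels to pooled
#'   group labels (applied after QC and marker intersection).
#' @param map a [map_function()].
#' @param out_dir output directory for the stage TSVs and run log.
#' @param seed recorded in the run log (the pipeline itself is
#'   deterministic given its inputs).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(populations, thresholds = qc_thresholds(),
                            phased = NULL, bin_bp = 1e5, max_bp = 15e6,
                            ld_thresholds = c(0.2, 0.3), pldp_pairs = NULL,
                            pldp_max_bp = 1e6, pooling = NULL,
                            map = map_function(), out_dir = ".",
                            seed = NULL) {
  if (is.null(names(populations)) || any(!nzchar(names(populations))))
    stop("populations must be a named list")
  if (anyDuplicated(names(populations)))
    stop("population labels must be unique")
  structure(list(populations = populations, thresholds = thresholds,
                 phased = phased, bin_bp = bin_bp, max_bp = max_bp,
                 ld_thresholds = ld_thresholds, pldp_pairs = pldp_pairs,
                 pldp_max_bp = pldp_max_bp, pooling = pooling, map = map,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the full LD analysis workflow
#'
#' Ingest (or accept) per-population genotypes, apply QC and the
#' common-marker merge, align alleles, optionally pool populations, then
#' compute adjacent-SNP LD summaries, LD decay curves, phase persistence for
#' the configured pairs, and Ne trajectories.  One TSV per stage is written
#' to `out_dir` (with `#`-prefixed header comments recording the parameters
#' used) plus a `run_log.txt`; identical config and inputs give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `manifest` (named vector of file paths)
#'   and the in-memory stage results.
#' @export
run_ld_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # fail fast: every referenced input must exist before any computation
  for (label in names(config$populations)) {
    x <- config$populations[[label]]
    if (is.character(x)) {
      ok <- file.exists(x) || file.exists(paste0(x, ".bed")) ||
        file.exists(paste0(x, ".ped"))
      if (!ok) stop("input for population '", label, "' not found: ", x)
    } else if (!inherits(x, "genotype_dataset")) {
      stop("input for population '", label,
           "' must be a genotype_dataset or a file reference")
    }
  }
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  log_lines <- c(paste0("# popld ",
                        as.character(utils::packageVersion("popld"))),
                 paste0("seed: ", config$seed %||% "none"),
                 paste0("mind: ", config$thresholds$max_missing_individual),
                 paste0("geno: ", config$thresholds$max_missing_snp),
                 paste0("maf: ", config$thresholds$min_maf),
                 paste0("hwe_p: ", config$thresholds$hwe_p_cutoff),
                 paste0("bin_bp: ", config$bin_bp),
                 paste0("max_bp: ", config$max_bp),
                 paste0("cm_per_mb: ", config$map$cm_per_mb))
  manifest <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  datasets <- stage("ingest", lapply(names(config$populations), function(l) {
    x <- config$populations[[l]]
    if (inherits(x, "genotype_dataset")) {
      x$samples$population <- l
      x
    } else if (grepl("\\.vcf(\\.gz)?$", x)) {
      read_vcf(x, population = l)
    } else read_plink(x, population = l)
  }))
  names(datasets) <- names(config$populations)

  qc <- stage("qc", run_qc(datasets, config$thresholds))
  datasets <- qc$datasets
  names(datasets) <- names(config$populations)

  # align all datasets' allele coding to the first
  datasets <- stage("align", {
    if (length(datasets) > 1)
      for (k in 2:length(datasets))
        datasets[[k]] <- align_alleles(datasets[[1]], datasets[[k]])$b
    datasets
  })

  groups <- stage("pooling", {
    if (is.null(config$pooling)) datasets
    else pool_populations(datasets, config$pooling)
  })

  hdr <- function(extra = character(0)) c(log_lines, extra)
  rep_path <- file.path(config$out_dir, "qc_report.tsv")
  r <- qc$report
  write_stage_tsv(data.frame(
    metric = c("individuals_removed", "snps_removed_missing",
               "snps_removed_hwe",
               paste0("snps_removed_maf_", names(r$snps_removed_maf)),
               "snps_after_merge", "total_genotyping_rate"),
    value = c(r$individuals_removed, r$snps_removed_missing,
              r$snps_removed_hwe, unname(r$snps_removed_maf),
              r$snps_after_merge, r$total_genotyping_rate)),
    rep_path, hdr())
  manifest["qc_report"] <- rep_path

  results <- list(qc_report = qc$report, adjacent = list(), decay = list(),
                  pldp = list(), ne = list())
  for (g in names(groups)) {
    ds <- groups[[g]]
    adj <- stage(paste0("adjacent_ld:", g),
                 adjacent_ld_summary(ds, phased = config$phased,
                                     thresholds = config$ld_thresholds))
    p <- file.path(config$out_dir, paste0("adjacent_ld_", g, ".tsv"))
    write_stage_tsv(adj, p, hdr(paste0("population: ", g)))
    manifest[paste0("adjacent_ld_", g)] <- p
    results$adjacent[[g]] <- adj

    dec <- stage(paste0("ld_decay:", g),
                 ld_decay(ds, max_bp = config$max_bp, bin_bp = config$bin_bp,
                          phased = config$phased))
    p <- file.path(config$out_dir, paste0("ld_decay_", g, ".tsv"))
    write_stage_tsv(dec, p, hdr(paste0("population: ", g)))
    manifest[paste0("ld_decay_", g)] <- p
    results$decay[[g]] <- dec

    ne <- stage(paste0("ne:", g), ne_trajectory(dec, map = config$map))
    p <- file.path(config$out_dir, paste0("ne_trajectory_", g, ".tsv"))
    write_stage_tsv(ne, p, hdr(paste0("population: ", g)))
    manifest[paste0("ne_trajectory_", g)] <- p
    results$ne[[g]] <- ne
  }

  pairs <- config$pldp_pairs
  if (is.null(pairs) && length(groups) > 1) {
    cmb <- utils::combn(names(groups), 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
  }
  for (pr in pairs) {
    nm <- paste0(pr[1], "_", pr[2])
    pp <- stage(paste0("pldp:", nm),
                pldp(groups[[pr[1]]], groups[[pr[2]]],
                     bin_bp = config$bin_bp, max_bp = config$pldp_max_bp,
                     phased = config$phased))
    p <- file.path(config$out_dir, paste0("pldp_", nm, ".tsv"))
    write_stage_tsv(pp$bins, p,
                    hdr(c(paste0("populations: ", pr[1], " ", pr[2]),
                          paste0("pairs_dropped: ", pp$n_dropped))))
    manifest[paste0("pldp_", nm)] <- p
    results$pldp[[nm]] <- pp
  }

  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(c(log_lines, paste0("outputs: ", length(manifest))), log_path)
  manifest["run_log"] <- log_path
  invisible(list(manifest = manifest, results = results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TSV with '#' comment header lines carrying run parameters
write_stage_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", sub("^# ", "", comments)), con)
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 12,
                                                trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
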