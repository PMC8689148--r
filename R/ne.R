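#' Linear genetic map
#'
#' A constant cM-per-Mb map used to convert physical marker separation into
#' recombination distance.  The default 1 cM/Mb is the usual coarse assumption
#' for SNP-array work in cattle-mapped livestock genomes.
#'
#' @param cm_per_mb recombination rate in centimorgans per megabase.
#' @return list of class `map_function`.
#' @export
map_function <- function(cm_per_mb = 1) {
  if (!is.numeric(cm_per_mb) || length(cm_per_mb) != 1 || cm_per_mb <= 0)
    stop("cm_per_mb must be a single positive number")
  structure(list(cm_per_mb = cm_per_mb), class = "map_function")
}

#' Physical distance to recombination distance
#'
#' `bp -> Mb -> cM -> Morgans`, i.e. `distance_bp * cm_per_mb * 1e-8`.
#'
#' @param distance_bp physical separation in base pairs (vectorised).
#' @param map a [map_function()].
#' @return distance in Morgans.
#' @examples
#' distance_to_morgans(1e6)  # 0.01 Morgans at 1 cM/Mb
#' @export
distance_to_morgans <- function(distance_bp, map = map_function()) {
  if (any(distance_bp < 0)) stop("distances must be >= 0")
  distance_bp * map$cm_per_mb * 1e-8
}

#' Generations in the past probed by a recombination distance
#'
#' The LD between markers separated by `c` Morgans reflects effective
#' population size roughly `T = 1/(2c)` generations ago.
#'
#' @param c recombination distance in Morgans (vectorised, all > 0).
#' @return generations.
#' @examples
#' generation_for_c(0.001)  # 500 generations
#' @export
generation_for_c <- function(c) {
  if (any(is.na(c)) || any(c <= 0)) stop("c must be > 0")
  1 / (2 * c)
}

#' Effective population size from mean adjusted r-squared (Sved's relation)
#'
#' Inverts the drift-recombination expectation `E[r2] = 1/(1 + 4 Ne c)`:
#' `Ne = (1/(4c)) * (1/r2 - 1)`.
#'
#' @param mean_r2_adj mean adjusted r-squared at distance `c` (vectorised).
#' @param c recombination distance in Morgans, > 0.
#' @return the Ne estimate; `NA` (with a warning) where `mean_r2_adj <= 0`,
#'   which can occur after the finite-sample correction.
#' @examples
#' sved_ne(0.25, 0.0005)  # 1500
#' sved_ne(0.05, 0.01)    # 475
#' @export
sved_ne <- function(mean_r2_adj, c) {
  if (any(is.na(c)) || any(c <= 0)) stop("c must be > 0")
  bad <- is.na(mean_r2_adj) | mean_r2_adj <= 0
  if (any(bad))
    warning("Ne undefined for ", sum(bad),
            " value(s) with mean adjusted r2 <= 0; returning NA")
  ne <- (1 / (4 * c)) * (1 / mean_r2_adj - 1)
  ne[bad] <- NA_real_
  ne
}

#' Effective-population-size trajectory from an LD decay curve
#'
#' Maps every non-empty decay bin to one point of the Ne history: the bin's
#' representative distance becomes a recombination distance `c` through the
#' genetic map, `T = 1/(2c)` dates the estimate, and Sved's relation converts
#' the bin's mean adjusted r-squared into Ne.  Bins whose adjusted mean
#' r-squared is non-positive are skipped and counted.
#'
#' @param decay an [ld_decay()] result (or data frame with columns
#'   `lower_bp`, `upper_bp`, `n_pairs`, `mean_r2_adj`, optionally
#'   `mean_distance_bp`).
#' @param map a [map_function()].
#' @param distance `"midpoint"` (default, deterministic bin midpoint) or
#'   `"mean"` (mean observed pair distance per bin).
#' @return data frame of class `ne_trajectory`, sorted by generations `T`
#'   ascending, with columns `c_morgans`, `T_generations`, `n_pairs`,
#'   `mean_r2_adj`, `ne`.  Attribute `n_skipped_bins` counts skipped bins.
#' @examples
#' decay <- data.frame(lower_bp = 450000, upper_bp = 550000, n_pairs = 10L,
#'                     mean_distance_bp = 5e5, mean_r2_adj = 0.1)
#' ne_trajectory(decay)  # c = 0.005, T = 100, Ne = 450
#' @export
ne_trajectory <- function(decay, map = map_function(),
                          distance = c("midpoint", "mean")) {
  distance <- match.arg(distance)
  if (nrow(decay) == 0) stop("decay table is empty")
  use <- decay$n_pairs > 0
  skipped <- sum(use & (is.na(decay$mean_r2_adj) | decay$mean_r2_adj <= 0))
  use <- use & !is.na(decay$mean_r2_adj) & decay$mean_r2_adj > 0
  if (!any(use))
    stop("no usable decay bins (all empty or with non-positive adjusted r2)")
  d_bp <- if (distance == "midpoint") (decay$lower_bp + decay$upper_bp) / 2
          else decay$mean_distance_bp
  cc <- distance_to_morgans(d_bp[use], map)
  res <- data.frame(c_morgans = cc,
                    T_generations = generation_for_c(cc),
                    n_pairs = decay$n_pairs[use],
                    mean_r2_adj = decay$mean_r2_adj[use],
                    ne = sved_ne(decay$mean_r2_adj[use], cc))
  res <- res[order(res$T_generations), ]
  rownames(res) <- NULL
  attr(res, "n_skipped_bins") <- skipped
  attr(res, "map") <- map
  class(res) <- c("ne_trajectory", "data.frame")
  res
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("Ne trajectory:", nrow(x), "points, T in [",
      format(min(x$T_generations), digits = 4), ",",
      format(max(x$T_generations), digits = 4), "] generations\n")
  if (attr(x, "n_skipped_bins") > 0)
    cat("  (", attr(x, "n_skipped_bins"),
        "bins skipped: non-positive adjusted r2 )\n")
  print.data.frame(x)
  invisible(x)
}

#' @export
plot.ne_trajectory <- function(x, ...) {
  graphics::plot(x$T_generations, x$ne, type = "b", pch = 16, cex = 0.6,
                 log = "x", xlab = "generations ago (T)",
                 ylab = "effective population size (Ne)", ...)
  invisible(x)
}

#' Expected loss of genetic diversity over future generations
#'
#' The standard compounding of heterozygosity loss at rate `1/(2 Ne)` per
#' generation: `100 * (1 - (1 - 1/(2 ne))^generations)` percent.
#'
#' @param ne effective population size, > 0.
#' @param generations number of future generations, >= 0.
#' @return percentage of diversity lost.
#' @examples
#' expected_diversity_loss(25, 10)   # ~18.3%
#' expected_diversity_loss(50, 10)   # ~9.6%
#' @export
expected_diversity_loss <- function(ne, generations) {
  if (any(is.na(ne)) || any(ne <= 0)) stop("ne must be > 0")
  if (any(generations < 0)) stop("generations must be >= 0")
  100 * (1 - (1 - 1 / (2 * ne))^generations)
}
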