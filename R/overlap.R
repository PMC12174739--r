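#' @title Monte Carlo overlap null
#' @description Empirical null distribution of cross-list gene overlap under
#'   repeated uniform or connectivity-weighted resampling of study-sized gene
#'   lists from the universe, with empirical p-values for observed overlaps.
#' @name overlap_null
NULL

#' Configuration for the overlap simulation
#'
#' @param universe character (or integer) vector of gene identifiers forming
#'   the sampling frame.
#' @param list_sizes one positive integer per study list; each must not
#'   exceed the universe size.
#' @param iterations number of Monte Carlo iterations (default 10000).
#' @param sampling `"weighted"` (probability proportional to `weights`, via
#'   successive renormalized draws without replacement) or `"uniform"`.
#' @param weights strictly positive finite per-gene weights, named by gene id
#'   or aligned with `universe`; required when `sampling = "weighted"`.
#' @param seed integer seed; every run with the same configuration is
#'   bit-identical.
#' @param simulate_directions `NULL` (default) records plain identity
#'   overlap, matching a vote count that ignores fold-change direction in the
#'   null. A numeric up-fraction (single value, or one per list) additionally
#'   assigns independent random signs to sampled genes, and the null then
#'   counts direction-consistent overlap (modal direction, exact ties
#'   inconsistent) - the direction-aware variant of the test.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(universe, list_sizes, iterations = 10000,
                              sampling = c("weighted", "uniform"),
                              weights = NULL, seed = NULL,
                              simulate_directions = NULL) {
  sampling <- match.arg(sampling)
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop("universe contains duplicated gene ids", call. = FALSE)
  list_sizes <- as.integer(list_sizes)
  if (!length(list_sizes) || any(list_sizes < 1))
    stop("`list_sizes` must be positive integers", call. = FALSE)
  if (any(list_sizes > length(universe)))
    stop("a list size exceeds the universe size", call. = FALSE)
  if (length(iterations) != 1 || iterations < 1)
    stop("`iterations` must be a positive integer", call. = FALSE)
  if (sampling == "weighted") {
    if (is.null(weights)) stop("weighted sampling requires `weights`", call. = FALSE)
    if (!is.null(names(weights))) {
      idx <- match(universe, names(weights))
      if (anyNA(idx)) stop("`weights` lacks some universe genes", call. = FALSE)
      weights <- unname(weights[idx])
    }
    if (length(weights) != length(universe))
      stop("`weights` must align with the universe", call. = FALSE)
    if (any(!is.finite(weights)) || any(weights <= 0))
      stop("weights must be strictly positive and finite", call. = FALSE)
  } else weights <- NULL
  if (!is.null(simulate_directions)) {
    simulate_directions <- rep_len(as.numeric(simulate_directions), length(list_sizes))
    if (any(simulate_directions < 0 | simulate_directions > 1))
      stop("`simulate_directions` up-fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(universe = universe, list_sizes = list_sizes,
                 iterations = as.integer(iterations), sampling = sampling,
                 weights = weights, seed = seed,
                 simulate_directions = simulate_directions),
            class = "simulation_config")
}

# one draw of all study lists, as integer indices into the universe;
# uses the current RNG stream
.draw_lists <- function(n, sizes, weights) {
  lapply(sizes, function(s) weighted_sample_int(n, s, weights))
}

#' Sample one set of study-sized gene lists
#'
#' Lists are sampled independently of each other, each without replacement
#' within itself. When `cfg$seed` is set the RNG is seeded first, so repeated
#' calls with the same configuration return identical lists.
#'
#' @param cfg a [simulation_config()].
#' @return list of character vectors of gene ids, one per study list.
#' @export
sample_gene_lists <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  idx <- .draw_lists(length(cfg$universe), cfg$list_sizes, cfg$weights)
  lapply(idx, function(i) cfg$universe[i])
}

#' Simulate the empirical null distribution of overlap
#'
#' For each iteration, study-sized gene lists are resampled from the
#' universe and the genes present in at least two lists are counted, both in
#' total and by exact level `k` (number of lists containing the gene). With
#' `simulate_directions` set, sampled genes get independent random signs and
#' only direction-consistent overlap (modal sign, ties dropped) is counted.
#'
#' 95% intervals are empirical 2.5/97.5 percentiles of the integer counts.
#'
#' @param cfg a [simulation_config()].
#' @return object of class `overlap_null`: list with `per_iteration_total`,
#'   `level_counts` (iterations x levels matrix, columns `"2"` ... `"m"`),
#'   `mean_total`, `sd_total`, `ci95_total`, `mean_by_level`,
#'   `ci95_by_level`, and the configuration summary.
#' @export
simulate_null <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- length(cfg$universe)
  m <- length(cfg$list_sizes)
  it <- cfg$iterations
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dirs <- cfg$simulate_directions
  max_lev <- max(m, 2L)
  levels_kept <- 2:max_lev
  level_counts <- matrix(0L, it, length(levels_kept),
                         dimnames = list(NULL, as.character(levels_kept)))
  sizes <- cfg$list_sizes
  for (i in seq_len(it)) {
    idx <- .draw_lists(n, sizes, cfg$weights)
    if (is.null(dirs)) {
      cnt <- tabulate(unlist(idx), nbins = n)
      lv <- tabulate(cnt, nbins = max_lev)
    } else {
      up <- integer(n); dn <- integer(n)
      for (j in seq_len(m)) {
        s <- stats::runif(sizes[j]) < dirs[j]
        iu <- idx[[j]][s]
        id <- idx[[j]][!s]
        up[iu] <- up[iu] + 1L
        dn[id] <- dn[id] + 1L
      }
      nag <- pmax(up, dn)
      nag[up == dn] <- 0L
      lv <- tabulate(nag, nbins = max_lev)
    }
    level_counts[i, ] <- lv[levels_kept]
  }
  total <- as.integer(rowSums(level_counts))
  q95 <- function(x) stats::quantile(x, c(0.025, 0.975), type = 1, names = FALSE)
  structure(list(per_iteration_total = total,
                 level_counts = level_counts,
                 mean_total = mean(total),
                 sd_total = stats::sd(total),
                 ci95_total = q95(total),
                 mean_by_level = colMeans(level_counts),
                 ci95_by_level = apply(level_counts, 2, q95),
                 iterations = it, sampling = cfg$sampling,
                 list_sizes = sizes, universe_size = n, seed = cfg$seed,
                 simulate_directions = dirs),
            class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat(sprintf("Monte Carlo overlap null (%s sampling, %d iterations, %d lists, universe %d)\n",
              x$sampling, x$iterations, length(x$list_sizes), x$universe_size))
  cat(sprintf("  genes in >=2 lists: mean %.2f (SD %.2f), 95%% CI %.2f-%.2f\n",
              x$mean_total, x$sd_total, x$ci95_total[1], x$ci95_total[2]))
  lv <- x$mean_by_level[x$mean_by_level > 0]
  if (length(lv))
    cat("  mean by level:", paste(sprintf("%s:%.2f", names(lv), lv), collapse = "  "), "\n")
  invisible(x)
}

# per-iteration counts of genes reaching at least `min_level` lists
.totals_at_least <- function(null, min_level) {
  lev <- as.integer(colnames(null$level_counts))
  keep <- lev >= min_level
  if (!any(keep)) return(rep(0L, null$iterations))
  as.integer(rowSums(null$level_counts[, keep, drop = FALSE]))
}

#' Empirical p-value for an observed overlap
#'
#' `p = (exceedances + 1) / (iterations + 1)` where exceedances counts null
#' iterations with overlap at least as large as observed; the add-one
#' convention keeps p strictly positive, and when no null draw reaches the
#' observed value the result is reported as the bound `p < 1/iterations`
#' (e.g. "p < 0.0001" at 10000 iterations).
#'
#' @param null an `overlap_null` from [simulate_null()].
#' @param observed observed integer overlap count.
#' @param min_level overlap level the observed count refers to: 2 (default)
#'   tests the total multi-list overlap; larger values test the count of
#'   genes reaching at least that many lists.
#' @return object of class `overlap_test`.
#' @export
empirical_pvalue <- function(null, observed, min_level = 2) {
  stopifnot(inherits(null, "overlap_null"))
  totals <- if (min_level <= 2) null$per_iteration_total
            else .totals_at_least(null, min_level)
  exceedances <- sum(totals >= observed)
  it <- null$iterations
  structure(list(observed = as.integer(observed),
                 min_level = as.integer(min_level),
                 iterations = it,
                 exceedances = as.integer(exceedances),
                 p_value = (exceedances + 1) / (it + 1),
                 p_is_bound = exceedances == 0L,
                 null_mean = mean(totals),
                 null_sd = stats::sd(totals)),
            class = "overlap_test")
}

#' Render an empirical p-value, as a bound when no null draw reached it
#' @param x an `overlap_test`.
#' @return character scalar such as `"0.0123"` or `"< 0.0001"`.
#' @export
format_pvalue <- function(x) {
  stopifnot(inherits(x, "overlap_test"))
  if (x$p_is_bound)
    paste0("< ", format(1 / x$iterations, scientific = FALSE))
  else format(x$p_value, digits = 4, scientific = FALSE)
}

#' @export
print.overlap_test <- function(x, ...) {
  lev <- if (x$min_level <= 2) ">=2 lists" else sprintf(">=%d lists", x$min_level)
  cat(sprintf("Monte Carlo overlap test (%s): observed %d, null mean %.2f (SD %.2f)\n",
              lev, x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  p %s (%d permutations)\n",
              if (x$p_is_bound) format_pvalue(x) else paste("=", format_pvalue(x)),
              x$iterations))
  invisible(x)
}

#' Run the null under weighted and uniform sampling side by side
#'
#' Both runs share the same seed schedule (each is seeded with `cfg$seed`),
#' so the comparison isolates the effect of connectivity weighting on the
#' null overlap level.
#'
#' @param cfg a [simulation_config()] with weights set.
#' @return object of class `overlap_null_pair`: list with `weighted`,
#'   `uniform`, `mean_diff` (weighted minus uniform mean total).
#' @export
compare_sampling_modes <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(cfg$weights)) stop("`cfg` must carry weights", call. = FALSE)
  cfg_w <- cfg; cfg_w$sampling <- "weighted"
  cfg_u <- cfg; cfg_u$sampling <- "uniform"; cfg_u$weights <- NULL
  w <- simulate_null(cfg_w)
  u <- simulate_null(cfg_u)
  structure(list(weighted = w, uniform = u,
                 mean_diff = w$mean_total - u$mean_total),
            class = "overlap_null_pair")
}

#' @export
print.overlap_null_pair <- function(x, ...) {
  cat("Weighted vs uniform overlap null\n")
  cat(sprintf("  weighted mean: %.2f (SD %.2f)\n", x$weighted$mean_total, x$weighted$sd_total))
  cat(sprintf("  uniform  mean: %.2f (SD %.2f)\n", x$uniform$mean_total, x$uniform$sd_total))
  cat(sprintf("  difference (weighted - uniform): %.2f\n", x$mean_diff))
  invisible(x)
}

#' Histogram of the two null distributions with the observed overlap
#'
#' @param x an `overlap_null_pair`.
#' @param observed optional observed overlap, drawn as a dashed vertical
#'   line.
#' @param ... further arguments passed to [graphics::hist()].
#' @return invisibly, `x`.
#' @export
plot.overlap_null_pair <- function(x, observed = NULL, ...) {
  wt <- x$weighted$per_iteration_total
  ut <- x$uniform$per_iteration_total
  rng <- range(c(wt, ut, observed))
  breaks <- seq(rng[1] - 0.5, rng[2] + 0.5, by = max(1, floor(diff(rng) / 40)))
  hw <- graphics::hist(wt, breaks = breaks, plot = FALSE)
  hu <- graphics::hist(ut, breaks = breaks, plot = FALSE)
  ylim <- c(0, max(hw$counts, hu$counts))
  graphics::plot(hu, col = grDevices::adjustcolor("forestgreen", 0.5),
                 border = NA, ylim = ylim, xlim = rng,
                 main = "Simulated overlap: uniform vs weighted null",
                 xlab = "genes in >=2 lists", ...)
  graphics::plot(hw, col = grDevices::adjustcolor("steelblue", 0.5),
                 border = NA, add = TRUE)
  if (!is.null(observed))
    graphics::abline(v = observed, col = "red", lty = 2, lwd = 2)
  graphics::legend("topright", fill = c("forestgreen", "steelblue"),
                   legend = c("uniform", "weighted"), bty = "n")
  invisible(x)
}
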