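#' @title Co-expression connectivity (WGCNA-style)
#' @description Build a weighted co-expression network over the gene
#'   universe - correlation, soft-threshold adjacency, topological overlap -
#'   and reduce it to one connectivity score per gene, used downstream as a
#'   sampling weight for the Monte Carlo overlap null.
#' @name coexpression
NULL

#' Gene-gene correlation matrix
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns; at least 3 samples.
#' @param method correlation type, passed to [stats::cor()].
#' @return symmetric genes x genes matrix in [-1, 1] with unit diagonal.
#' @export
correlation_matrix <- function(expr, method = "pearson") {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("`expr` must be a numeric matrix", call. = FALSE)
  if (ncol(expr) < 3) stop("at least 3 samples are required", call. = FALSE)
  v <- apply(expr, 1, stats::var)
  if (any(v == 0 | is.na(v))) {
    bad <- rownames(expr)[which(v == 0 | is.na(v))] %||% which(v == 0 | is.na(v))
    stop("zero-variance gene row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  cc <- stats::cor(t(expr), method = method)
  diag(cc) <- 1
  cc
}

#' Soft-threshold adjacency
#'
#' Unsigned networks use `|cor|^beta`; signed networks use
#' `((1 + cor)/2)^beta`. The diagonal is 1 by convention.
#'
#' @param corr correlation matrix.
#' @param beta soft-threshold exponent (> 0).
#' @param network_type `"unsigned"` (default) or `"signed"`.
#' @return adjacency matrix with entries in [0, 1].
#' @export
adjacency_matrix <- function(corr, beta, network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0)
    stop("`beta` must be a single positive number", call. = FALSE)
  a <- if (network_type == "unsigned") abs(corr)^beta else ((1 + corr) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over shared neighbours `u != i, j` and
#' `k_i = sum_{u != i} a_iu`; `TOM_ii = 1`. Optionally computed in column
#' blocks; the blocked result is bit-identical to the unblocked one.
#'
#' @param adj symmetric adjacency matrix with values in [0, 1].
#' @param block_size optional number of columns per block for the shared-
#'   neighbour product (memory control on large universes).
#' @return symmetric matrix in [0, 1].
#' @export
tom_similarity <- function(adj, block_size = NULL) {
  if (!is.matrix(adj) || !isSymmetric(unname(adj)))
    stop("`adj` must be a symmetric matrix", call. = FALSE)
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  n <- nrow(a)
  if (is.null(block_size) || block_size >= n) {
    l <- a %*% a
  } else {
    l <- matrix(0, n, n, dimnames = dimnames(a))
    starts <- seq(1, n, by = block_size)
    for (s in starts) {
      idx <- s:min(s + block_size - 1, n)
      l[, idx] <- a %*% a[, idx, drop = FALSE]
    }
  }
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Per-gene connectivity from a similarity matrix
#'
#' `k_i = sum_{j != i} TOM_ij` (the unit diagonal is excluded).
#'
#' @param tom topological overlap (or adjacency) matrix with unit diagonal.
#' @return named nonnegative numeric vector, one score per gene.
#' @export
connectivity_scores <- function(tom) {
  rowSums(tom) - diag(tom)
}

# signed scale-free topology fit: equal-width connectivity bins, log10 p(k)
# regressed on log10 of the per-bin mean k, R^2 sign-flipped so a decreasing
# degree distribution scores positive (the standard WGCNA fit index)
scale_free_fit <- function(k, n_breaks = 10) {
  k <- k[k > 0]
  if (length(k) < n_breaks) return(NA_real_)
  bins <- cut(k, breaks = n_breaks)
  p_k <- tapply(k, bins, length) / length(k)
  k_mid <- tapply(k, bins, mean)
  ok <- !is.na(p_k) & p_k > 0 & !is.na(k_mid) & k_mid > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(p_k[ok]) ~ log10(k_mid[ok]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Scan soft-threshold powers for scale-free topology fit
#'
#' For each candidate power the adjacency-based connectivity distribution is
#' binned and `log10 p(k)` regressed on `log10 k`; the signed model fit R^2
#' is positive when the degree distribution decreases (scale-free-like).
#' The chosen power is the smallest one reaching `r2_target`; if none does,
#' the best-fitting power is chosen with a warning.
#'
#' @param corr correlation matrix.
#' @param powers candidate exponents (default 1:20).
#' @param r2_target signed R^2 to reach (default 0.8).
#' @param network_type see [adjacency_matrix()].
#' @param n_breaks connectivity bins for the fit.
#' @return object of class `soft_threshold_scan`: list with `scan`
#'   (data.frame power / fit_r2 / mean_connectivity), `chosen_power`,
#'   `r2_target`, `reached_target`.
#' @export
pick_soft_threshold <- function(corr, powers = 1:20, r2_target = 0.8,
                                network_type = c("unsigned", "signed"),
                                n_breaks = 10) {
  network_type <- match.arg(network_type)
  if (!length(powers)) stop("`powers` must be nonempty", call. = FALSE)
  base <- if (network_type == "unsigned") abs(corr) else (1 + corr) / 2
  diag(base) <- 0
  if (all(base == 0)) stop("all-zero adjacency: no co-expression structure to scan", call. = FALSE)
  rows <- lapply(powers, function(b) {
    k <- rowSums(base^b)
    data.frame(power = b, fit_r2 = scale_free_fit(k, n_breaks),
               mean_connectivity = mean(k))
  })
  scan <- do.call(rbind, rows)
  hit <- which(!is.na(scan$fit_r2) & scan$fit_r2 >= r2_target)
  if (length(hit)) {
    chosen <- scan$power[hit[1]]
    reached <- TRUE
  } else {
    reached <- FALSE
    if (all(is.na(scan$fit_r2))) {
      chosen <- scan$power[1]
      warning("scale-free fit undefined for every candidate power; using the smallest",
              call. = FALSE)
    } else {
      chosen <- scan$power[which.max(scan$fit_r2)]
      warning(sprintf("no candidate power reached signed R^2 >= %g; using power %g (best fit %.3f)",
                      r2_target, chosen, max(scan$fit_r2, na.rm = TRUE)), call. = FALSE)
    }
  }
  structure(list(scan = scan, chosen_power = chosen, r2_target = r2_target,
                 reached_target = reached, network_type = network_type),
            class = "soft_threshold_scan")
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat(sprintf("Soft-threshold scan (%s network): chosen power %g (target R^2 %g%s)\n",
              x$network_type, x$chosen_power, x$r2_target,
              if (x$reached_target) "" else ", not reached"))
  print(x$scan, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Fit the full connectivity model over a gene universe
#'
#' Convenience wrapper: correlation -> soft-threshold scan -> adjacency ->
#' topological overlap -> per-gene connectivity.
#'
#' @inheritParams pick_soft_threshold
#' @param expr genes x samples expression matrix (rownames = gene ids).
#' @param beta fixed soft-threshold power; `NULL` (default) scans `powers`.
#' @param connectivity_basis `"tom"` (default) sums TOM rows; `"adjacency"`
#'   sums adjacency rows instead.
#' @param keep_matrices keep the adjacency and TOM matrices in the returned
#'   object (memory permitting).
#' @param block_size passed to [tom_similarity()].
#' @return object of class `connectivity_model`: list with `connectivity`
#'   (named per-gene scores), `power_beta`, `network_type`, `scan` (or NULL),
#'   and optionally `adjacency`, `tom`.
#' @export
build_connectivity_model <- function(expr, beta = NULL, powers = 1:20,
                                     r2_target = 0.8,
                                     network_type = c("unsigned", "signed"),
                                     connectivity_basis = c("tom", "adjacency"),
                                     keep_matrices = FALSE, block_size = NULL) {
  network_type <- match.arg(network_type)
  connectivity_basis <- match.arg(connectivity_basis)
  cc <- correlation_matrix(expr)
  scan <- NULL
  if (is.null(beta)) {
    scan <- pick_soft_threshold(cc, powers = powers, r2_target = r2_target,
                                network_type = network_type)
    beta <- scan$chosen_power
  }
  adj <- adjacency_matrix(cc, beta, network_type)
  tom <- tom_similarity(adj, block_size = block_size)
  k <- if (connectivity_basis == "tom") connectivity_scores(tom)
       else connectivity_scores(adj)
  out <- list(connectivity = k, power_beta = beta, network_type = network_type,
              connectivity_basis = connectivity_basis, scan = scan)
  if (keep_matrices) {
    out$adjacency <- adj
    out$tom <- tom
  }
  structure(out, class = "connectivity_model")
}

#' @export
print.connectivity_model <- function(x, ...) {
  cat(sprintf("Co-expression connectivity model: %d genes, %s network, beta = %g, %s-based k\n",
              length(x$connectivity), x$network_type, x$power_beta,
              x$connectivity_basis))
  cat(sprintf("  connectivity: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$connectivity), min(x$connectivity), max(x$connectivity)))
  invisible(x)
}

#' Sampling weights for an arbitrary gene set
#'
#' Genes present in DEG lists but absent from the expression universe cannot
#' be excluded without shrinking the universe asymmetrically; they receive
#' the universe's median connectivity and are flagged in the `"imputed"`
#' attribute.
#'
#' @param model a `connectivity_model` (or a named connectivity vector).
#' @param genes character vector of gene ids to weight (default: the whole
#'   universe).
#' @param floor small positive value replacing nonpositive scores so
#'   weighted sampling stays well-defined.
#' @return named positive numeric weights with attribute `"imputed"` (the
#'   ids that fell back to the median).
#' @export
connectivity_weights <- function(model, genes = NULL, floor = 1e-8) {
  k <- if (inherits(model, "connectivity_model")) model$connectivity else model
  if (is.null(names(k))) stop("connectivity scores must be named by gene id", call. = FALSE)
  genes <- genes %||% names(k)
  w <- k[match(genes, names(k))]
  imputed <- genes[is.na(w)]
  w[is.na(w)] <- stats::median(k)
  w <- pmax(w, floor)
  names(w) <- genes
  attr(w, "imputed") <- imputed
  w
}
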