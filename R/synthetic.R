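#' @title Synthetic study generator
#' @description Seed-deterministic generators for every input the pipeline
#'   consumes: per-study DEG tables over a shared universe with a planted set
#'   of consistently deregulated genes, a block-correlated expression matrix,
#'   an interaction graph with planted dense complexes, and a perturbation
#'   annotation table with known effect directions.
#' @name synthetic_data
NULL

#' Synthetic study configuration
#'
#' Defaults emulate a scaled-down multi-study white-matter meta-analysis:
#' 9 study lists of 50-80 genes drawn from a 2000-gene universe, 50 planted
#' genes each present in a given study with probability 0.6 and a consistent
#' fold-change direction, background genes drawn uniformly with random
#' directions, and an expression matrix in which the first half of the
#' universe is organized into correlated modules (the rest is independent
#' background noise, so connectivity is heterogeneous across genes).
#'
#' @param seed integer seed; all generators are deterministic given the
#'   configuration.
#' @param n_universe_genes universe size.
#' @param n_samples expression-matrix samples.
#' @param n_modules number of co-expression modules.
#' @param within_module_cor target pairwise correlation within a module.
#' @param n_studies number of study lists.
#' @param list_size_range inclusive (min, max) study list sizes.
#' @param planted_gene_count number of consistently deregulated genes.
#' @param planted_presence_prob probability a planted gene enters a given
#'   study list.
#' @param planted_direction_consistency probability a planted occurrence
#'   keeps the gene's true direction.
#' @param background_direction_split up-fraction for background genes.
#' @param plant_in `"modules"` places planted genes inside co-expression
#'   modules (stressing connectivity-weighted sampling); `"uniform"`
#'   scatters them over the universe.
#' @param ppi_complex_sizes sizes of planted dense complexes.
#' @param ppi_intra_p edge probability inside a planted complex.
#' @param ppi_background_p edge probability elsewhere.
#' @return object of class `synthesis_config`.
#' @export
synthesis_config <- function(seed = 1, n_universe_genes = 2000, n_samples = 50,
                             n_modules = 8, within_module_cor = 0.7,
                             n_studies = 9, list_size_range = c(50, 80),
                             planted_gene_count = 50,
                             planted_presence_prob = 0.6,
                             planted_direction_consistency = 1.0,
                             background_direction_split = 0.5,
                             plant_in = c("modules", "uniform"),
                             ppi_complex_sizes = c(25, 20, 15),
                             ppi_intra_p = 0.9, ppi_background_p = 0.05) {
  plant_in <- match.arg(plant_in)
  probs <- c(planted_presence_prob, planted_direction_consistency,
             background_direction_split, ppi_intra_p, ppi_background_p,
             within_module_cor)
  if (any(probs < 0 | probs > 1))
    stop("probabilities and correlations must lie in [0, 1]", call. = FALSE)
  if (length(list_size_range) != 2 || list_size_range[1] > list_size_range[2])
    stop("`list_size_range` must be (min, max)", call. = FALSE)
  if (list_size_range[2] > n_universe_genes)
    stop("list sizes cannot exceed the universe size", call. = FALSE)
  if (planted_gene_count > list_size_range[1])
    warning("planted_gene_count exceeds the smallest list size; planted genes may not all fit a list",
            call. = FALSE)
  structure(list(seed = as.integer(seed), n_universe_genes = as.integer(n_universe_genes),
                 n_samples = as.integer(n_samples), n_modules = as.integer(n_modules),
                 within_module_cor = within_module_cor, n_studies = as.integer(n_studies),
                 list_size_range = as.integer(list_size_range),
                 planted_gene_count = as.integer(planted_gene_count),
                 planted_presence_prob = planted_presence_prob,
                 planted_direction_consistency = planted_direction_consistency,
                 background_direction_split = background_direction_split,
                 plant_in = plant_in,
                 ppi_complex_sizes = as.integer(ppi_complex_sizes),
                 ppi_intra_p = ppi_intra_p, ppi_background_p = ppi_background_p),
            class = "synthesis_config")
}

#' Universe gene table for a configuration
#'
#' Gene identity is deterministic in the configuration: Entrez-style integer
#' ids, display symbols, a module assignment (0 = unstructured background;
#' modules cover the first half of the universe) and the planted flag.
#'
#' @param cfg a [synthesis_config()].
#' @return data.frame with columns `entrez_id`, `gene_symbol`, `module`,
#'   `planted`, `true_direction`.
#' @export
synth_universe <- function(cfg) {
  stopifnot(inherits(cfg, "synthesis_config"))
  n <- cfg$n_universe_genes
  # geometrically decaying module sizes over ~3/4 of the universe; the rest
  # is unstructured background, so connectivity is heterogeneous and the
  # adjacency degree distribution decays like real co-expression networks
  raw <- 0.7^(0:(cfg$n_modules - 1))
  sizes <- pmax(1L, as.integer(round(raw / sum(raw) * floor(0.75 * n))))
  module <- integer(n)
  assigned <- rep.int(seq_along(sizes), sizes)
  idx <- seq_len(min(n, length(assigned)))
  module[idx] <- assigned[idx]
  planted <- logical(n)
  if (cfg$planted_gene_count > 0) {
    if (cfg$plant_in == "modules") {
      planted[seq_len(min(cfg$planted_gene_count, n))] <- TRUE
    } else {
      set.seed(cfg$seed + 11L)
      planted[sample.int(n, cfg$planted_gene_count)] <- TRUE
    }
  }
  set.seed(cfg$seed + 12L)
  true_dir <- ifelse(stats::runif(n) < 0.5, "up", "down")
  data.frame(entrez_id = 100000L + seq_len(n),
             gene_symbol = sprintf("SYNG%05d", seq_len(n)),
             module = module, planted = planted, true_direction = true_dir,
             stringsAsFactors = FALSE)
}

#' Simulate a block-correlated expression matrix
#'
#' Genes of module m share a latent factor: each expression row is
#' `sqrt(rho) * factor_m + sqrt(1 - rho) * noise`, giving expected pairwise
#' within-module correlation `rho` and ~0 across modules and for background
#' genes.
#'
#' @param cfg a [synthesis_config()].
#' @return numeric matrix genes x samples; rownames are universe Entrez ids,
#'   attribute `"module"` carries the module assignment.
#' @export
simulate_expression <- function(cfg) {
  uni <- synth_universe(cfg)
  n <- nrow(uni)
  set.seed(cfg$seed + 1L)
  rho <- cfg$within_module_cor
  factors <- matrix(stats::rnorm(cfg$n_modules * cfg$n_samples),
                    cfg$n_modules, cfg$n_samples)
  noise <- matrix(stats::rnorm(n * cfg$n_samples), n, cfg$n_samples)
  expr <- sqrt(1 - rho) * noise
  in_mod <- uni$module > 0
  expr[in_mod, ] <- expr[in_mod, ] + sqrt(rho) * factors[uni$module[in_mod], ]
  dimnames(expr) <- list(as.character(uni$entrez_id),
                         sprintf("S%02d", seq_len(cfg$n_samples)))
  attr(expr, "module") <- uni$module
  expr
}

#' Simulate per-study DEG tables
#'
#' Each study list mixes planted genes (present with
#' `planted_presence_prob`, direction equal to the gene's true direction
#' with probability `planted_direction_consistency`, |log2FC| > 1) with
#' uniformly drawn background genes of random direction; p-values are drawn
#' below 0.05 so every record passes the default significance filter.
#' Roughly every other study reports two comparisons, with a duplicated
#' subset of genes at different fold changes, to exercise within-study
#' merging.
#'
#' @param cfg a [synthesis_config()].
#' @param universe optional universe table from [synth_universe()].
#' @return list with `studies` (named list of raw study data.frames:
#'   `gene_symbol`, `fold_change` on the log2 scale, `p_value`,
#'   `adj_p_value`, `comparison`, `n_ms_samples`, `n_ctrl_samples`),
#'   `id_map` (symbol/Entrez table), `universe`, and `planted` (Entrez ids
#'   of the planted genes).
#' @export
simulate_studies <- function(cfg, universe = synth_universe(cfg)) {
  stopifnot(inherits(cfg, "synthesis_config"))
  set.seed(cfg$seed + 2L)
  n <- nrow(universe)
  planted_idx <- which(universe$planted)
  comparisons <- c("NAWM_vs_ctrl", "AL_vs_ctrl", "CAL_vs_ctrl")
  studies <- list()
  for (j in seq_len(cfg$n_studies)) {
    size <- sample(cfg$list_size_range[1]:cfg$list_size_range[2], 1)
    pl <- planted_idx[stats::runif(length(planted_idx)) < cfg$planted_presence_prob]
    pl <- utils::head(pl, size)
    bg <- sample(setdiff(seq_len(n), pl), max(0L, size - length(pl)))
    idx <- c(pl, bg)
    dir <- c(
      ifelse(stats::runif(length(pl)) < cfg$planted_direction_consistency,
             universe$true_direction[pl],
             ifelse(universe$true_direction[pl] == "up", "down", "up")),
      ifelse(stats::runif(length(bg)) < cfg$background_direction_split, "up", "down"))
    sgn <- ifelse(dir == "up", 1, -1)
    lfc <- sgn * stats::runif(length(idx), 1.2, 3)
    pv <- stats::runif(length(idx), 1e-6, 0.049)
    n_ms <- sample(4:16, 1)
    n_ctrl <- sample(4:16, 1)
    tab <- data.frame(gene_symbol = universe$gene_symbol[idx],
                      fold_change = lfc,
                      p_value = pv,
                      adj_p_value = pmin(1, pv * 2),
                      comparison = comparisons[(j - 1) %% 3 + 1],
                      n_ms_samples = n_ms, n_ctrl_samples = n_ctrl,
                      stringsAsFactors = FALSE)
    if (j %% 2 == 0 && nrow(tab) >= 10) {
      # second comparison repeating ~10% of the list at other fold changes
      dup <- tab[sample.int(nrow(tab), max(2L, nrow(tab) %/% 10)), , drop = FALSE]
      dup$comparison <- comparisons[j %% 3 + 1]
      dup$fold_change <- dup$fold_change * stats::runif(nrow(dup), 0.8, 1.25)
      dup$p_value <- stats::runif(nrow(dup), 1e-6, 0.049)
      dup$adj_p_value <- pmin(1, dup$p_value * 2)
      tab <- rbind(tab, dup)
    }
    studies[[sprintf("study%02d", j)]] <- tab
  }
  list(studies = studies,
       id_map = universe[, c("gene_symbol", "entrez_id")],
       universe = universe,
       planted = universe$entrez_id[universe$planted])
}

#' Simulate a STRING-style interaction edge list with planted complexes
#'
#' Dense Erdos-Renyi blocks (edge probability `ppi_intra_p`) are planted on
#' disjoint subsets of the supplied genes over a sparse background
#' (`ppi_background_p`); generated edges get combined scores in 700-990,
#' above the default confidence threshold.
#'
#' @param cfg a [synthesis_config()].
#' @param genes character vector of node identifiers; the planted complexes
#'   occupy its first `sum(ppi_complex_sizes)` entries.
#' @return list with `edges` (data.frame `node1`, `node2`,
#'   `combined_score`) and `complexes` (list of member vectors).
#' @export
simulate_ppi <- function(cfg, genes) {
  stopifnot(inherits(cfg, "synthesis_config"))
  genes <- as.character(genes)
  sizes <- cfg$ppi_complex_sizes
  if (sum(sizes) > length(genes))
    stop("not enough genes to plant the configured complexes", call. = FALSE)
  set.seed(cfg$seed + 3L)
  n <- length(genes)
  bounds <- cumsum(c(0, sizes))
  complexes <- lapply(seq_along(sizes), function(i)
    genes[(bounds[i] + 1):bounds[i + 1]])
  block <- integer(n)
  for (i in seq_along(sizes)) block[(bounds[i] + 1):bounds[i + 1]] <- i
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  intra <- block[pair_i] > 0 & block[pair_i] == block[pair_j]
  # complexes are disjoint modules: they reach the rest of the network only
  # through background nodes, never by direct complex-to-complex edges
  cross <- block[pair_i] > 0 & block[pair_j] > 0 & block[pair_i] != block[pair_j]
  p_edge <- ifelse(intra, cfg$ppi_intra_p,
                   ifelse(cross, 0, cfg$ppi_background_p))
  keep <- stats::runif(length(p_edge)) < p_edge
  edges <- data.frame(node1 = genes[pair_i[keep]],
                      node2 = genes[pair_j[keep]],
                      combined_score = sample(700:990, sum(keep), replace = TRUE),
                      stringsAsFactors = FALSE)
  list(edges = edges, complexes = complexes)
}

#' Simulate a perturbation annotation table with known truth
#'
#' Each gene is assigned a true effect (detrimental / beneficial / none) and
#' 1-3 experiments are emitted whose perturbation/outcome combinations
#' classify back to that effect under the classification truth table.
#'
#' @param cfg a [synthesis_config()].
#' @param genes character vector of gene identifiers.
#' @return list with `records` (data.frame `gene`, `perturbation`,
#'   `outcome`, `model`, `citation`) and `truth` (named character vector of
#'   true effects).
#' @export
simulate_perturbations <- function(cfg, genes) {
  stopifnot(inherits(cfg, "synthesis_config"))
  genes <- as.character(genes)
  set.seed(cfg$seed + 4L)
  truth <- stats::setNames(sample(c("detrimental", "beneficial", "none"),
                                  length(genes), replace = TRUE), genes)
  reduction <- c("knockout", "knockdown", "inhibiting_treatment")
  increase <- c("overexpression", "activating_treatment")
  rows <- lapply(genes, function(g) {
    k <- sample(1:3, 1)
    pert <- sample(c(reduction, increase), k, replace = TRUE)
    reduced <- pert %in% reduction
    out <- switch(truth[[g]],
      detrimental = ifelse(reduced, "amelioration", "exacerbation"),
      beneficial = ifelse(reduced, "exacerbation", "amelioration"),
      none = rep("no_effect", k))
    data.frame(gene = g, perturbation = pert, outcome = out,
               model = sample(c("EAE", "CREAE"), k, replace = TRUE),
               citation = sprintf("synthetic-ref-%s-%d", g, seq_len(k)),
               stringsAsFactors = FALSE)
  })
  list(records = do.call(rbind, rows), truth = truth)
}
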