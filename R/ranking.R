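#' @title Vote-count ranking across studies
#' @description Tabulate per-gene cross-study support, rank genes by the
#'   three vote-count criteria (agreeing study lists, samples in agreement,
#'   mean fold change in agreement), and summarize overlap levels.
#' @name ranking
NULL

#' Tabulate cross-study support per gene
#'
#' Each study contributes at most one record per gene (see
#' [merge_within_study()]). A gene's direction is the modal fold-change sign
#' across the study lists that report it; the agreeing subset defines
#' `n_agree`, the sample sum and the mean log2 fold change. An exact tie of
#' up and down lists makes the gene `inconsistent` with `n_agree = 0`.
#'
#' @param merged data.frame with one row per (study_id, entrez_id), carrying
#'   `log2fc`, `gene_symbol` and the per-comparison sample counts.
#' @param samples_unit `"tissues"` (default) counts tissue samples from
#'   columns `n_ms_samples`/`n_ctrl_samples`; `"donors"` uses
#'   `n_ms_donors`/`n_ctrl_donors` when a table distinguishes brain donors
#'   from tissue samples.
#' @return data.frame (one row per gene) with columns `entrez_id`,
#'   `gene_symbol`, `direction` (`up`/`down`/`inconsistent`), `n_agree`,
#'   `studies_agree` (comma-separated), `n_samples_agree`, `mean_fc_agree`,
#'   `n_total`.
#' @export
tabulate_gene_support <- function(merged, samples_unit = c("tissues", "donors")) {
  samples_unit <- match.arg(samples_unit)
  stop_if_not_df(merged, c("study_id", "entrez_id", "log2fc"), "merged")
  key <- paste(merged$study_id, merged$entrez_id)
  if (anyDuplicated(key))
    stop("input contract violated: a study lists the same gene more than once",
         call. = FALSE)
  sc <- if (samples_unit == "tissues") c("n_ms_samples", "n_ctrl_samples")
        else c("n_ms_donors", "n_ctrl_donors")
  stop_if_not_df(merged, sc, "merged")
  n_samp <- merged[[sc[1]]] + merged[[sc[2]]]

  gid <- factor(merged$entrez_id)
  up <- merged$log2fc > 0
  n_up <- as.integer(tapply(up, gid, sum))
  n_tot <- as.integer(tapply(up, gid, length))
  n_dn <- n_tot - n_up
  direction <- ifelse(n_up > n_dn, "up", ifelse(n_dn > n_up, "down", "inconsistent"))
  n_agree <- ifelse(direction == "up", n_up, ifelse(direction == "down", n_dn, 0L))

  lev <- levels(gid)
  agree_row <- (direction[as.integer(gid)] == "up" & up) |
               (direction[as.integer(gid)] == "down" & !up)
  sum_by <- function(v) {
    out <- tapply(ifelse(agree_row, v, 0), gid, sum)
    as.numeric(out)
  }
  n_samples_agree <- as.integer(sum_by(n_samp))
  mean_fc_agree <- ifelse(n_agree > 0, sum_by(merged$log2fc) / n_agree, NA_real_)
  studies_agree <- vapply(seq_along(lev), function(i) {
    rows <- which(as.integer(gid) == i & agree_row)
    paste(sort(unique(merged$study_id[rows])), collapse = ",")
  }, character(1))
  symbol <- if ("gene_symbol" %in% names(merged))
    as.character(tapply(merged$gene_symbol, gid, function(s) s[[1]]))
  else NA_character_

  data.frame(entrez_id = as.integer(lev),
             gene_symbol = symbol,
             direction = direction,
             n_agree = as.integer(n_agree),
             studies_agree = studies_agree,
             n_samples_agree = n_samples_agree,
             mean_fc_agree = mean_fc_agree,
             n_total = n_tot,
             stringsAsFactors = FALSE)
}

#' Rank genes by the vote-count criteria
#'
#' Descending lexicographic order on (1) number of agreeing study lists,
#' (2) sum of samples over the agreeing comparisons, (3) |mean log2 fold
#' change| over the agreeing comparisons; remaining ties are broken by
#' ascending Entrez id so output files are reproducible. Genes with an
#' inconsistent direction rank after all consistent genes.
#'
#' @param support output of [tabulate_gene_support()].
#' @return the same data.frame, ordered, with a `rank` column prepended.
#' @export
rank_genes <- function(support) {
  stop_if_not_df(support, c("entrez_id", "direction", "n_agree",
                            "n_samples_agree", "mean_fc_agree"), "support")
  incons <- support$direction == "inconsistent"
  fc <- abs(support$mean_fc_agree)
  fc[is.na(fc)] <- -Inf
  ord <- order(incons, -support$n_agree, -support$n_samples_agree, -fc,
               support$entrez_id)
  out <- support[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Count genes by overlap level
#'
#' Level `k` counts genes whose direction is consistent in exactly `k` study
#' lists (`n_agree = k`). `total_multi` is the number of direction-consistent
#' multi-study genes (levels >= 2); `total_multi_any` additionally includes
#' the direction-inconsistent genes, i.e. it counts genes reported in >= 2
#' lists regardless of fold-change direction, which is the quantity the
#' identity-based Monte Carlo null simulates.
#'
#' @param support output of [tabulate_gene_support()].
#' @return object of class `overlap_profile`: list with `counts_by_level`
#'   (named integer vector over observed levels), `total_multi`,
#'   `total_multi_any`, `n_inconsistent`, `n_genes`.
#' @export
count_overlap_levels <- function(support) {
  stop_if_not_df(support, c("direction", "n_agree"), "support")
  cons <- support$direction != "inconsistent"
  counts <- table(factor(support$n_agree[cons],
                         levels = seq_len(max(support$n_agree, 1))))
  counts <- stats::setNames(as.integer(counts), names(counts))
  n_inc <- sum(!cons)
  lev <- as.integer(names(counts))
  structure(list(counts_by_level = counts,
                 total_multi = sum(counts[lev >= 2]),
                 total_multi_any = sum(counts[lev >= 2]) + n_inc,
                 n_inconsistent = n_inc,
                 n_genes = nrow(support)),
            class = "overlap_profile")
}

#' @export
print.overlap_profile <- function(x, ...) {
  cat("Cross-study overlap profile\n")
  cat("  genes in union:", x$n_genes, "\n")
  cat("  direction-consistent in >=2 lists:", x$total_multi, "\n")
  cat("  reported in >=2 lists (any direction):", x$total_multi_any, "\n")
  cat("  inconsistent direction:", x$n_inconsistent, "\n")
  lev <- x$counts_by_level[x$counts_by_level > 0]
  cat("  by level:", paste(sprintf("%s:%d", names(lev), lev), collapse = "  "), "\n")
  invisible(x)
}
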