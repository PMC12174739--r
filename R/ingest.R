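#' @title DEG-list ingestion
#' @description Read, validate, filter and normalize per-study lists of
#'   differentially expressed genes (DEGs) into one canonical per-study,
#'   per-gene table keyed by Entrez identifier.
#' @name ingest
NULL

.comparison_levels <- c("NAWM_vs_ctrl", "AL_vs_ctrl", "CAL_vs_ctrl", "other")

.deg_fields <- c("gene_symbol", "entrez_id", "log2fc", "fold_change_linear",
                 "p_value", "adj_p_value", "comparison",
                 "n_ms_samples", "n_ctrl_samples")

#' Default column mapping for DEG tables
#'
#' A schema maps the canonical record fields to the column names used by a
#' particular study's table. Only `gene_symbol` plus one of `log2fc` /
#' `fold_change_linear` are mandatory.
#'
#' @param ... named overrides, e.g. `log2fc = "logFC"`, `p_value = "P.Value"`.
#' @return named character vector (canonical field -> column name).
#' @export
#' @examples
#' deg_schema(log2fc = "logFC", p_value = "P.Value")
deg_schema <- function(...) {
  schema <- stats::setNames(.deg_fields, .deg_fields)
  over <- c(...)
  if (length(over)) {
    unknown <- setdiff(names(over), .deg_fields)
    if (length(unknown))
      stop("unknown schema field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    schema[names(over)] <- over
  }
  schema
}

#' Convert a raw study table into canonical DEG records
#'
#' Fold changes are harmonized onto the log2 scale. When only a linear fold
#' change is available it is converted as `log2(x)` for `x > 0` and, for
#' sign-magnitude down-regulation reporting (`x < 0`, meaning "|x|-fold
#' down"), as `-log2(|x|)`. Rows with a non-numeric or zero fold change, or a
#' p-value outside [0, 1], are skipped and reported with their row numbers in
#' the `"skipped"` attribute.
#'
#' @param x data.frame as read from a study's supplementary table.
#' @param study_id identifier attached to every record.
#' @param schema column mapping from [deg_schema()].
#' @param fc_scale scale of the fold-change column named by `schema["log2fc"]`
#'   when both conventions could apply: `"log2"` (default) or `"linear"`.
#'   With `"linear"`, the column named by `schema["fold_change_linear"]`
#'   (or, failing that, `schema["log2fc"]`) is treated as linear.
#' @param comparison fallback comparison label used when the table has no
#'   comparison column; one of `"NAWM_vs_ctrl"`, `"AL_vs_ctrl"`,
#'   `"CAL_vs_ctrl"`, `"other"`.
#' @return data.frame of canonical records (one per retained row) with
#'   attribute `"skipped"`: a data.frame of row numbers and reasons.
#' @seealso [read_deg_table()] for the file-reading wrapper.
#' @export
as_deg_records <- function(x, study_id, schema = deg_schema(),
                           fc_scale = c("log2", "linear"),
                           comparison = "other") {
  fc_scale <- match.arg(fc_scale)
  comparison <- match.arg(comparison, .comparison_levels)
  if (!is.data.frame(x)) stop("`x` must be a data.frame", call. = FALSE)

  get_col <- function(field) {
    cn <- schema[[field]]
    if (!is.null(cn) && !is.na(cn) && cn %in% names(x)) x[[cn]] else NULL
  }

  sym <- get_col("gene_symbol")
  if (is.null(sym))
    stop(sprintf("schema error: mandatory column '%s' (gene_symbol) absent",
                 schema[["gene_symbol"]]), call. = FALSE)

  n <- nrow(x)
  num <- function(v) if (is.null(v)) rep(NA_real_, n) else suppressWarnings(as.numeric(v))

  lfc_raw <- num(get_col("log2fc"))
  lin_raw <- num(get_col("fold_change_linear"))
  if (fc_scale == "linear" && all(is.na(lin_raw))) {
    lin_raw <- lfc_raw
    lfc_raw <- rep(NA_real_, n)
  }
  pv <- num(get_col("p_value"))
  apv <- num(get_col("adj_p_value"))
  eid <- num(get_col("entrez_id"))
  nms <- num(get_col("n_ms_samples"))
  nct <- num(get_col("n_ctrl_samples"))
  cmp <- get_col("comparison")
  cmp <- if (is.null(cmp)) rep(comparison, n) else as.character(cmp)
  cmp[!(cmp %in% .comparison_levels)] <- "other"

  # sign-magnitude linear fold change -> log2: log2(x) for x > 0,
  # -log2(|x|) for x < 0 ("|x|-fold down"); x = 0 is malformed
  lin_log2 <- ifelse(is.na(lin_raw) | lin_raw == 0, NA_real_,
                     sign(lin_raw) * log2(abs(lin_raw)))
  log2fc <- ifelse(is.na(lfc_raw), lin_log2, lfc_raw)
  # retain the linear magnitude for policies filtering on the linear scale
  fc_linear <- ifelse(!is.na(lin_raw) & lin_raw != 0, abs(lin_raw),
                      ifelse(is.na(log2fc), NA_real_, 2^abs(log2fc)))

  reasons <- character(n)
  had_fc_input <- !(is.null(get_col("log2fc")) && is.null(get_col("fold_change_linear")))
  bad_fc <- is.na(log2fc)
  reasons[bad_fc] <- if (had_fc_input) "non-numeric or zero fold change" else "no fold-change column"
  bad_p <- !is.na(pv) & (pv < 0 | pv > 1)
  reasons[bad_p & reasons == ""] <- "p-value outside [0, 1]"
  bad_ap <- !is.na(apv) & (apv < 0 | apv > 1)
  reasons[bad_ap & reasons == ""] <- "adjusted p-value outside [0, 1]"
  bad_sym <- is.na(sym) | !nzchar(trimws(as.character(sym)))
  reasons[bad_sym & reasons == ""] <- "empty gene symbol"

  keep <- reasons == ""
  out <- data.frame(
    study_id = study_id,
    comparison = cmp[keep],
    gene_symbol = as.character(sym)[keep],
    entrez_id = as.integer(eid[keep]),
    log2fc = log2fc[keep],
    fold_change_linear = fc_linear[keep],
    p_value = pv[keep],
    adj_p_value = apv[keep],
    n_ms_samples = as.integer(round(ifelse(is.na(nms[keep]), 0, nms[keep]))),
    n_ctrl_samples = as.integer(round(ifelse(is.na(nct[keep]), 0, nct[keep]))),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- data.frame(row = which(!keep), reason = reasons[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' Read a delimited DEG table
#'
#' Thin wrapper around [utils::read.delim()] + [as_deg_records()].
#'
#' @inheritParams as_deg_records
#' @param path path to a delimited text file with a header row.
#' @param sep field separator (default tab).
#' @return see [as_deg_records()].
#' @export
read_deg_table <- function(path, study_id, schema = deg_schema(),
                           fc_scale = c("log2", "linear"),
                           comparison = "other", sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  as_deg_records(raw, study_id = study_id, schema = schema,
                 fc_scale = fc_scale, comparison = comparison)
}

#' Significance filter policy
#'
#' The default policy retains genes with |log2 fold change| > 1 and p < 0.05.
#' Alternative modes cover studies reporting only a linear fold-change
#' threshold (kept when linear magnitude >= `linear_fc_threshold`), only a
#' p-value threshold, or only a Benjamini-Hochberg adjusted p-value
#' threshold.
#'
#' @param mode one of `"log2fc_p"` (default), `"linear_fc_only"`,
#'   `"p_only"`, `"adj_p_only"`.
#' @param log2fc_threshold strict lower bound on |log2fc| (default 1).
#' @param p_threshold strict upper bound on the p-value (default 0.05).
#' @param linear_fc_threshold lower bound on the linear fold-change
#'   magnitude (default 2.5).
#' @param adj_p_threshold strict upper bound on the adjusted p-value
#'   (default 0.05).
#' @return object of class `filter_policy`.
#' @export
filter_policy <- function(mode = c("log2fc_p", "linear_fc_only", "p_only", "adj_p_only"),
                          log2fc_threshold = 1, p_threshold = 0.05,
                          linear_fc_threshold = 2.5, adj_p_threshold = 0.05) {
  mode <- match.arg(mode)
  thr <- c(log2fc_threshold, p_threshold, linear_fc_threshold, adj_p_threshold)
  if (any(!is.finite(thr)) || any(thr <= 0))
    stop("filter thresholds must be strictly positive", call. = FALSE)
  structure(list(mode = mode,
                 log2fc_threshold = log2fc_threshold,
                 p_threshold = p_threshold,
                 linear_fc_threshold = linear_fc_threshold,
                 adj_p_threshold = adj_p_threshold),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  rule <- switch(x$mode,
    log2fc_p = sprintf("|log2FC| > %g and p < %g", x$log2fc_threshold, x$p_threshold),
    linear_fc_only = sprintf("linear |FC| >= %g", x$linear_fc_threshold),
    p_only = sprintf("p < %g", x$p_threshold),
    adj_p_only = sprintf("adjusted p < %g", x$adj_p_threshold))
  cat("DEG significance filter:", rule, "\n")
  invisible(x)
}

#' Apply a significance filter to DEG records
#'
#' Records lacking a field the policy mode requires are excluded and counted
#' separately rather than silently kept. Filtering is idempotent.
#'
#' @param records canonical records from [as_deg_records()].
#' @param policy a [filter_policy()].
#' @return filtered data.frame with attribute `"removed"`: a list with
#'   `n_failed` (tested and rejected) and `n_missing_field` (could not be
#'   tested).
#' @export
apply_significance_filter <- function(records, policy = filter_policy()) {
  if (!inherits(policy, "filter_policy")) stop("`policy` must be a filter_policy", call. = FALSE)
  stop_if_not_df(records, c("log2fc", "p_value", "adj_p_value", "fold_change_linear"),
                 "records")
  pass <- switch(policy$mode,
    log2fc_p = list(ok = abs(records$log2fc) > policy$log2fc_threshold &
                         records$p_value < policy$p_threshold,
                    need = !is.na(records$log2fc) & !is.na(records$p_value)),
    linear_fc_only = list(ok = records$fold_change_linear >= policy$linear_fc_threshold,
                          need = !is.na(records$fold_change_linear)),
    p_only = list(ok = records$p_value < policy$p_threshold,
                  need = !is.na(records$p_value)),
    adj_p_only = list(ok = records$adj_p_value < policy$adj_p_threshold,
                      need = !is.na(records$adj_p_value)))
  keep <- pass$need & !is.na(pass$ok) & pass$ok
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- list(n_failed = sum(pass$need & !keep),
                               n_missing_field = sum(!pass$need))
  out
}

#' Gene symbol to Entrez identifier map
#'
#' @param mapping data.frame with columns `gene_symbol`, `entrez_id`, or a
#'   named integer vector (names = symbols).
#' @param manual_overrides optional mapping in the same form; overrides take
#'   precedence over `mapping`.
#' @return object of class `gene_id_map` (named integer vector).
#' @export
gene_id_map <- function(mapping, manual_overrides = NULL) {
  as_vec <- function(m) {
    if (is.null(m)) return(integer(0))
    if (is.data.frame(m)) {
      stop_if_not_df(m, c("gene_symbol", "entrez_id"), "mapping")
      stats::setNames(as.integer(m$entrez_id), as.character(m$gene_symbol))
    } else stats::setNames(as.integer(m), names(m))
  }
  base <- as_vec(mapping)
  over <- as_vec(manual_overrides)
  if (length(base) == 0 && length(over) == 0)
    stop("configuration error: empty gene identifier map", call. = FALSE)
  merged <- c(over, base[!(names(base) %in% names(over))])
  merged <- merged[!duplicated(names(merged))]
  structure(merged, class = "gene_id_map")
}

#' Read a two-column symbol/Entrez mapping table
#'
#' @param path TSV with columns `gene_symbol` and `entrez_id`.
#' @param manual_overrides see [gene_id_map()].
#' @export
read_gene_id_map <- function(path, manual_overrides = NULL) {
  gene_id_map(utils::read.delim(path, stringsAsFactors = FALSE),
              manual_overrides = manual_overrides)
}

#' Map record gene symbols to Entrez identifiers
#'
#' Every returned record carries an `entrez_id`; symbols absent from the map
#' are dropped and listed, with per-study counts, in the unmapped report.
#' Identifiers already present in the input are ignored in favour of the map
#' so one authority decides gene identity.
#'
#' @param records canonical DEG records.
#' @param idmap a [gene_id_map()].
#' @return list with `records` (mapped) and `unmapped` (data.frame of
#'   study_id, gene_symbol).
#' @export
map_gene_ids <- function(records, idmap) {
  if (!inherits(idmap, "gene_id_map")) stop("`idmap` must be a gene_id_map", call. = FALSE)
  stop_if_not_df(records, c("study_id", "gene_symbol"), "records")
  hit <- match(records$gene_symbol, names(idmap))
  mapped <- records[!is.na(hit), , drop = FALSE]
  mapped$entrez_id <- as.integer(idmap[hit[!is.na(hit)]])
  rownames(mapped) <- NULL
  unmapped <- unique(records[is.na(hit), c("study_id", "gene_symbol"), drop = FALSE])
  rownames(unmapped) <- NULL
  list(records = mapped, unmapped = unmapped)
}

#' Collapse each study to one record per gene
#'
#' Within each study, a gene reported by several comparisons keeps the record
#' with the highest |log2fc|. Ties in |log2fc| with the same sign collapse to
#' one record; ties with opposite signs are resolved by a fixed comparison
#' priority (CAL > AL > NAWM > other), flagged in `tie_flag`, and warned
#' about, so the choice is deterministic and visible.
#'
#' @param records mapped canonical records (must carry `entrez_id`).
#' @return data.frame with at most one row per (study_id, entrez_id),
#'   including `comparison` of the kept record and a logical `tie_flag`.
#' @export
merge_within_study <- function(records) {
  stop_if_not_df(records, c("study_id", "entrez_id", "log2fc", "comparison"),
                 "records")
  if (any(is.na(records$entrez_id)))
    stop("records must be id-mapped before merging (NA entrez_id found)", call. = FALSE)
  prio <- match(records$comparison,
                c("CAL_vs_ctrl", "AL_vs_ctrl", "NAWM_vs_ctrl", "other"))
  key <- paste(records$study_id, records$entrez_id, sep = "\r")
  # per key: max |log2fc|; among those, best (lowest) comparison priority
  ord <- order(key, -abs(records$log2fc), prio)
  r <- records[ord, , drop = FALSE]
  k <- key[ord]
  first <- !duplicated(k)
  # opposite-sign tie detection among the |log2fc| maxima of each key
  amax <- stats::ave(abs(r$log2fc), k, FUN = max)
  at_max <- abs(r$log2fc) == amax
  sgn_up <- stats::ave(as.numeric(at_max & r$log2fc > 0), k, FUN = max)
  sgn_dn <- stats::ave(as.numeric(at_max & r$log2fc < 0), k, FUN = max)
  tied <- (sgn_up + sgn_dn) == 2
  out <- r[first, , drop = FALSE]
  out$tie_flag <- tied[first]
  if (any(out$tie_flag))
    warning(sprintf("%d gene(s) had opposite-sign fold-change ties within a study; resolved by comparison priority CAL > AL > NAWM",
                    sum(out$tie_flag)), call. = FALSE)
  rownames(out) <- NULL
  out[order(out$study_id, out$entrez_id), , drop = FALSE]
}
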