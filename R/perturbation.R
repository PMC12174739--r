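#' @title In-vivo perturbation evidence
#' @description Classify annotated perturbation experiments in EAE/CREAE
#'   models into detrimental / beneficial / no-effect evidence per gene and
#'   tally the net direction of evidence.
#' @name perturbation
NULL

.reduction <- c("knockout", "knockdown", "inhibiting_treatment")
.increase <- c("overexpression", "activating_treatment")
.outcomes <- c("amelioration", "exacerbation", "no_effect")

#' Classify one or more perturbation experiments
#'
#' A gene is evidence of a detrimental role when reducing its activity
#' (knockout, knockdown, inhibiting treatment) ameliorates the disease
#' model, or increasing it (overexpression, activating treatment)
#' exacerbates it; the reverse combinations are evidence of a beneficial
#' role; experiments with no effect on the model classify as `no_effect`.
#'
#' @param perturbation character vector over `knockout`, `knockdown`,
#'   `inhibiting_treatment`, `overexpression`, `activating_treatment`.
#' @param outcome character vector over `amelioration`, `exacerbation`,
#'   `no_effect`.
#' @return character vector over `detrimental`, `beneficial`, `no_effect`.
#' @export
#' @examples
#' classify_perturbation("knockout", "amelioration")       # detrimental
#' classify_perturbation("overexpression", "amelioration") # beneficial
classify_perturbation <- function(perturbation, outcome) {
  perturbation <- as.character(perturbation)
  outcome <- as.character(outcome)
  bad_p <- !(perturbation %in% c(.reduction, .increase))
  bad_o <- !(outcome %in% .outcomes)
  if (any(bad_p | bad_o))
    stop("invalid perturbation/outcome value(s): ",
         paste(unique(c(perturbation[bad_p], outcome[bad_o])), collapse = ", "),
         call. = FALSE)
  reduced <- perturbation %in% .reduction
  ifelse(outcome == "no_effect", "no_effect",
         ifelse((reduced & outcome == "amelioration") |
                (!reduced & outcome == "exacerbation"),
                "detrimental", "beneficial"))
}

#' Tally perturbation evidence per gene
#'
#' @param records data.frame with columns `gene`, `perturbation`, `outcome`
#'   (one row per experiment).
#' @return data.frame with one row per gene: counts of detrimental,
#'   beneficial and no-effect experiments and a `net` label (`detrimental`,
#'   `beneficial`, `mixed` when both directions are present in equal number,
#'   `none` when only no-effect evidence exists).
#' @export
tally_gene_effects <- function(records) {
  stop_if_not_df(records, c("gene", "perturbation", "outcome"), "records")
  eff <- classify_perturbation(records$perturbation, records$outcome)
  gid <- factor(records$gene)
  cnt <- function(label) as.integer(tapply(eff == label, gid, sum))
  nd <- cnt("detrimental"); nb <- cnt("beneficial"); nn <- cnt("no_effect")
  net <- ifelse(nd > nb, "detrimental",
                ifelse(nb > nd, "beneficial",
                       ifelse(nd > 0, "mixed", "none")))
  data.frame(gene = levels(gid),
             n_detrimental = nd, n_beneficial = nb, n_no_effect = nn,
             net = net, stringsAsFactors = FALSE)
}
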