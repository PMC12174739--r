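# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_df <- function(x, cols, what = deparse(substitute(x))) {
  if (!is.data.frame(x)) stop(sprintf("`%s` must be a data.frame", what), call. = FALSE)
  missing <- setdiff(cols, names(x))
  if (length(missing))
    stop(sprintf("`%s` lacks required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' Weighted sampling without replacement
#'
#' Draws `size` distinct indices from `1:n` with inclusion driven by
#' successive draws proportional to `weights` (renormalized after each draw).
#' Implemented with exponential keys: the `size` smallest values of
#' `Exp(1)/w_i` identify exactly the indices a sequential renormalized-draw
#' scheme would select, at O(n log n) instead of O(n * size).
#'
#' @param n universe size.
#' @param size number of draws (<= n).
#' @param weights strictly positive finite weights of length `n`, or `NULL`
#'   for uniform sampling.
#' @return integer vector of `size` distinct indices in `1:n`.
#' @keywords internal
#' @noRd
weighted_sample_int <- function(n, size, weights = NULL) {
  if (size > n) stop("sample size exceeds universe size", call. = FALSE)
  if (is.null(weights)) return(sample.int(n, size))
  keys <- stats::rexp(n) / weights
  order(keys)[seq_len(size)]
}
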