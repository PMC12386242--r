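`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate fn() under `seed` without disturbing the caller's RNG stream;
## seed = NULL means "use the current stream as-is".
eval_with_seed <- function(seed, fn) {
  if (is.null(seed) || (length(seed) == 1L && is.na(seed))) fn()
  else withr::with_seed(as.integer(seed), fn())
}

## Probabilities live on [0, prob_ceiling]; the ceiling keeps logits finite.
clip_prob <- function(p, upper = 0.95) pmin(pmax(p, 0), upper)

is_count <- function(x) {
  is.numeric(x) & !is.na(x) & x >= 0 & x == round(x)
}

#' Format a percentage the way report tables print it
#'
#' One decimal place, e.g. `"17.9%"`.
#'
#' @param x numeric vector of percentages (already on the 0-100 scale).
#' @return character vector.
#' @export
format_percent <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.1f%%", x))
}

#' Format a permutation p-value for reporting
#'
#' Four decimal places with a `"<0.0001"` floor.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p)))
}
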