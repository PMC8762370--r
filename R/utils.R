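#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL

## Internal helpers shared across modules.

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

is_count_vector <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x == floor(x))
}

#' Derive a reproducible child seed from a master seed and a key
#'
#' All stochastic operations in the package draw their random numbers from
#' streams keyed by a master seed plus a textual key (a sample identifier, a
#' scenario label, ...). This makes every component independently
#' reproducible: adding samples or scenarios never perturbs the draws of the
#' existing ones.
#'
#' @param seed master integer seed.
#' @param ... character or numeric key components identifying the stream.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "reads", "s01")
derive_seed <- function(seed, ...) {
  abort_if(!is.numeric(seed) || length(seed) != 1 || is.na(seed),
           "`seed` must be a single integer")
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "\r")
  codes <- utf8ToInt(key)
  h <- 0
  m <- 2147483647  # 2^31 - 1, keeps the result a valid 32-bit seed
  for (code in codes) h <- (h * 31 + code) %% m
  as.integer(h)
}

## Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Explicit marker for estimator values that are undefined on the input
## (e.g. ACE when every rare read is a singleton). NA_real_ carrying the
## reason, so downstream summaries can distinguish "undefined" from "missing".
undefined_value <- function(reason) {
  structure(NA_real_, reason = reason, class = c("undefined_value", "numeric"))
}

#' Test whether a value is an undefined-estimator marker
#'
#' @param x value returned by an estimator such as [ace()] or [margalef()].
#' @return `TRUE` if the estimator was undefined on its input.
#' @export
is_undefined <- function(x) inherits(x, "undefined_value")

#' @export
print.undefined_value <- function(x, ...) {
  cat("<undefined: ", attr(x, "reason"), ">\n", sep = "")
  invisible(x)
}
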