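#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variant classes treated as nonsynonymous coding changes
#'
#' The classes counted in the mutation landscape and in tumor mutational
#' burden: missense and nonsense substitutions, frameshift and in-frame
#' indels, and splice-site changes.  Synonymous and "other" calls are
#' excluded.
#' @export
NONSYNONYMOUS_CLASSES <- c(
  "missense", "nonsense", "frameshift_indel", "inframe_indel", "splice"
)

#' All recognised variant classes
#' @export
VARIANT_CLASSES <- c(NONSYNONYMOUS_CLASSES, "synonymous", "other")

## Deterministic per-component seed derived from a root seed, so that
## adding a simulation component does not perturb the streams of the
## existing ones.  FNV-style string hash folded with the root seed,
## kept strictly below 2^31 - 1.
derive_seed <- function(seed, component) {
  stopifnot(is.character(component), length(component) == 1L)
  h <- 2166136261
  for (code in utf8ToInt(component)) {
    h <- (h * 16777619) %% 2147483629
    h <- (h + code) %% 2147483629
  }
  as.integer((h + (as.numeric(seed) %% 2147483629) * 2654435761) %% 2147483629)
}

## Run `expr` under a local RNG stream seeded with `seed`, restoring the
## caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_format <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop_format("'%s' must be a probability in [0, 1]", name)
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0))
    stop_format("'%s' must be > 0", name)
  invisible(x)
}
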