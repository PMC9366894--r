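#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed
#'
#' A single integer seed is expanded into independent per-component
#' sub-streams (placement, rendering noise, trace noise, ...) so that adding
#' draws to one component never perturbs another. The derivation is a simple
#' multiplicative hash of the component label, kept below 2^31.
#'
#' @param seed master integer seed.
#' @param component character label of the consuming component.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(component)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# all(x is whole number)
is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
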