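#' @keywords internal
"_PACKAGE"

## Internal assertion helpers. All user-facing errors go through these so the
## messages stay uniform.

stop_glym <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_glym(...)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Run `expr` under a fixed RNG state, restoring the caller's stream.
## Generators must be pure functions of their spec (seed included), so they
## must not consume or disturb the global RNG.
with_seed <- function(seed, expr) {
  assert_that(is_scalar_number(seed), "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## A run manifest: a list of stage entries (stage name, parameters, input
## digests) serialisable to JSON. Every pipeline stage appends to it so a run
## can be audited and re-executed.
new_manifest <- function() {
  structure(list(created = "run", stages = list()), class = "glym_manifest")
}

manifest_add <- function(manifest, stage, params = list(), inputs = list()) {
  if (is.null(manifest)) return(NULL)
  entry <- list(stage = stage, params = params, inputs = inputs)
  manifest$stages[[length(manifest$stages) + 1L]] <- entry
  manifest
}

## Stable digest of numeric content without external dependencies: a short
## fingerprint from the serialised object.
content_digest <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  v <- as.double(raw)
  w <- (seq_along(v) - 1) %% 9973 + 1
  h <- (sum(v * w) + 7919 * length(v)) %% 281474976710655
  sprintf("%012.0f", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
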