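# Internal utilities: seeded evaluation, seed derivation, config hashing.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a base seed and indices
#'
#' Implements the documented counter scheme used throughout the package: every
#' source of randomness (down-sampling, splits, search, permutations) draws its
#' seed from the analysis base seed combined with its position in the workflow,
#' so no global RNG state is shared between stages.
#'
#' @param base integer base seed.
#' @param ... integer indices (stage, run index, permutation index, ...). The
#'   last argument may be a vector, in which case a vector of seeds is
#'   returned.
#' @return integer seed(s) in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(42, 1, 1:3)
#' @export
derive_seed <- function(base, ...) {
  idx <- list(...)
  h <- as.numeric(base) %% 2147483647
  if (length(idx) == 0L) return(as.integer(h %% 2147483646 + 1))
  scalars <- idx[-length(idx)]
  last <- idx[[length(idx)]]
  for (v in scalars) h <- (h * 48271 + as.numeric(v)) %% 2147483647
  out <- vapply(as.numeric(last), function(v) {
    (h * 48271 + v) %% 2147483647
  }, numeric(1))
  as.integer(out %% 2147483646 + 1)
}

# Recursively sort list names so hashing is stable under key reordering.
canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x)))) {
      x <- x[order(names(x))]
    }
    lapply(x, canonicalize)
  } else x
}

#' Hash a configuration object
#'
#' Produces a stable MD5 hex digest of any (non-environment, non-function)
#' configuration list. Names are sorted recursively first, so the hash is
#' invariant under key reordering. Used to guarantee that the observed and
#' permutation-null arms of an analysis ran under identical settings.
#'
#' @param x a list of configuration values (functions and environments are
#'   dropped before hashing, since their serialization is not stable).
#' @return a 32-character hex string.
#' @export
config_hash <- function(x) {
  strip <- function(z) {
    if (is.function(z) || is.environment(z)) return(NULL)
    if (is.list(z)) {
      z <- lapply(z, strip)
      z[vapply(z, is.null, logical(1))] <- NULL
    }
    z
  }
  x <- canonicalize(strip(x))
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                          force = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(txt), tf)
  unname(tools::md5sum(tf))
}

# Shared input checks ---------------------------------------------------------

assert_dosage_matrix <- function(G) {
  if (!is.matrix(G) || !is.numeric(G))
    stop("genotypes must be a numeric samples x SNPs matrix", call. = FALSE)
  if (is.null(colnames(G)))
    stop("genotype matrix must carry SNP ids as column names", call. = FALSE)
  invisible(G)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
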