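# Internal utilities: deterministic seed derivation and small IO helpers.

#' Derive a reproducible substream seed from a base seed and a key
#'
#' Mixes a base integer seed with an arbitrary character key through a
#' polynomial rolling hash modulo 2^31 - 1, so per-record random substreams
#' (e.g. one per SNV) do not depend on row order and never exceed the 32-bit
#' integer range R's RNG accepts.
#'
#' @param seed Integer base seed.
#' @param ... Key components (coerced to character and concatenated).
#' @return A single integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "|")
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed %% m)
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards (so library internals never perturb user streams).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

read_tsv_strict <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(dt))
    if (length(missing))
      stop("file ", path, " is missing required column(s): ",
           paste(missing, collapse = ", "))
  }
  dt
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
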