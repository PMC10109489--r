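# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their `seed` argument and never disturb the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a over a character scalar; cheap content hash for provenance records.
# Returns an 8-hex-digit string. Not cryptographic; collision resistance is
# not needed, only a stable fingerprint of the configuration.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  xor32 <- function(a, b)
    bitwXor(a %% 65536, b %% 65536) +
    bitwXor(a %/% 65536, b %/% 65536) * 65536
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    # 32-bit modular multiply by the FNV prime 16777619, done in two halves
    # to stay inside double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# stable TSV writer: fixed col ordering, no quoting surprises, "." decimal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
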