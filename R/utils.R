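#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Mixes a master seed with an arbitrary sequence of tags (stage names,
#' chromosome names, replicate indices) into a 31-bit integer seed, so that
#' each randomized step of a run draws from its own deterministic stream and
#' partial regeneration is stable: regenerating one chromosome or one stage
#' never perturbs another.
#'
#' @param seed Integer master seed.
#' @param ... Tags (coerced to character) identifying the consumer.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' mixSeed(1, "sites", "chr1") != mixSeed(1, "sites", "chr2")
#' @export
mixSeed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  h <- abs(as.double(seed)) %% m
  for (part in as.character(unlist(list(...), use.names = FALSE))) {
    for (v in utf8ToInt(part)) h <- (h * 31 + v) %% m
  }
  as.integer(h)
}

# Evaluate expr under set.seed(seed), restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Write a data.frame as a plain TSV (no quoting, no row names).
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
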