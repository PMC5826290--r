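# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# deterministic child seed; stays below 2^31 - 1
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 2147483647L + 104729L * (as.integer(k) %% 20011L)) %%
    2147483647L
}

chrom_levels <- function(map) names(attr(map, "chrom_lengths"))

region_name <- function(chrom, start, end) {
  sprintf("%s:%d-%d", as.character(chrom), as.integer(start), as.integer(end))
}

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("catada_validation_error", "error",
                                "condition")))
}

is_validation_error <- function(e) inherits(e, "catada_validation_error")
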