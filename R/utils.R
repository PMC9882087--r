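#' @importFrom stats pnorm phyper rnorm rgamma sd cor p.adjust
#' @importFrom utils read.delim write.table
NULL

# Run `expr` under a fixed RNG seed and restore the caller's RNG state.
# Every stochastic operation in the package routes through this, so results
# are pure functions of their (input, seed) arguments and never perturb the
# user's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Zero-padded integer labels: gene_0001 style, stable under lexicographic sort.
padded_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(1L, nchar(as.character(n))), seq_len(n))
}

stop_modproj <- function(..., class) {
  stop(structure(
    class = c(class, "modproj_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_modproj(sprintf("`%s` must be a single integer >= %d", name, min),
                 class = "modproj_invalid_scenario")
  }
  as.integer(x)
}
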