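#' Derive a child seed from a master seed and a purpose label
#'
#' Every random operation in the package draws its seed from the single
#' top-level run seed through this function, keyed by a named purpose, so
#' adding a pipeline stage never perturbs the random stream of another.
#'
#' @param seed Master integer seed.
#' @param purpose Character label identifying the consumer of the stream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(purpose))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(abs(seed)) %% m
  for (code in utf8ToInt(purpose)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# Length of the intersection of [a1, a2) with [b1, b2); 0 when disjoint.
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}

# Total length of the union of half-open intervals given as a two-column
# matrix / data.frame of (start, stop).
interval_union_length <- function(start, stop) {
  if (length(start) == 0) {
    return(0)
  }
  o <- order(start, stop)
  start <- start[o]
  stop <- stop[o]
  total <- 0
  cur_s <- start[1]
  cur_e <- stop[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]
      cur_e <- stop[i]
    } else {
      cur_e <- max(cur_e, stop[i])
    }
  }
  total + (cur_e - cur_s)
}
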