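# Seed plumbing shared by all generators.
#
# A single user-facing seed fans out to per-component child seeds through
# a fixed arithmetic derivation, so adding a new generator never perturbs
# the streams of existing ones. All helpers restore the caller's RNG
# state on exit.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a component seed from a master seed
#'
#' Deterministic derivation (master seed and a component tag hashed into
#' 0..2^31-2) used so that one run-level seed yields independent,
#' reproducible streams for population sampling, antigen generation,
#' binding tables and trial noise.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the component (and, optionally, an
#'   index such as a replicate number appended by the caller).
#' @return an integer seed.
#' @export
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) *
             (seq_len(nchar(as.character(tag))) %% 97 + 1))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483629)
}
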