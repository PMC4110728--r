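# Shared internal helpers: condition constructors, seeded evaluation,
# canonical chromosome ordering.

svb_error <- function(msg, class) {
  structure(
    class = c(class, "svb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
}

stop_missing_file <- function(path) {
  stop(svb_error(paste0("input file not found: ", path), "svb_missing_file"))
}

stop_format <- function(...) {
  stop(svb_error(paste0(...), "svb_format_error"))
}

stop_param <- function(...) {
  stop(svb_error(paste0(...), "svb_param_error"))
}

stop_empty_input <- function(...) {
  stop(svb_error(paste0(...), "svb_empty_input"))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the previous
#' global RNG state afterwards, so seeded package operations do not perturb
#' the caller's random number stream. With `seed = NULL` the expression is
#' evaluated against the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Canonical chromosome rank: position in the sequence dictionary when known,
# lexicographic fallback for names outside it.
chrom_rank <- function(chrom, seqlevels) {
  chrom <- as.character(chrom)
  if (is.null(seqlevels)) seqlevels <- character(0)
  extra <- sort(setdiff(unique(chrom), seqlevels))
  match(chrom, c(seqlevels, extra))
}

# Deterministic union of sequence dictionaries.
merge_seqlevels <- function(a, b) {
  c(a, sort(setdiff(b, a)))
}
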