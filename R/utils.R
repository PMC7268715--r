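# internal helpers

# Run code with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# Coerce sequence input (DNAStringSet, named/unnamed character) to a named
# character vector of upper-case residues.
as_seq_chr <- function(x, default_prefix = "seq") {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    if (is.null(names(out)) && length(out))
      names(out) <- paste0(default_prefix, seq_along(out))
    return(toupper(out))
  }
  if (is.character(x)) {
    out <- toupper(x)
    if ((is.null(names(out)) || any(!nzchar(names(out)))) && length(out))
      names(out) <- paste0(default_prefix, seq_along(out))
    return(out)
  }
  stop("expected a DNAStringSet or a character vector of sequences",
       call. = FALSE)
}

is_acgt <- function(s) !grepl("[^ACGT]", s)

stopifnot_scalar_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("%s must be TRUE or FALSE", what), call. = FALSE)
}
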