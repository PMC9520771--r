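# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Quiet progress/diagnostic messages, silenced unless options(dcsp.verbose).
dcsp_log <- function(...) {
  if (isTRUE(getOption("dcsp.verbose", FALSE))) {
    message("[dcsp] ", ...)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Check a data.frame has the given columns, with a readable error.
need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
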