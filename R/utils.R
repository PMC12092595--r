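`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
# Every stochastic routine in the package takes an explicit seed and wraps
# its draws in this, so generators have independent streams.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Minimal leveled logging; controlled by options(isgtkit.log_level=).
# Levels: debug < info < warn. Warnings always go through warning().
isgt_log <- function(msg, level = c("info", "debug")) {
  level <- match.arg(level)
  opt <- getOption("isgtkit.log_level", "info")
  show <- switch(opt, debug = TRUE, info = level == "info", warn = FALSE, TRUE)
  if (isTRUE(show)) message("[isgtkit] ", msg)
  invisible(NULL)
}

stop_ <- function(...) stop(..., call. = FALSE)

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_(what, " is missing required column(s): ",
          paste(missing, collapse = ", "))
  }
  invisible(df)
}
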