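# Error conditions used across the package. Three classes:
#   octamorph_validation_error  -- bad arguments / malformed inputs
#   octamorph_io_error          -- unreadable or unwritable files
#   octamorph_undefined_marker  -- a biomarker that has no value on this input
stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("octamorph_validation_error", "octamorph_error", "error")))
}

stop_io <- function(msg) {
  stop(errorCondition(msg, class = c("octamorph_io_error", "octamorph_error", "error")))
}

stop_undefined <- function(msg) {
  stop(errorCondition(msg, class = c("octamorph_undefined_marker", "octamorph_error", "error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Default physical pixel pitch of a 3 x 3 mm en face scan sampled on a
# 304 x 304 grid.
DEFAULT_PIXEL_SCALE_MM <- 3 / 304
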