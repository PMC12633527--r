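#' @importFrom rlang abort
#' @keywords internal
nm_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "nervemap_error"), ...)
}

# Per-purpose random streams derived from one master seed, so that e.g.
# adding fibers never perturbs fascicle placement.
stream_offsets <- c(
  placement = 11L, diameters = 23L, orientation = 37L, warp = 51L,
  fibers = 67L, trace = 83L, schedule = 97L
)

#' Run code under a purpose-specific random stream
#'
#' Derives a deterministic sub-seed from a master seed and a purpose label,
#' evaluates `expr` with that seed, and restores the caller's RNG state.
#' @keywords internal
with_stream <- function(seed, purpose, expr) {
  off <- stream_offsets[[purpose]]
  sub <- (as.double(seed) * 1009L + off * 9973L) %% 2147483629
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(sub))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (strict && x <= min) || (!strict && x < min)) {
    nm_abort("INVALID_ARGUMENT", sprintf(
      "`%s` must be a finite scalar %s %s", name,
      if (strict) ">" else ">=", format(min)
    ))
  }
  invisible(x)
}
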