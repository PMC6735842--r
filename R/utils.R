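# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_seedspan <- function(msg, class) {
  stop(structure(
    class = c(class, "seedspan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_seedspan(sprintf("`%s` must be finite and > 0", name),
                  "seedspan_invalid_input")
  }
  invisible(x)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# extdata accessor (also used by tests and the acceptance script)

#' Path to a packaged example data file
#'
#' @param file File name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return A file path (or a character vector of file names).
#' @export
seedspan_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "seedspan")))
  }
  path <- system.file("extdata", file, package = "seedspan")
  if (!nzchar(path)) {
    stop_seedspan(sprintf("no packaged file '%s'", file), "seedspan_io_error")
  }
  path
}
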