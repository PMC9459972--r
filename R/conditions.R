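#' @keywords internal
#' @noRd
fs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "facesym_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

fs_stop_validation <- function(msg) fs_stop(msg, "facesym_validation_error")
fs_stop_format     <- function(msg) fs_stop(msg, "facesym_format_error")
fs_stop_io         <- function(msg) fs_stop(msg, "facesym_io_error")
fs_stop_degenerate <- function(msg) fs_stop(msg, "facesym_degenerate_error")

#' @noRd
fs_warn <- function(msg) {
  warning(structure(
    class = c("facesym_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
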