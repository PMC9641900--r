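#' @useDynLib cervimotion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Classed errors so callers can test for specific failure modes with
# tryCatch(..., MissingLandmark = ...) instead of matching message text.
cmStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cervimotionError", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

cmAssert <- function(cond, class, msg) {
  if (!isTRUE(cond)) cmStop(class, msg)
  invisible(TRUE)
}

# Deterministic sub-seed derivation: keeps every stream reproducible from one
# user-facing seed while staying inside the 32-bit integer range.
deriveSeed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt) %% 2147483647L)
}
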