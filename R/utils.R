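# Internal helpers shared across modules.

# Derive a child seed from a root seed and a counter, staying well inside
# the 32-bit integer range so set.seed() never overflows.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 1000003 + 1) * 1009 + counter) %% 2147483647L
}

stop_icclust <- function(..., class = "icclust_error") {
  stop(structure(
    class = c(class, "icclust_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Symmetrize a square matrix to remove floating-point asymmetry.
symmetrize <- function(m) (m + t(m)) / 2

check_square_symmetric <- function(m, name = "matrix", tol = 1e-9) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_icclust(name, " must be a numeric matrix", class = "icclust_validation_error")
  }
  if (nrow(m) != ncol(m)) {
    stop_icclust(name, " must be square", class = "icclust_validation_error")
  }
  if (max(abs(m - t(m))) > tol) {
    stop_icclust(name, " must be symmetric (tolerance ", tol, ")",
                 class = "icclust_validation_error")
  }
  invisible(TRUE)
}
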