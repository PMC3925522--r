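# Classed error conditions so callers and tests can distinguish failure
# modes without matching on message text.

stop_quadzone <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "quadzone_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

check_point3 <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3L || !all(is.finite(x))) {
    stop_quadzone("quadzone_invalid_argument",
                  sprintf("%s must be a finite numeric 3-vector", what))
  }
  as.numeric(x)
}

as_point_matrix <- function(x, what = "points") {
  if (is.null(dim(x))) {
    x <- matrix(check_point3(x, what), ncol = 3L)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L || !all(is.finite(x))) {
    stop_quadzone("quadzone_invalid_argument",
                  sprintf("%s must be an n x 3 matrix of finite coordinates", what))
  }
  dimnames(x) <- NULL
  x
}
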