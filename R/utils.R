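#' @importFrom rlang %||% abort warn
NULL

# stop with a consistent error class so callers can test on it
plaq_abort <- function(msg, class = "plaqomics_error") {
  rlang::abort(msg, class = class)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) plaq_abort(msg)
  invisible(TRUE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_prop <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# run a block with a local RNG state so generators are pure in (config, seed)
with_seed <- function(seed, code) {
  assert_that(is_count(seed), "`seed` must be a single non-negative integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# lower-triangular Cholesky sampling of multivariate normal with unit variances
rmvnorm_chol <- function(n, corr) {
  p <- ncol(corr)
  l <- tryCatch(chol(corr), error = function(e) {
    plaq_abort("correlation matrix is not positive definite")
  })
  z <- matrix(stats::rnorm(n * p), nrow = n)
  z %*% l
}

check_correlation_matrix <- function(r) {
  assert_that(is.matrix(r) && nrow(r) == ncol(r), "correlation matrix must be square")
  assert_that(max(abs(r - t(r))) < 1e-8, "correlation matrix must be symmetric")
  assert_that(max(abs(diag(r) - 1)) < 1e-8, "correlation matrix must have unit diagonal")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > 1e-10, "correlation matrix must be positive definite")
  invisible(r)
}
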