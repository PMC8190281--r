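# Internal numerical and plumbing helpers shared across modules.

#' Dense matrix exponential
#'
#' Thin wrapper around [Matrix::expm()] returning a base matrix.
#'
#' @param x square numeric matrix
#' @return base matrix e^x
#' @keywords internal
#' @noRd
expm_mat <- function(x) {
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  as.matrix(Matrix::expm(Matrix::Matrix(x, sparse = FALSE)))
}

#' Composite trapezoid quadrature on a uniform grid
#'
#' @param y values on the grid (vector) or one column per grid point (matrix,
#'   integrated row-wise)
#' @param dt grid spacing
#' @keywords internal
#' @noRd
trapz <- function(y, dt) {
  if (is.matrix(y)) {
    k <- ncol(y)
    dt * (rowSums(y) - 0.5 * (y[, 1L] + y[, k]))
  } else {
    k <- length(y)
    dt * (sum(y) - 0.5 * (y[1L] + y[k]))
  }
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards so that package functions do not clobber user seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic named substream seed derived from a master seed.
# Keeps results reproducible per module while remaining inside 32-bit range.
seed_substream <- function(master, name, index = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(master) * 7919 + h * 131 + index) %% 2147483562L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ctl_log <- function(...) {
  message("[netctl] ", ...)
}
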