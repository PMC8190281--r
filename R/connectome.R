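# Structural connectome container, IO, group averaging, and stabilization
# into a continuous-time dynamics matrix.

#' Construct a structural connectome
#'
#' A connectome is a weighted, undirected, self-loop-free graph over `n`
#' brain regions, stored as a dense symmetric matrix of nonnegative weights
#' (fractional-anisotropy-like, dimensionless). This is the `A` of the linear
#' model before stabilization.
#'
#' @param weights n x n numeric matrix; symmetric (within `1e-10`), entries
#'   `>= 0`, zero diagonal.
#' @param labels character vector of `n` unique region identifiers. Defaults
#'   to `"R001"..` style names.
#' @return An object of class `connectome` with fields `weights`, `labels`,
#'   `n`.
#' @examples
#' w <- matrix(c(0, .4, .2, .4, 0, .1, .2, .1, 0), 3)
#' cn <- connectome(w)
#' cn$n
#' @export
connectome <- function(weights, labels = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("weights must be a numeric matrix")
  }
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (n < 2L) stop("a connectome needs at least 2 regions")
  if (anyNA(weights) || any(!is.finite(weights))) stop("NaN or non-finite weight entries")
  if (any(weights < 0)) stop("negative weight entries are not allowed")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-10) {
    stop(sprintf("weights not symmetric (max asymmetry %.3g)", asym))
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) stop("diagonal must be zero (no self-loops)")
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length must equal n")
  if (anyDuplicated(labels)) stop("labels must be unique")
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels, n = n),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<connectome> %d regions, %d edges, mean weight %.4g\n",
              x$n, nz, mean(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

#' Read a structural connectome from a dense delimited file
#'
#' Accepts a dense numeric matrix with an optional header row and/or first
#' column of region labels (auto-detected). Sub-tolerance asymmetries
#' (`< 1e-8`, file-precision noise) are symmetrized by `(W + t(W))/2`;
#' larger asymmetries are an error. A nonzero diagonal is zeroed with a
#' warning, since FA between a region and itself is undefined.
#'
#' @param path path to a delimited text file.
#' @param delimiter field separator, default `","`.
#' @return A [connectome()].
#' @export
load_connectome <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), delimiter, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first[-1L])))) ||
    (length(first) > 1L && is.na(suppressWarnings(as.numeric(first[2L]))))
  tab <- utils::read.table(path, sep = delimiter, header = has_header,
                           check.names = FALSE, stringsAsFactors = FALSE)
  labels <- NULL
  first_col_numeric <- is.numeric(tab[[1L]])
  if (!first_col_numeric) {
    labels <- as.character(tab[[1L]])
    tab <- tab[, -1L, drop = FALSE]
  } else if (has_header) {
    labels <- colnames(tab)
  }
  w <- as.matrix(tab)
  if (!is.numeric(w)) stop("non-numeric entries in connectome file: ", path)
  if (nrow(w) != ncol(w)) {
    stop(sprintf("non-square matrix (%d x %d) in %s", nrow(w), ncol(w), path))
  }
  if (anyNA(w)) stop("NaN entries in connectome file: ", path)
  if (any(w < 0)) stop("negative weight in connectome file: ", path)
  asym <- max(abs(w - t(w)))
  if (asym >= 1e-8) {
    stop(sprintf("asymmetry %.3g exceeds tolerance 1e-8 in %s", asym, path))
  }
  w <- (w + t(w)) / 2
  if (any(diag(w) != 0)) {
    warning("nonzero diagonal zeroed in ", path)
    diag(w) <- 0
  }
  connectome(w, labels = labels)
}

#' Write a connectome to a dense delimited file
#'
#' Writes full double precision (`%.17g`) so that write/read round-trips are
#' lossless; a header row and first column carry the region labels.
#'
#' @param x a [connectome()].
#' @param path output file path.
#' @param delimiter field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path, delimiter = ",") {
  stopifnot(inherits(x, "connectome"))
  header <- paste(c("region", x$labels), collapse = delimiter)
  rows <- vapply(seq_len(x$n), function(i) {
    paste(c(x$labels[i], sprintf("%.17g", x$weights[i, ])), collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Link-wise average of a set of connectomes
#'
#' Element-wise arithmetic mean of the weight matrices, used to build a
#' group-averaged connectome when per-subject diffusion data are unavailable.
#'
#' @param connectomes non-empty list of [connectome()] objects sharing
#'   dimension and labels.
#' @return A [connectome()] holding the mean weights.
#' @export
average_connectomes <- function(connectomes) {
  if (length(connectomes) == 0L) stop("empty connectome list")
  stopifnot(all(vapply(connectomes, inherits, logical(1), "connectome")))
  ref <- connectomes[[1L]]
  for (cn in connectomes[-1L]) {
    if (cn$n != ref$n || !identical(cn$labels, ref$labels)) {
      stop("connectomes differ in dimension or labels")
    }
  }
  w <- Reduce(`+`, lapply(connectomes, `[[`, "weights")) / length(connectomes)
  connectome(w, labels = ref$labels)
}

#' Stabilize a connectome into a continuous-time dynamics matrix
#'
#' Raw nonnegative symmetric weights give an unstable linear system; a
#' normalization is required before the weights can serve as the state matrix
#' of `dx/dt = A x + B u`. The default `"spectral"` scheme is the convention
#' of the continuous-time network-control literature,
#' `A = W / (lambda_max(W) + 1) - I`, which is strictly stable for any
#' nonnegative symmetric `W` (all eigenvalues in `[-1 - 1/(lambda_max + 1),
#' -1/(lambda_max + 1)]`). The `"scaled"` scheme divides by
#' `lambda_max + 1` and subtracts `c * I` with configurable `c`.
#'
#' @param x a [connectome()].
#' @param scheme `"spectral"` (default) or `"scaled"`.
#' @param c_shift diagonal shift for the `"scaled"` scheme (default 1).
#' @return An object of class `system_matrix` with fields `A`,
#'   `spectral_bound` (largest real part of the eigenvalues of `A`),
#'   `normalization`, `labels`, `n`.
#' @export
stabilize <- function(x, scheme = c("spectral", "scaled"), c_shift = 1) {
  stopifnot(inherits(x, "connectome"))
  scheme <- match.arg(scheme)
  ev <- eigen(x$weights, symmetric = TRUE, only.values = TRUE)$values
  lam_max <- max(ev)
  w_scaled <- x$weights / (lam_max + 1)
  if (scheme == "spectral") {
    A <- w_scaled - diag(x$n)
    tag <- "spectral: W/(lambda_max+1) - I"
  } else {
    A <- w_scaled - c_shift * diag(x$n)
    tag <- sprintf("scaled: W/(lambda_max+1) - %.6g*I", c_shift)
  }
  bound <- max(ev / (lam_max + 1)) - if (scheme == "spectral") 1 else c_shift
  if (bound >= 0) {
    stop(sprintf("scheme '%s' does not stabilize (spectral bound %.3g >= 0); increase c_shift",
                 scheme, bound))
  }
  structure(list(A = A, spectral_bound = bound, normalization = tag,
                 labels = x$labels, n = x$n),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("<system_matrix> n=%d, spectral bound %.4g, %s\n",
              x$n, x$spectral_bound, x$normalization))
  invisible(x)
}

# Coerce a raw matrix into a system_matrix (internal; used by tests and the
# scalar/analytic paths where stabilization is not meaningful).
as_system_matrix <- function(A, labels = NULL) {
  n <- nrow(A)
  ev <- eigen(A, only.values = TRUE)$values
  structure(list(A = A, spectral_bound = max(Re(ev)),
                 normalization = "as-is",
                 labels = labels %||% sprintf("R%03d", seq_len(n)), n = n),
            class = "system_matrix")
}
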