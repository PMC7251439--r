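# Kernel functions for the SVM engine.
#
# Canonical forms (the published kernel table prints the sigmoid and Laplace
# formulas swapped; each formula is used here under its standard name):
#   linear      K(x, z) = x'z
#   polynomial  K(x, z) = (x'z)^d
#   gauss       K(x, z) = exp(-||x - z||^2 / (2 sigma^2))
#   laplace     K(x, z) = exp(-||x - z|| / sigma)
#   sigmoid     K(x, z) = tanh(beta x'z + theta)

#' Kernel specification
#'
#' @param kind One of `"linear"`, `"polynomial"`, `"gauss"`, `"sigmoid"`,
#'   `"laplace"`.
#' @param degree Integer degree `d >= 1` (polynomial only).
#' @param sigma Positive bandwidth (gauss and laplace only).
#' @param beta,theta Slope and offset of the sigmoid kernel.
#' @return A list of class `"kernel_spec"`.
#' @export
#' @examples
#' kernel_eval(kernel_spec("gauss", sigma = 1), rep(0, 6), rep(0, 6))
kernel_spec <- function(kind = c("linear", "polynomial", "gauss", "sigmoid", "laplace"),
                        degree = NULL, sigma = NULL, beta = NULL, theta = NULL) {
  kind <- match.arg(kind)
  spec <- list(kind = kind)
  if (kind == "polynomial") {
    if (is.null(degree)) stop("polynomial kernel requires a degree")
    if (degree < 1 || degree != round(degree)) stop("degree must be an integer >= 1")
    spec$degree <- as.integer(degree)
  }
  if (kind %in% c("gauss", "laplace")) {
    if (is.null(sigma)) stop(kind, " kernel requires a bandwidth sigma")
    if (sigma <= 0) stop("sigma must be positive")
    spec$sigma <- sigma
  }
  if (kind == "sigmoid") {
    if (is.null(beta) || is.null(theta)) stop("sigmoid kernel requires beta and theta")
    spec$beta <- beta
    spec$theta <- theta
  }
  structure(spec, class = "kernel_spec")
}

#' Evaluate a kernel on two vectors
#'
#' @param spec A [kernel_spec()].
#' @param x,z Numeric vectors of equal length.
#' @return A single kernel value; symmetric in `(x, z)`.
#' @export
kernel_eval <- function(spec, x, z) {
  if (length(x) != length(z)) stop("x and z must have equal dimension")
  drop(kernel_matrix(spec, matrix(x, 1), matrix(z, 1)))
}

#' Kernel (Gram) matrix between two sample sets
#'
#' @param spec A [kernel_spec()].
#' @param X,Z Numeric matrices with samples in rows (equal column counts);
#'   `Z` defaults to `X`.
#' @return The `nrow(X) x nrow(Z)` matrix of kernel values.
#' @export
kernel_matrix <- function(spec, X, Z = X) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != ncol(Z)) stop("X and Z must have equal dimension")
  switch(spec$kind,
    linear = tcrossprod(X, Z),
    polynomial = tcrossprod(X, Z)^spec$degree,
    gauss = {
      d2 <- sq_dists(X, Z)
      exp(-d2 / (2 * spec$sigma^2))
    },
    laplace = {
      d2 <- sq_dists(X, Z)
      exp(-sqrt(d2) / spec$sigma)
    },
    sigmoid = tanh(spec$beta * tcrossprod(X, Z) + spec$theta)
  )
}

# Pairwise squared Euclidean distances, clipped at 0 for round-off.
sq_dists <- function(X, Z) {
  xx <- rowSums(X^2)
  zz <- rowSums(Z^2)
  d2 <- outer(xx, zz, "+") - 2 * tcrossprod(X, Z)
  pmax(d2, 0)
}
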