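# Internal helpers shared across the pipeline.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' seeded fits and simulations do not perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

# Derive a child seed from a base seed and a small tag, staying below 2^31.
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1009L) * 104729L + as.integer(tag) * 7919L
}

# Stratified train/test split: per-class index lists with round(frac * n)
# training rows (at least one row on each side when the class allows it).
split_stratified <- function(labels, train_frac) {
  stopifnot(train_frac > 0, train_frac < 1)
  train <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    n <- length(idx)
    if (n == 0L) next
    n_tr <- round(train_frac * n)
    n_tr <- max(1L, min(n - 1L, n_tr))
    if (n == 1L) n_tr <- 1L
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

# Column standardization statistics learned on the training split and applied
# everywhere downstream (SVM kernels, neural nets, stacking).
scaling_fit <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  list(center = mu, scale = sdev)
}

scaling_apply <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$center, "-"), 2, scaling$scale, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
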