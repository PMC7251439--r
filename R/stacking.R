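# Stacking layer: concatenated base-learner outputs and the exponential
# linear regression (ELR) meta-learner producing the EM score.

#' Stack base-learner outputs into the 36-dim meta feature
#'
#' Fixed block order: the three one-vs-one SVM one-hot votes (4 each), then
#' the three MLP score vectors, then the three RBF score vectors
#' (9 learners x 4 = 36 coordinates).
#'
#' @param X Input vector or matrix on the training scale.
#' @param groups List of 3 `"em_ovo"` committees.
#' @param mlps List of 3 `"em_mlp"` fits.
#' @param rbfs List of 3 `"em_rbf"` fits.
#' @return Numeric matrix `n x 36`.
#' @export
stack_features <- function(X, groups, mlps, rbfs) {
  Xn <- if (is.null(dim(X))) matrix(X, 1) else as.matrix(X)
  blocks <- c(
    lapply(seq_along(groups), function(i) {
      B <- ovo_predict(groups[[i]], Xn); colnames(B) <- paste0("svm", i, "_", malignant_stages()); B
    }),
    lapply(seq_along(mlps), function(i) {
      B <- net_predict(mlps[[i]], Xn); colnames(B) <- paste0("mlp", i, "_", malignant_stages()); B
    }),
    lapply(seq_along(rbfs), function(i) {
      B <- net_predict(rbfs[[i]], Xn); colnames(B) <- paste0("rbf", i, "_", malignant_stages()); B
    })
  )
  do.call(cbind, blocks)
}

#' Fit the exponential linear regression meta-learner
#'
#' Least squares of the supervising values on the stacked features: the
#' affine map `ln_em = w'z + b` is fitted by minimizing the mean squared
#' loss between prediction and the manually set supervising value of each
#' sample's stage (3, 4, 5, 6 for stages I-IV), and the malignancy score is
#' `EM = exp(ln_em)`. The supervising values are interpreted on the lnEM
#' scale by default (`em_scale = "log"`); `em_scale = "raw"` instead fits
#' them on the raw EM scale. Because each one-hot block sums to one the
#' normal matrix is rank-deficient; a ridge of 1e-8 is added only when the
#' unregularized normal equations are numerically singular.
#'
#' @param Z Stacked feature matrix (`n x 36`).
#' @param stages Malignant stage labels (`"I"`-`"IV"`), one per row of `Z`.
#' @param supervising_values Named targets per stage (default 3-6).
#' @param em_scale `"log"` or `"raw"` (see above).
#' @return An object of class `"em_elr"` with `w`, `b`, `em_scale`,
#'   `training_loss` (mean squared loss), and `ridge_used`.
#' @export
elr_fit <- function(Z, stages, supervising_values = c(I = 3, II = 4, III = 5, IV = 6),
                    em_scale = c("log", "raw")) {
  em_scale <- match.arg(em_scale)
  Z <- as.matrix(Z)
  st <- as.character(stages)
  if (any(!st %in% malignant_stages())) {
    stop("ELR is fitted on malignant stages only (benign sample present)")
  }
  if (any(!st %in% names(supervising_values))) stop("missing supervising value for a stage")
  y <- as.numeric(supervising_values[st])
  A <- cbind(intercept = 1, Z)
  M <- crossprod(A)
  rhs <- crossprod(A, y)
  ridge_used <- 0
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch) || rcond(M) < 1e-12) {
    ridge_used <- 1e-8
    ch <- chol(M + ridge_used * diag(ncol(M)))
  }
  wb <- backsolve(ch, forwardsolve(t(ch), rhs))
  fitted <- as.numeric(A %*% wb)
  if (nrow(unique(Z)) == 1 && length(unique(y)) > 1) {
    warning("degenerate stacked features: identical rows with conflicting targets (irreducible loss)",
            call. = FALSE)
  }
  structure(list(
    w = setNames(wb[-1], colnames(Z)),
    b = wb[1],
    em_scale = em_scale,
    training_loss = mean((fitted - y)^2),
    ridge_used = ridge_used,
    supervising_values = supervising_values
  ), class = "em_elr")
}

#' Predict the EM malignancy score
#'
#' @param model An `"em_elr"` fit.
#' @param Z A stacked feature vector or matrix.
#' @return Data frame with `ln_em` and `em = exp(ln_em)` (always positive).
#'   Under `em_scale = "raw"` the affine map predicts EM directly (floored
#'   just above zero) and `ln_em` is its logarithm.
#' @export
predict_em <- function(model, Z) {
  Zn <- if (is.null(dim(Z))) matrix(Z, 1) else as.matrix(Z)
  lin <- as.numeric(Zn %*% model$w) + model$b
  if (model$em_scale == "log") {
    data.frame(ln_em = lin, em = exp(lin))
  } else {
    em <- pmax(lin, 1e-12)
    data.frame(ln_em = log(em), em = em)
  }
}
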