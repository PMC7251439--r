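# Soft-margin SVM in dual form and the one-vs-one staging committee.

#' Fit a binary soft-margin SVM (dual form)
#'
#' Solves the kernelized soft-margin dual
#' `max sum(alpha) - 0.5 alpha' Q alpha` subject to `sum(y alpha) = 0` and
#' `0 <= alpha <= C` by sequential minimal optimization, and recovers the
#' offset `b*` from the free support vectors. The decision function is
#' `sign(sum_i alpha_i y_i K(x_i, x) + b*)`.
#'
#' @param X Numeric matrix of training inputs (rows = samples), already on
#'   the scale the kernel should see.
#' @param y Labels in `{-1, +1}` (both classes present).
#' @param C Positive penalty parameter.
#' @param kernel A [kernel_spec()].
#' @param tol Termination tolerance on the KKT violation gap.
#' @return An object of class `"em_svm"` with elements `alpha`, `b`, `sv`
#'   (support-vector inputs), `sv_alpha_y`, `objective`, `xi` (slack
#'   summary), and diagnostics.
#' @export
#' @examples
#' X <- rbind(c(-1, 0, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0))
#' m <- svm_fit(X, c(-1, 1), C = 10, kernel = kernel_spec("linear"))
#' svm_decision(m, c(2, 0, 0, 0, 0, 0))$sign
svm_fit <- function(X, y, C, kernel = kernel_spec("linear"), tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (C <= 0) stop("C must be positive")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  K <- kernel_matrix(kernel, X)
  sol <- smo_solve(K, y, C, tol = tol)
  alpha <- sol$alpha
  keep <- alpha > 1e-10
  f_train <- as.numeric(K %*% (alpha * y)) + sol$b
  xi <- pmax(0, 1 - y * f_train)
  structure(list(
    alpha = alpha[keep],
    b = sol$b,
    sv = X[keep, , drop = FALSE],
    sv_y = y[keep],
    C = C,
    kernel = kernel,
    objective = sol$objective,
    n_sv = sum(keep),
    xi_summary = summary(xi),
    train_error = mean(sign(f_train) != y),
    converged = sol$converged,
    iterations = sol$iterations,
    alpha_full = alpha,
    y_full = y
  ), class = "em_svm")
}

#' Evaluate an SVM decision function
#'
#' @param model An `"em_svm"` fit.
#' @param x A marker vector or matrix of rows to score (same scale as
#'   training).
#' @return List with `value` (raw decision values) and `sign` (-1/+1; zero
#'   values are assigned +1).
#' @export
svm_decision <- function(model, x) {
  Xn <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  k <- kernel_matrix(model$kernel, Xn, model$sv)
  val <- as.numeric(k %*% (model$alpha * model$sv_y)) + model$b
  list(value = val, sign = ifelse(val >= 0, 1, -1))
}

# Candidate kernel specs for a kernel kind under the configured grids.
kernel_candidates <- function(kind, config) {
  switch(kind,
    linear = list(kernel_spec("linear")),
    polynomial = lapply(config$degree_grid, function(d) kernel_spec("polynomial", degree = d)),
    gauss = lapply(config$sigma_grid, function(s) kernel_spec("gauss", sigma = s)),
    laplace = lapply(config$sigma_grid, function(s) kernel_spec("laplace", sigma = s)),
    sigmoid = list(kernel_spec("sigmoid", beta = 1 / 6, theta = 0)),
    stop("unknown kernel kind: ", kind)
  )
}

# Grid search for one binary SVM: hold out a fifth of the rows for selection,
# pick the (C, kernel parameters) with the lowest held-out error (ties ->
# smaller C, earlier kernel candidate), then refit on all rows.
svm_fit_grid <- function(X, y, kinds, config) {
  n <- nrow(X)
  hold <- sample(n, max(1L, round(n / 5)))
  if (length(unique(y[-hold])) < 2 || length(unique(y[hold])) < 2) {
    # degenerate holdout (tiny classes): select on training error instead
    hold <- integer(0)
  }
  tr <- if (length(hold)) seq_len(n)[-hold] else seq_len(n)
  ev <- if (length(hold)) hold else seq_len(n)
  best <- NULL
  for (kind in kinds) {
    for (ks in kernel_candidates(kind, config)) {
      for (C in sort(config$C_grid)) {
        m <- svm_fit(X[tr, , drop = FALSE], y[tr], C = C, kernel = ks)
        err <- mean(svm_decision(m, X[ev, , drop = FALSE])$sign != y[ev])
        if (is.null(best) || err < best$err - 1e-12) {
          best <- list(err = err, C = C, kernel = ks)
        }
      }
    }
  }
  final <- svm_fit(X, y, C = best$C, kernel = best$kernel)
  final$heldout_error <- best$err
  final
}

#' Train a one-vs-one SVM committee for stages I-IV
#'
#' Fits `choose(4, 2) = 6` pairwise binary SVMs, one per unordered stage
#' pair, all sharing one kernel kind. Each pairwise model sees only its two
#' classes. Per model, the penalty C and kernel parameters are selected on a
#' held-out fifth of that pair's rows, targeting held-out error below
#' `config$epsilon`; when the grid cannot reach it, the best model found is
#' kept and flagged.
#'
#' @param X Numeric matrix of malignant training inputs.
#' @param stages Factor of stage labels (`"I"`-`"IV"`; all four present).
#' @param kind Kernel kind shared by the group.
#' @param config An [em_config()].
#' @return An object of class `"em_ovo"`: list of 6 pairwise models (named
#'   `"I|II"`, ...), the kernel kind, and a per-pair held-out error table.
#' @export
ovo_fit <- function(X, stages, kind, config = em_config()) {
  stages <- factor(as.character(stages), levels = malignant_stages())
  if (any(table(stages) == 0)) stop("all four stages must be represented")
  pairs <- utils::combn(malignant_stages(), 2)
  models <- list()
  report <- data.frame(pair = character(0), heldout_error = numeric(0),
                       meets_epsilon = logical(0), C = numeric(0))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    idx <- which(stages %in% c(a, b))
    y <- ifelse(stages[idx] == a, 1, -1)  # +1 = lower stage of the pair
    m <- svm_fit_grid(X[idx, , drop = FALSE], y, kinds = kind, config = config)
    m$pair <- c(a, b)
    nm <- paste(a, b, sep = "|")
    models[[nm]] <- m
    report <- rbind(report, data.frame(pair = nm, heldout_error = m$heldout_error,
                                       meets_epsilon = m$heldout_error <= config$epsilon,
                                       C = m$C))
  }
  if (any(!report$meets_epsilon)) {
    warning("OvO group (", kind, "): ", sum(!report$meets_epsilon),
            " pairwise model(s) above epsilon = ", config$epsilon, call. = FALSE)
  }
  structure(list(models = models, kind = kind, report = report),
            class = "em_ovo")
}

#' Vote counts of a one-vs-one committee
#'
#' @param group An `"em_ovo"` committee.
#' @param X Input vector or matrix (training scale).
#' @return Integer matrix `n x 4` of per-stage vote counts; rows sum to 6.
#' @export
ovo_votes <- function(group, X) {
  Xn <- if (is.null(dim(X))) matrix(X, 1) else as.matrix(X)
  votes <- matrix(0L, nrow(Xn), 4, dimnames = list(NULL, malignant_stages()))
  for (m in group$models) {
    s <- svm_decision(m, Xn)$sign
    win <- ifelse(s >= 0, m$pair[1], m$pair[2])
    for (st in malignant_stages()) votes[, st] <- votes[, st] + (win == st)
  }
  votes
}

#' One-hot majority-vote prediction of a one-vs-one committee
#'
#' Majority voting over the six pairwise decisions; ties break to the lowest
#' tied stage (deterministic and conservative: never over-stages).
#'
#' @inheritParams ovo_votes
#' @return Numeric matrix `n x 4`; each row is one-hot over stages I-IV.
#' @export
ovo_predict <- function(group, X) {
  v <- ovo_votes(group, X)
  onehot <- matrix(0, nrow(v), 4, dimnames = list(NULL, malignant_stages()))
  win <- apply(v, 1, which.max)  # which.max -> first (lowest) tied stage
  onehot[cbind(seq_len(nrow(v)), win)] <- 1
  onehot
}
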