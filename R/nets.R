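# Neural base learners: fixed-architecture MLPs and RBF networks with
# k-means hidden centers.

#' Lloyd k-means for RBF hidden centers
#'
#' Plain Lloyd iteration: initialize centers at k distinct sample rows,
#' alternate nearest-center assignment and mean updates until assignments
#' stabilize. Empty clusters are reseeded at the point farthest from its
#' center. The within-cluster sum of squares (inertia) is recorded at every
#' iteration and is non-increasing by construction.
#'
#' @param X Numeric matrix of samples in rows.
#' @param k Number of centers (`k <=` number of distinct rows).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return List with `centers` (`k x ncol(X)`), `assignment`, `inertia`
#'   (final value), and `inertia_trace` (one value per iteration).
#' @export
kmeans_centers <- function(X, k, seed = NULL) {
  X <- as.matrix(X)
  ux <- unique(X)
  if (k > nrow(ux)) stop("k exceeds the number of distinct samples")
  with_seed(seed, {
    centers <- ux[sample(nrow(ux), k), , drop = FALSE]
    trace <- numeric(0)
    assign_old <- rep(-1L, nrow(X))
    for (it in 1:100) {
      d2 <- sq_dists(X, centers)
      assign_new <- max.col(-d2, ties.method = "first")
      inertia <- sum(d2[cbind(seq_len(nrow(X)), assign_new)])
      trace <- c(trace, inertia)
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
      for (j in seq_len(k)) {
        rows <- which(assign_new == j)
        if (length(rows)) {
          centers[j, ] <- colMeans(X[rows, , drop = FALSE])
        } else {
          far <- which.max(d2[cbind(seq_len(nrow(X)), assign_new)])
          centers[j, ] <- X[far, ]
        }
      }
    }
    list(centers = centers, assignment = assign_old, inertia = trace[length(trace)],
         inertia_trace = trace)
  })
}

#' Radial basis activation
#'
#' `exp(-beta * ||x - c||^2)`: equals 1 iff `x` coincides with the center and
#' decays strictly with distance.
#'
#' @param x Input vector.
#' @param center Center vector of the hidden unit.
#' @param beta Positive width parameter.
#' @return Activation in `(0, 1]`.
#' @export
rbf_activation <- function(x, center, beta) {
  if (beta <= 0) stop("beta must be positive")
  exp(-beta * sum((x - center)^2))
}

# One-hot target matrix (n x 4) from stage labels I-IV.
onehot_targets <- function(stages) {
  stages <- factor(as.character(stages), levels = malignant_stages())
  Y <- matrix(0, length(stages), 4, dimnames = list(NULL, malignant_stages()))
  Y[cbind(seq_along(stages), as.integer(stages))] <- 1
  Y
}

#' Train an RBF network
#'
#' Hidden centers come from [kmeans_centers()]; widths are set to
#' `beta_i = 1 / (2 m_i^2)` with `m_i` the mean distance from center i to its
#' two nearest other centers; output weights are fitted by ridge-regularized
#' least squares against the one-hot stage targets.
#'
#' @param X Numeric matrix of training inputs (standardized scale).
#' @param stages Stage labels (`"I"`-`"IV"`).
#' @param hidden Number of hidden units.
#' @param config An [em_config()] (supplies `rbf_ridge` and `epsilon`).
#' @param heldout_frac Fraction held out to report the generalization error.
#' @return An object of class `"em_rbf"`.
#' @export
rbf_fit <- function(X, stages, hidden, config = em_config(), heldout_frac = 0.2) {
  X <- as.matrix(X)
  if (hidden > nrow(X)) stop("hidden unit count exceeds the training size")
  Y <- onehot_targets(stages)
  n <- nrow(X)
  hold <- sample(n, max(1L, round(heldout_frac * n)))
  tr <- seq_len(n)[-hold]
  fit_one <- function(rows) {
    km <- kmeans_centers(X[rows, , drop = FALSE], hidden)
    centers <- km$centers
    dc <- sqrt(sq_dists(centers, centers))
    diag(dc) <- Inf
    m_i <- apply(dc, 1, function(d) mean(sort(d)[1:2]))
    m_i[!is.finite(m_i) | m_i < 1e-8] <- 1
    beta <- 1 / (2 * m_i^2)
    Phi <- cbind(1, exp(-sweep(sq_dists(X[rows, , drop = FALSE], centers), 2, beta, "*")))
    A <- crossprod(Phi) + config$rbf_ridge * diag(ncol(Phi))
    W <- solve(A, crossprod(Phi, Y[rows, , drop = FALSE]))
    list(centers = centers, beta = beta, W = W)
  }
  probe <- fit_one(tr)
  model <- structure(c(probe, list(hidden = hidden)), class = "em_rbf")
  pred <- net_predict(model, X[hold, , drop = FALSE])
  heldout_error <- mean(max.col(pred, ties.method = "first") !=
                          as.integer(factor(as.character(stages[hold]), levels = malignant_stages())))
  final <- fit_one(seq_len(n))
  structure(c(final, list(hidden = hidden, heldout_error = heldout_error,
                          meets_epsilon = heldout_error <= config$epsilon)),
            class = "em_rbf")
}

#' Train a multilayer perceptron
#'
#' Fixed architecture mapping the 6 markers to 4 stage scores: ReLU hidden
#' layers, an exponentially normalized (softmax) output layer, mean
#' cross-entropy loss against one-hot stage targets, full-batch gradient
#' descent with a fixed step. A fifth of the rows is held out to monitor the
#' generalization error; training stops early once it falls below
#' `config$epsilon`, otherwise the weights with the best held-out error seen
#' are kept and flagged.
#'
#' @param X Numeric matrix of training inputs (standardized scale).
#' @param stages Stage labels (`"I"`-`"IV"`).
#' @param architecture Layer sizes from input to output, e.g.
#'   `c(6, 9, 7, 4)`.
#' @param config An [em_config()].
#' @param heldout_frac Fraction held out for early stopping.
#' @return An object of class `"em_mlp"` with weights `W`, biases `b`,
#'   `heldout_error`, and `meets_epsilon`.
#' @export
mlp_fit <- function(X, stages, architecture, config = em_config(), heldout_frac = 0.2) {
  X <- as.matrix(X)
  if (architecture[1] != ncol(X) || architecture[length(architecture)] != 4) {
    stop("architecture must map ", ncol(X), " inputs to 4 outputs")
  }
  Y <- onehot_targets(stages)
  n <- nrow(X)
  hold <- sample(n, max(1L, round(heldout_frac * n)))
  tr <- seq_len(n)[-hold]
  par <- mlp_init(architecture)
  vel <- lapply(par, function(p) lapply(p, function(m) m * 0))
  best <- list(err = Inf, par = par)
  y_hold <- as.integer(factor(as.character(stages[hold]), levels = malignant_stages()))
  for (ep in seq_len(config$mlp_epochs)) {
    g <- mlp_loss_grad(par, X[tr, , drop = FALSE], Y[tr, , drop = FALSE])$grad
    for (l in seq_along(par$W)) {
      vel$W[[l]] <- config$mlp_momentum * vel$W[[l]] - config$mlp_lr * g$W[[l]]
      vel$b[[l]] <- config$mlp_momentum * vel$b[[l]] - config$mlp_lr * g$b[[l]]
      par$W[[l]] <- par$W[[l]] + vel$W[[l]]
      par$b[[l]] <- par$b[[l]] + vel$b[[l]]
    }
    if (ep %% 25 == 0 || ep == config$mlp_epochs) {
      scores <- mlp_forward(par, X[hold, , drop = FALSE])$probs
      err <- mean(max.col(scores, ties.method = "first") != y_hold)
      if (err < best$err) best <- list(err = err, par = par)
      if (err <= config$epsilon) break
    }
  }
  structure(list(W = best$par$W, b = best$par$b, architecture = architecture,
                 heldout_error = best$err,
                 meets_epsilon = best$err <= config$epsilon),
            class = "em_mlp")
}

# He-normal initialization for ReLU layers.
mlp_init <- function(architecture) {
  L <- length(architecture) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- architecture[l]
    W[[l]] <- matrix(rnorm(fan_in * architecture[l + 1], 0, sqrt(2 / fan_in)),
                     fan_in, architecture[l + 1])
    b[[l]] <- rep(0, architecture[l + 1])
  }
  list(W = W, b = b)
}

# Forward pass: ReLU hiddens, softmax output. Returns activations for backprop.
mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- list(X)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    A[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
  }
  logits <- A[[L + 1]]
  m <- apply(logits, 1, max)
  P <- exp(logits - m)
  P <- P / rowSums(P)
  list(acts = A, probs = P)
}

# Mean cross-entropy loss and its analytic gradient (used by training and by
# the finite-difference gradient check in the tests).
mlp_loss_grad <- function(par, X, Y) {
  fw <- mlp_forward(par, X)
  A <- fw$acts; P <- fw$probs
  n <- nrow(X); L <- length(par$W)
  loss <- -mean(rowSums(Y * log(pmax(P, 1e-300))))
  delta <- (P - Y) / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$W[[l]])) * (A[[l]] > 0)
    }
  }
  list(loss = loss, grad = list(W = gW, b = gb))
}

#' Score inputs with a neural base learner
#'
#' Forward pass of an MLP or RBF network. Outputs are non-negative 4-vectors
#' summing to 1: softmax scores for the MLP; for the RBF network the linear
#' outputs are clipped at zero and renormalized (uniform if all are zero),
#' which preserves the least-squares calibration of the dominant class.
#'
#' @param model An `"em_mlp"` or `"em_rbf"` fit.
#' @param X Input vector or matrix (training scale).
#' @return Numeric matrix `n x 4` of stage scores.
#' @export
net_predict <- function(model, X) {
  Xn <- if (is.null(dim(X))) matrix(X, 1) else as.matrix(X)
  if (inherits(model, "em_mlp")) {
    return(mlp_forward(list(W = model$W, b = model$b), Xn)$probs)
  }
  if (inherits(model, "em_rbf")) {
    Phi <- cbind(1, exp(-sweep(sq_dists(Xn, model$centers), 2, model$beta, "*")))
    S <- pmax(Phi %*% model$W, 0)
    rs <- rowSums(S)
    S[rs < 1e-12, ] <- 1
    S <- S / rowSums(S)
    colnames(S) <- malignant_stages()
    return(S)
  }
  stop("unknown base-learner class")
}
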