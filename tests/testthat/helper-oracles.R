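# Independent oracles and shared fixtures (built in code, cached per run).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small cohort + fitted system for unit-level pipeline tests.
small_cohort <- function() {
  cached("small_cohort", simulate_cohort(cohort_spec(
    n_per_class = c(benign = 60, I = 60, II = 60, III = 60, IV = 60), seed = 11)))
}

small_system <- function() {
  cached("small_system", suppressWarnings(em_system(small_cohort(), em_config(seed = 7))))
}

# Default-scale cohort (300 per class) + fitted system for the acceptance
# criteria.
acceptance_cohort <- function() {
  cached("acceptance_cohort", simulate_cohort(cohort_spec(seed = 101)))
}

acceptance_system <- function() {
  cached("acceptance_system",
         suppressWarnings(em_system(acceptance_cohort(), em_config(seed = 102))))
}

# Brute-force QP oracle for the soft-margin SVM dual: projected gradient
# descent on f(a) = 0.5 a'Qa - sum(a) over {0 <= a <= C, y'a = 0}, with the
# exact projection computed by bisection on the equality multiplier.
# Independent of the package's SMO path.
svm_dual_oracle <- function(K, y, C, iters = 50000) {
  n <- length(y)
  Q <- outer(y, y) * K
  L <- max(abs(eigen(Q, symmetric = TRUE, only.values = TRUE)$values), 1e-8)
  step <- 1 / L
  project <- function(a) {
    g <- function(nu) sum(y * pmin(pmax(a - nu * y, 0), C))
    lo <- -10 * C - 10
    hi <- 10 * C + 10
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    pmin(pmax(a - ((lo + hi) / 2) * y, 0), C)
  }
  a <- project(rep(0, n))
  for (i in seq_len(iters)) {
    a_new <- project(a - step * (Q %*% a - 1))
    if (max(abs(a_new - a)) < 1e-12) { a <- a_new; break }
    a <- a_new
  }
  a <- as.numeric(a)
  list(alpha = a, objective = sum(a) - 0.5 * sum(a * (Q %*% a)))
}

# Stub binary SVM emitting a fixed decision sign for any input: one zero
# support vector under a linear kernel makes the decision value equal b.
stub_svm <- function(sign_value, pair) {
  structure(list(alpha = 1, b = sign_value, sv = matrix(0, 1, 6), sv_y = 1,
                 C = 1, kernel = kernel_spec("linear"), pair = pair),
            class = "em_svm")
}

# OvO committee whose six pairwise decisions are prescribed: signs[k] = +1
# means the lower stage of pair k wins. Pair order follows combn(4, 2).
stub_ovo <- function(signs) {
  pairs <- utils::combn(c("I", "II", "III", "IV"), 2)
  models <- lapply(seq_len(6), function(k) {
    stub_svm(ifelse(signs[k] > 0, 1, -1), pairs[, k])
  })
  names(models) <- apply(pairs, 2, paste, collapse = "|")
  structure(list(models = models, kind = "linear", report = NULL), class = "em_ovo")
}

# Exhaustive-enumeration oracle for majority voting with lowest-stage
# tie-break, given the six prescribed pairwise outcomes.
vote_oracle <- function(signs) {
  pairs <- utils::combn(c("I", "II", "III", "IV"), 2)
  votes <- setNames(rep(0, 4), c("I", "II", "III", "IV"))
  for (k in seq_len(6)) {
    win <- if (signs[k] > 0) pairs[1, k] else pairs[2, k]
    votes[win] <- votes[win] + 1
  }
  names(votes)[which(votes == max(votes))[1]]
}

# Noise-free marker profile at a given latent severity (for constructed
# diagnostic cases).
clean_profile <- function(L) {
  sp <- cohort_spec(noise_sd = 1e-9, seed = 1)
  set.seed(1)
  severity_to_profile(L, sp)
}
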