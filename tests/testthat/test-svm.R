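test_that("the symmetric 2-point problem puts the separating plane at the origin", {
  X <- rbind(c(-1, 0, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0))
  m <- svm_fit(X, c(-1, 1), C = 10, kernel = kernel_spec("linear"))
  expect_lt(abs(svm_decision(m, rep(0, 6))$value), 1e-6)
  expect_equal(svm_decision(m, c(2, 0, 0, 0, 0, 0))$sign, 1)
  expect_equal(svm_decision(m, X)$sign, c(-1, 1))  # 100% on its training set
})

test_that("dual constraints hold on random seeded toy problems", {
  for (s in 1:5) {
    set.seed(s)
    n <- 12
    X <- matrix(rnorm(n * 6), n, 6) + outer(rep(c(-1, 1), each = n / 2), c(1, 1, 0, 0, 0, 0))
    y <- rep(c(-1, 1), each = n / 2)
    C <- sample(c(0.5, 1, 10), 1)
    kern <- if (s %% 2) kernel_spec("gauss", sigma = 1) else kernel_spec("linear")
    m <- svm_fit(X, y, C = C, kernel = kern)
    expect_true(all(m$alpha_full >= -1e-8 & m$alpha_full <= C + 1e-8))
    expect_lte(abs(sum(m$alpha_full * m$y_full)), 1e-6)
  }
})

test_that("SMO matches the brute-force QP oracle on small instances", {
  for (s in 1:4) {
    set.seed(100 + s)
    n <- 8
    X <- matrix(rnorm(n * 6), n, 6)
    y <- rep(c(-1, 1), each = n / 2)
    kern <- if (s %% 2) kernel_spec("gauss", sigma = 1) else kernel_spec("linear")
    C <- c(1, 10)[1 + s %% 2]
    m <- svm_fit(X, y, C = C, kernel = kern)
    K <- kernel_matrix(kern, X)
    oracle <- svm_dual_oracle(K, y, C)
    expect_equal(m$objective, oracle$objective,
                 tolerance = 1e-4 * max(1, abs(oracle$objective)))
    # decision signs agree on the training points (oracle offset from free SVs)
    free <- oracle$alpha > 1e-6 & oracle$alpha < C - 1e-6
    f_nob <- as.numeric(K %*% (oracle$alpha * y))
    b_o <- if (any(free)) mean(y[free] - f_nob[free]) else m$b
    expect_equal(svm_decision(m, X)$sign, ifelse(f_nob + b_o >= 0, 1, -1))
  }
})

test_that("svm_fit rejects invalid inputs", {
  X <- matrix(rnorm(12), 2, 6)
  expect_error(svm_fit(X, c(1, 1), C = 1), "both classes")
  expect_error(svm_fit(X, c(-1, 1), C = 0), "positive")
  expect_error(svm_fit(X, c(0, 1), C = 1), "-1/\\+1")
})

test_that("a one-vs-one group has 6 pairwise models, each seeing only its pair", {
  co <- small_cohort()
  mal <- co[co$label != "benign", ]
  X <- marker_matrix(mal)
  X <- scale(log(pmax(X, 1e-9)))  # any sensible scale works for this check
  set.seed(1)
  grp <- suppressWarnings(ovo_fit(X, mal$label, kind = "linear", config = em_config()))
  expect_length(grp$models, 6)
  expect_setequal(names(grp$models),
                  c("I|II", "I|III", "I|IV", "II|III", "II|IV", "III|IV"))
  n12 <- sum(mal$label %in% c("I", "II"))
  expect_equal(length(grp$models[["I|II"]]$y_full), n12)
  expect_error(ovo_fit(X[mal$label != "III", ], mal$label[mal$label != "III"],
                       "linear", em_config()),
               "all four stages")
})

test_that("well-separated stage clusters are classified almost perfectly", {
  sp <- cohort_spec(n_per_class = c(benign = 0, I = 40, II = 40, III = 40, IV = 40),
                    severity_sd = 0.05, noise_sd = 0.01, seed = 23)
  co <- simulate_cohort(sp)
  X <- scale(log(pmax(marker_matrix(co), 1e-9)))
  set.seed(2)
  grp <- ovo_fit(X, co$label, kind = "gauss", config = em_config())
  onehot <- ovo_predict(grp, X)
  pred <- c("I", "II", "III", "IV")[max.col(onehot)]
  expect_gte(mean(pred == as.character(co$label)), 0.95)
})

test_that("majority voting matches exhaustive enumeration incl. tie-breaks", {
  x <- rep(0, 6)
  for (code in 0:63) {
    signs <- 2 * as.integer(intToBits(code)[1:6]) - 1
    grp <- stub_ovo(signs)
    votes <- ovo_votes(grp, x)
    expect_equal(sum(votes), 6)  # each classifier casts exactly one vote
    onehot <- ovo_predict(grp, x)
    expect_equal(sum(onehot), 1)
    expect_equal(c("I", "II", "III", "IV")[which(onehot[1, ] == 1)],
                 vote_oracle(signs))
  }
  # the 2-2-2-0 tie resolves to the lowest tied stage
  signs <- c(1, 1, -1, 1, 1, -1)  # I: 2 votes, II: 2, III: 0, IV: 2
  v <- ovo_votes(stub_ovo(signs), x)
  expect_equal(as.integer(v), c(2L, 2L, 0L, 2L))
  expect_equal(as.integer(ovo_predict(stub_ovo(signs), x)), c(1L, 0L, 0L, 0L))
})
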