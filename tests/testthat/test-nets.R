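test_that("Lloyd k-means reaches standard solutions with a monotone inertia trace", {
  set.seed(1)
  X <- matrix(rnorm(120), 20, 6)
  km1 <- kmeans_centers(X, 1, seed = 5)
  expect_equal(drop(km1$centers), colMeans(X), tolerance = 1e-10)

  Xu <- unique(X)
  kmn <- kmeans_centers(Xu, nrow(Xu), seed = 5)
  expect_lt(kmn$inertia, 1e-10)

  expect_error(kmeans_centers(X, nrow(X) + 1, seed = 1), "distinct")

  # two well-separated blobs: centers near the blob means, and the trace
  # never increases
  set.seed(2)
  blob <- rbind(matrix(rnorm(300, 0, 0.3), 50, 6),
                matrix(rnorm(300, 5, 0.3), 50, 6))
  km2 <- kmeans_centers(blob, 2, seed = 3)
  expect_true(all(diff(km2$inertia_trace) <= 1e-9))
  cent <- km2$centers[order(km2$centers[, 1]), ]
  se <- 0.3 / sqrt(50)
  expect_true(all(abs(cent[1, ] - colMeans(blob[1:50, ])) < 3 * se + 0.1))
  expect_true(all(abs(cent[2, ] - colMeans(blob[51:100, ])) < 3 * se + 0.1))

  # agreement with the reference Lloyd implementation on the same task
  ref <- stats::kmeans(blob, 2, nstart = 5)
  expect_equal(km2$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("radial basis activation behaves as exp(-beta ||x - c||^2)", {
  c0 <- rnorm(6)
  expect_equal(rbf_activation(c0, c0, beta = 2), 1)
  x <- c0 + sqrt(1 / (2 * 6)) * rep(1, 6)  # beta * d^2 = 1 at beta = 2
  expect_equal(rbf_activation(x, c0, beta = 2), exp(-1), tolerance = 1e-12)
  # doubling the distance raises the activation to the fourth power
  d <- rnorm(6)
  a1 <- rbf_activation(c0 + d, c0, 0.7)
  a2 <- rbf_activation(c0 + 2 * d, c0, 0.7)
  expect_equal(a2, a1^4, tolerance = 1e-10)
  expect_error(rbf_activation(x, c0, beta = 0), "positive")
})

test_that("RBF networks interpolate noise-free clusters and keep their width", {
  sp <- cohort_spec(n_per_class = c(benign = 0, I = 30, II = 30, III = 30, IV = 30),
                    severity_sd = 0.05, noise_sd = 0.01, seed = 31)
  co <- simulate_cohort(sp)
  X <- scale(log(pmax(marker_matrix(co), 1e-9)))
  for (k in em_config()$rbf_hidden_units) {
    set.seed(4)
    m <- rbf_fit(X, co$label, hidden = k, config = em_config())
    expect_equal(nrow(m$centers), k)
    expect_true(all(m$beta > 0))
    S <- net_predict(m, X)
    expect_equal(ncol(S), 4)
    expect_true(all(S >= 0))
    expect_equal(rowSums(S), rep(1, nrow(S)), tolerance = 1e-9)
    pred <- c("I", "II", "III", "IV")[max.col(S)]
    expect_gte(mean(pred == as.character(co$label)), 0.95)
  }
})

test_that("one-hot targets mark the stage position", {
  T <- prostEM:::onehot_targets(c("I", "III"))
  expect_equal(unname(T[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(T[2, ]), c(0, 0, 1, 0))
  expect_equal(rowSums(T), c(1, 1))
})

test_that("MLP analytic gradients match central finite differences", {
  set.seed(9)
  arch <- c(6, 5, 4)
  par <- prostEM:::mlp_init(arch)
  X <- matrix(rnorm(60), 10, 6)
  T <- prostEM:::onehot_targets(sample(c("I", "II", "III", "IV"), 10, replace = TRUE))
  g <- prostEM:::mlp_loss_grad(par, X, T)
  eps <- 1e-6
  for (l in seq_along(par$W)) {
    for (idx in list(c(1, 1), c(2, 3))) {
      pp <- par; pp$W[[l]][idx[1], idx[2]] <- pp$W[[l]][idx[1], idx[2]] + eps
      pm <- par; pm$W[[l]][idx[1], idx[2]] <- pm$W[[l]][idx[1], idx[2]] - eps
      num <- (prostEM:::mlp_loss_grad(pp, X, T)$loss -
                prostEM:::mlp_loss_grad(pm, X, T)$loss) / (2 * eps)
      ana <- g$grad$W[[l]][idx[1], idx[2]]
      expect_equal(unname(ana), num, tolerance = 1e-5 * max(1, abs(num)))
    }
    pb <- par; pb$b[[l]][1] <- pb$b[[l]][1] + eps
    mb <- par; mb$b[[l]][1] <- mb$b[[l]][1] - eps
    num <- (prostEM:::mlp_loss_grad(pb, X, T)$loss -
              prostEM:::mlp_loss_grad(mb, X, T)$loss) / (2 * eps)
    expect_equal(unname(g$grad$b[[l]][1]), num, tolerance = 1e-5 * max(1, abs(num)))
  }
})

test_that("MLPs learn well-separated clusters and emit normalized scores", {
  sp <- cohort_spec(n_per_class = c(benign = 0, I = 30, II = 30, III = 30, IV = 30),
                    severity_sd = 0.05, noise_sd = 0.01, seed = 37)
  co <- simulate_cohort(sp)
  X <- scale(log(pmax(marker_matrix(co), 1e-9)))
  set.seed(6)
  m <- mlp_fit(X, co$label, architecture = c(6, 9, 7, 4), config = em_config())
  S <- net_predict(m, X)
  expect_true(all(S >= 0))
  expect_equal(rowSums(S), rep(1, nrow(S)), tolerance = 1e-9)
  pred <- c("I", "II", "III", "IV")[max.col(S)]
  expect_gte(mean(pred == as.character(co$label)), 0.95)
  # deterministic forward pass
  expect_identical(net_predict(m, X[1:3, ]), net_predict(m, X[1:3, ]))
  expect_error(mlp_fit(X, co$label, architecture = c(6, 3, 3), config = em_config()),
               "4 outputs")
})
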