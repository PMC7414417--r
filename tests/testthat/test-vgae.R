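test_that("encoder matrix form matches per-node message passing", {
  for (rep in 1:8) {
    g <- random_attributed_graph(n = 8, r = 5, seed = 500 + rep)
    set.seed(rep)
    params <- list(W0 = matrix(rnorm(5 * 6), 5),
                   W_mu = matrix(rnorm(6 * 3), 6),
                   W_sigma = matrix(rnorm(6 * 3), 6))
    fast <- gcn_forward(g$attributes, g$adj_norm, params)
    slow <- oracle_gcn(g$attributes, g$adj_norm, params)
    expect_equal(fast$mu, slow$mu, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(fast$log_sigma, slow$log_sigma, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("encoder closed forms hold on degenerate inputs", {
  # single node with self-loop: mu = ReLU(x * w0) * w_mu
  params <- list(W0 = matrix(2), W_mu = matrix(3), W_sigma = matrix(1))
  out <- gcn_forward(matrix(1), Matrix::Matrix(1), params)
  expect_equal(out$mu, matrix(6), ignore_attr = TRUE)
  # zero attributes give zero output regardless of weights
  g <- random_attributed_graph(n = 5, r = 4, seed = 3)
  params <- list(W0 = matrix(rnorm(4 * 6), 4), W_mu = matrix(rnorm(6 * 2), 6),
                 W_sigma = matrix(rnorm(6 * 2), 6))
  out <- gcn_forward(matrix(0, 5, 4), g$adj_norm, params)
  expect_equal(out$mu, matrix(0, 5, 2), ignore_attr = TRUE)
  # all-negative pre-activations are killed by the ReLU
  params$W0 <- -abs(params$W0)
  out <- gcn_forward(abs(g$attributes), g$adj_norm, params)
  expect_equal(out$mu, matrix(0, 5, 2), ignore_attr = TRUE)
})

test_that("reparameterized sampling collapses to the mean without noise", {
  dist <- list(mu = matrix(1:6 / 2, 2), log_sigma = matrix(0, 2, 3))
  expect_equal(sample_latent(dist, epsilon = matrix(0, 2, 3))$z, dist$mu)
  dist$log_sigma <- matrix(-50, 2, 3)  # sigma -> 0
  expect_equal(sample_latent(dist, seed = 1)$z, dist$mu, tolerance = 1e-15)
  # same seed, same draw
  expect_equal(sample_latent(dist, seed = 9), sample_latent(dist, seed = 9))
})

test_that("sampled latents have the requested moments", {
  dist <- list(mu = matrix(0, 1e5, 1), log_sigma = matrix(0, 1e5, 1))
  z <- sample_latent(dist, seed = 42)$z
  se <- 1 / sqrt(1e5)
  expect_lt(abs(mean(z)), 3 * se)
  expect_lt(abs(sd(z) - 1), 3 * se)
})

test_that("decoder is symmetric, bounded, and logistic in the inner product", {
  expect_equal(decode_links(matrix(0, 3, 2)), matrix(0.5, 3, 3))
  z <- matrix(c(1, 0), 1)
  expect_equal(decode_links(rbind(z, z))[1, 2], 1 / (1 + exp(-1)),
               tolerance = 1e-6)
  set.seed(8)
  z <- matrix(rnorm(12), 4)
  p <- decode_links(z)
  expect_equal(p, t(p))
  expect_true(all(p > 0 & p < 1))
})

test_that("the loss has its closed-form values and a non-negative KL", {
  a <- diag(2)
  zero_dist <- list(mu = matrix(0, 2, 2), log_sigma = matrix(0, 2, 2))
  l <- vgae_loss(a, zero_dist, matrix(0, 2, 2), pos_weight = 1, norm = 1)
  expect_equal(l$kl, 0)
  expect_equal(l$reconstruction, log(2), tolerance = 1e-9)
  expect_equal(l$total, l$reconstruction + l$kl)

  # closed-form Gaussian KL: mu=1, sigma=1, N=K=1 gives 1/2
  l <- vgae_loss(matrix(1), list(mu = matrix(1), log_sigma = matrix(0)),
                 matrix(0), pos_weight = 1, norm = 1)
  expect_equal(l$kl, 0.5)

  set.seed(31)
  for (rep in 1:20) {
    dist <- list(mu = matrix(rnorm(6), 2), log_sigma = matrix(rnorm(6), 2))
    kl <- vgae_loss(diag(2), dist, matrix(0, 2, 3))$kl
    expect_gte(kl, 0)
  }
})

test_that("analytic training gradients match finite differences", {
  set.seed(42)
  n <- 6; r <- 4; h <- 5; k <- 3
  g <- random_attributed_graph(n = n, r = r, p = 0.5, seed = 44)
  a <- as.matrix(g$adjacency)
  an <- as.matrix(g$adj_norm)
  x <- g$attributes
  params <- list(W0 = matrix(rnorm(r * h), r), W_mu = matrix(rnorm(h * k), h),
                 W_sigma = matrix(rnorm(h * k) * 0.1, h))
  eps_mat <- matrix(rnorm(n * k), n)
  nnz <- sum(a); pw <- (n^2 - nnz) / nnz; nrm <- n^2 / (2 * (n^2 - nnz))

  lossfn <- function(p) {
    pre <- an %*% x %*% p$W0; h1 <- pmax(pre, 0); ah1 <- an %*% h1
    mu <- ah1 %*% p$W_mu; ls <- ah1 %*% p$W_sigma
    z <- mu + exp(ls) * eps_mat
    vgae_loss(a, list(mu = mu, log_sigma = ls), z)$total
  }
  # analytic gradient, same algebra as the training loop
  pre <- an %*% x %*% params$W0; h1 <- pmax(pre, 0); ah1 <- an %*% h1
  mu <- ah1 %*% params$W_mu; ls <- ah1 %*% params$W_sigma; sg <- exp(ls)
  z <- mu + sg * eps_mat
  p <- plogis(tcrossprod(z))
  g_s <- nrm / n^2 * (pw * a * (p - 1) + (1 - a) * p)
  g_z <- (g_s + t(g_s)) %*% z
  g_mu <- g_z + mu / n
  g_ls <- g_z * eps_mat * sg + (sg^2 - 1) / n
  grads <- list(
    W0 = crossprod(an %*% x, ((an %*% g_mu) %*% t(params$W_mu) +
                                (an %*% g_ls) %*% t(params$W_sigma)) * (pre > 0)),
    W_mu = crossprod(ah1, g_mu),
    W_sigma = crossprod(ah1, g_ls))
  for (nm in names(params)) {
    num <- params[[nm]] * 0
    for (i in seq_along(num)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + 1e-6
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - 1e-6
      num[i] <- (lossfn(pp) - lossfn(pm)) / 2e-6
    }
    expect_equal(as.matrix(grads[[nm]]), num, tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  g <- random_attributed_graph(n = 30, r = 10, p = 0.3, seed = 60)
  fit <- vgae(g, hidden = 16, latent = 8, epochs = 60, learning_rate = 0.01,
              seed = 2)
  h <- fit$loss_history
  expect_lt(h$total[nrow(h)], h$total[1])
  fit2 <- vgae(g, hidden = 16, latent = 8, epochs = 60, learning_rate = 0.01,
               seed = 2)
  expect_equal(fit$mu, fit2$mu, tolerance = 1e-6)

  # epochs = 0 returns the untrained encoder's mean
  fit0 <- vgae(g, hidden = 16, latent = 8, epochs = 0, seed = 2)
  set.seed(2)
  params <- list(W0 = goembed:::glorot_init(10, 16),
                 W_mu = goembed:::glorot_init(16, 8),
                 W_sigma = goembed:::glorot_init(16, 8))
  expect_equal(unname(fit0$mu),
               unname(gcn_forward(g$attributes, g$adj_norm, params)$mu))
})

test_that("embedding concatenation checks alignment and orders blocks", {
  a <- matrix(1:4, 2, dimnames = list(c("p1", "p2"), NULL))
  b <- matrix(5:8, 2, dimnames = list(c("p1", "p2"), NULL))
  expect_equal(unname(concat_embeddings(a, b)[1, ]), c(1, 3, 5, 7))
  expect_equal(ncol(concat_embeddings(a[0, , drop = FALSE],
                                      b[0, , drop = FALSE])), 4)
  rownames(b) <- c("p2", "p1")
  expect_error(concat_embeddings(a, b), "indices")
  expect_error(concat_embeddings(a, b[1, , drop = FALSE]), "row counts")
})
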