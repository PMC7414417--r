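# Variational graph auto-encoder: two-layer GCN encoder to per-node Gaussian
# latents, inner-product decoder, ELBO cost, full-batch Adam training.
# Gradients are hand-derived; see the methods vignette for the algebra and
# tests/testthat/test-vgae.R for the finite-difference check.

#' Glorot (Xavier) uniform weight initialization
#'
#' Draws from uniform(-b, b) with `b = sqrt(6 / (fan_in + fan_out))`.
#'
#' @param fan_in,fan_out Matrix dimensions.
#' @return `fan_in` x `fan_out` numeric matrix.
#' @keywords internal
glorot_init <- function(fan_in, fan_out) {
  b <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out)
}

#' Two-layer GCN encoder forward pass
#'
#' Computes the per-node Gaussian parameters
#' `mu = A_norm %*% ReLU(A_norm %*% X %*% W0) %*% W_mu` and the analogous
#' `log_sigma` with `W_sigma`: one shared first graph-convolution layer and
#' two second-layer heads.
#'
#' @param x N x R attribute matrix.
#' @param a_norm Symmetrically normalized adjacency (with self-loops).
#' @param params List with matrices `W0` (R x H), `W_mu`, `W_sigma` (H x K).
#' @return List with `mu` and `log_sigma` (N x K matrices).
#' @export
gcn_forward <- function(x, a_norm, params) {
  fw <- gcn_forward_cache(x, a_norm, params)
  out <- list(mu = fw$mu, log_sigma = fw$log_sigma)
  if (!all(is.finite(out$mu)) || !all(is.finite(out$log_sigma)))
    stop("non-finite encoder output (exploding weights?)")
  out
}

# forward pass keeping intermediates needed for backprop
gcn_forward_cache <- function(x, a_norm, params) {
  ax <- as.matrix(a_norm %*% x)
  pre <- ax %*% params$W0
  h1 <- pmax(pre, 0)
  ah1 <- as.matrix(a_norm %*% h1)
  list(mu = ah1 %*% params$W_mu,
       log_sigma = ah1 %*% params$W_sigma,
       pre = pre, h1 = h1, ah1 = ah1, ax = ax)
}

#' Reparameterized sample from the latent distribution
#'
#' Draws `Z = mu + exp(log_sigma) * epsilon` with `epsilon ~ N(0, I)`,
#' elementwise.
#'
#' @param dist List with `mu` and `log_sigma` (from [gcn_forward()]).
#' @param seed Optional integer seed for the draw.
#' @param epsilon Optional pre-drawn noise matrix (overrides `seed`); pass
#'   zeros to get `Z = mu` deterministically.
#' @return List with `z` and `epsilon`.
#' @export
sample_latent <- function(dist, seed = NULL, epsilon = NULL) {
  if (is.null(epsilon)) {
    if (!is.null(seed)) set.seed(seed)
    epsilon <- matrix(stats::rnorm(length(dist$mu)), nrow(dist$mu))
  }
  list(z = dist$mu + exp(dist$log_sigma) * epsilon, epsilon = epsilon)
}

#' Inner-product decoder
#'
#' Reconstructs edge probabilities `p(A_ij = 1) = logistic(z_i . z_j)` for
#' all node pairs.
#'
#' @param z N x K latent matrix.
#' @return N x N symmetric matrix with entries in (0, 1).
#' @export
decode_links <- function(z) {
  plogis(tcrossprod(z))
}

#' Negative ELBO of the variational graph auto-encoder
#'
#' Reconstruction term: binary cross-entropy between the decoded edge
#' probabilities and the adjacency over all N^2 entries, with positive
#' entries up-weighted by `pos_weight` and the whole term scaled by `norm`
#' (defaults reproduce the usual sparse-graph weighting
#' `pos_weight = (N^2 - nnz) / nnz`, `norm = N^2 / (2 (N^2 - nnz))`).
#' KL term: `(1/N) * 0.5 * sum(mu^2 + sigma^2 - 1 - 2 log sigma)`, the
#' divergence from the standard-normal prior averaged per node. The total is
#' the minimized quantity (negative ELBO).
#'
#' @param a Binary adjacency with self-loops (dense or sparse).
#' @param dist Latent distribution (list with `mu`, `log_sigma`).
#' @param z N x K latent sample matrix.
#' @param pos_weight,norm Optional overrides; `pos_weight = 1, norm = 1`
#'   gives the unweighted mean cross-entropy.
#' @return List with `reconstruction`, `kl`, `total`.
#' @export
vgae_loss <- function(a, dist, z, pos_weight = NULL, norm = NULL) {
  a <- as.matrix(a)
  n <- nrow(a)
  nnz <- sum(a)
  if (is.null(pos_weight)) pos_weight <- (n^2 - nnz) / nnz
  if (is.null(norm)) norm <- n^2 / (2 * (n^2 - nnz))
  p <- decode_links(z)
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  recon <- norm * mean(-(pos_weight * a * log(p) + (1 - a) * log(1 - p)))
  sigma2 <- exp(2 * dist$log_sigma)
  kl <- 0.5 / n * sum(dist$mu^2 + sigma2 - 1 - 2 * dist$log_sigma)
  list(reconstruction = recon, kl = kl, total = recon + kl)
}

#' Fit a variational graph auto-encoder to an attributed graph
#'
#' Trains the two-layer GCN encoder and inner-product decoder by full-batch
#' Adam on the negative ELBO, with one reparameterized latent sample per
#' step. The exported embedding is the latent mean matrix `mu`, not a
#' sample. Training is deterministic given `seed`.
#'
#' @param graph An [attributed_graph()].
#' @param hidden Width of the shared first GCN layer (default 800).
#' @param latent Latent dimension K (default 400); the embedding width.
#' @param epochs Full-batch Adam iterations (default 200).
#' @param learning_rate Adam step size (default 0.001).
#' @param kl_warmup Number of initial epochs over which the KL weight ramps
#'   linearly from 0 to 1 (default 50; 0 disables). At initialization the KL
#'   term dwarfs the reconstruction term and can collapse the posterior onto
#'   the prior through a dead ReLU layer before any structure is learned;
#'   warming the regularizer in is the standard guard. The reported loss
#'   history always contains the unweighted terms.
#' @param seed Integer seed controlling initialization and sampling.
#' @param verbose Print the loss every 20 epochs.
#' @return Object of class `vgae`: list with `mu`, `log_sigma`, `weights`,
#'   `loss_history` (data frame epoch/reconstruction/kl/total), `node_index`,
#'   and the call configuration.
#' @seealso [predict.vgae()], [concat_embeddings()]
#' @export
vgae <- function(graph, hidden = 800L, latent = 400L, epochs = 200L,
                 learning_rate = 0.001, kl_warmup = 50L, seed = 1L,
                 verbose = FALSE) {
  stopifnot(inherits(graph, "attributed_graph"),
            hidden >= 1, latent >= 1, epochs >= 0)
  x <- graph$attributes
  a_norm <- graph$adj_norm
  a <- as.matrix(graph$adjacency)
  n <- nrow(a)
  r <- ncol(x)
  nnz <- sum(a)
  pos_weight <- (n^2 - nnz) / nnz
  norm <- n^2 / (2 * (n^2 - nnz))

  set.seed(seed)
  params <- list(W0 = glorot_init(r, hidden),
                 W_mu = glorot_init(hidden, latent),
                 W_sigma = glorot_init(hidden, latent))
  opt <- adam_state(params, learning_rate)
  history <- matrix(NA_real_, nrow = max(epochs, 0L), ncol = 3L)

  ax <- as.matrix(a_norm %*% x)  # constant across epochs
  an <- as.matrix(a_norm)
  fw <- NULL
  for (ep in seq_len(epochs)) {
    pre <- ax %*% params$W0
    h1 <- pmax(pre, 0)
    ah1 <- an %*% h1
    mu <- ah1 %*% params$W_mu
    log_sigma <- ah1 %*% params$W_sigma
    sigma <- exp(log_sigma)
    epsilon <- matrix(stats::rnorm(n * latent), n, latent)
    z <- mu + sigma * epsilon

    p <- plogis(tcrossprod(z))
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    recon <- norm * mean(-(pos_weight * a * log(p) + (1 - a) * log(1 - p)))
    kl <- 0.5 / n * sum(mu^2 + sigma^2 - 1 - 2 * log_sigma)
    total <- recon + kl
    if (!is.finite(total))
      stop("non-finite loss at epoch ", ep, " (recon = ", recon,
           ", kl = ", kl, ")")
    history[ep, ] <- c(recon, kl, total)
    if (verbose && (ep %% 20L == 0L || ep == 1L))
      message(sprintf("epoch %4d  recon %.4f  kl %.4f  total %.4f",
                      ep, recon, kl, total))

    # backprop: d(recon)/dS for S = Z Z^T, then through the encoder;
    # the KL weight ramps in over kl_warmup epochs
    klw <- if (kl_warmup > 0) min(1, ep / kl_warmup) else 1
    g_s <- norm / n^2 * (pos_weight * a * (p - 1) + (1 - a) * p)
    g_z <- (g_s + t(g_s)) %*% z
    g_mu <- g_z + klw * mu / n
    g_ls <- g_z * epsilon * sigma + klw * (sigma^2 - 1) / n
    an_gmu <- an %*% g_mu
    an_gls <- an %*% g_ls
    grads <- list(
      W0 = crossprod(ax, (an_gmu %*% t(params$W_mu) +
                            an_gls %*% t(params$W_sigma)) * (pre > 0)),
      W_mu = crossprod(ah1, g_mu),
      W_sigma = crossprod(ah1, g_ls))
    upd <- adam_step(opt, params, grads)
    params <- upd$params
    opt <- upd$state
  }

  fwd <- gcn_forward_cache(x, a_norm, params)
  mu <- fwd$mu
  rownames(mu) <- graph$node_index
  structure(
    list(mu = mu,
         log_sigma = fwd$log_sigma,
         weights = params,
         loss_history = data.frame(epoch = seq_len(epochs),
                                   reconstruction = history[, 1],
                                   kl = history[, 2],
                                   total = history[, 3]),
         node_index = graph$node_index,
         config = list(hidden = hidden, latent = latent, epochs = epochs,
                       learning_rate = learning_rate, kl_warmup = kl_warmup,
                       seed = seed,
                       pos_weight = pos_weight, norm = norm)),
    class = "vgae")
}

# Adam optimizer over a named list of weight matrices
adam_state <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- state$beta1 * state$m[[k]] + (1 - state$beta1) * grads[[k]]
    state$v[[k]] <- state$beta2 * state$v[[k]] + (1 - state$beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] - state$lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + state$eps)
  }
  list(state = state, params = params)
}

#' @export
#' @method print vgae
print.vgae <- function(x, ...) {
  cat("Variational graph auto-encoder\n")
  cat("  nodes:", nrow(x$mu), " latent dim:", ncol(x$mu),
      " hidden:", x$config$hidden, "\n")
  cat("  epochs:", x$config$epochs, " final loss:",
      if (x$config$epochs > 0)
        formatC(utils::tail(x$loss_history$total, 1), digits = 4)
      else "(untrained)", "\n")
  invisible(x)
}

#' @export
#' @method summary vgae
summary.vgae <- function(object, ...) {
  print(object)
  if (object$config$epochs > 0) {
    h <- object$loss_history
    cat("  loss epoch 1:", formatC(h$total[1], digits = 4),
        " epoch", nrow(h), ":", formatC(h$total[nrow(h)], digits = 4), "\n")
  }
  cat("  mean |mu|:", formatC(mean(abs(object$mu)), digits = 4), "\n")
  invisible(object)
}

#' @export
#' @method coef vgae
coef.vgae <- function(object, ...) object$weights

#' Predict from a fitted VGAE
#'
#' `type = "embedding"` returns the latent mean matrix (the per-protein
#' embedding); `type = "links"` returns the decoded N x N edge-probability
#' matrix `logistic(mu mu^T)`.
#'
#' @param object A fitted [vgae()].
#' @param type `"embedding"` or `"links"`.
#' @param ... Unused.
#' @export
predict.vgae <- function(object, type = c("embedding", "links"), ...) {
  type <- match.arg(type)
  if (type == "embedding") return(object$mu)
  p <- decode_links(object$mu)
  dimnames(p) <- list(object$node_index, object$node_index)
  p
}

#' Plot the VGAE training loss
#'
#' @param x A fitted [vgae()].
#' @param ... Passed to [graphics::plot()].
#' @export
#' @method plot vgae
plot.vgae <- function(x, ...) {
  h <- x$loss_history
  graphics::plot(h$epoch, h$total, type = "l", xlab = "epoch",
                 ylab = "negative ELBO", ...)
  graphics::lines(h$epoch, h$reconstruction, lty = 2)
  graphics::legend("topright", c("total", "reconstruction"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

#' Concatenate two embedding matrices over one protein index
#'
#' Column-binds the PPI-network embedding and the sequence-similarity-network
#' embedding (PPI block first) after checking row alignment.
#'
#' @param mu_ppi,mu_ssn N x K matrices with identical rownames.
#' @return N x 2K matrix.
#' @export
concat_embeddings <- function(mu_ppi, mu_ssn) {
  if (nrow(mu_ppi) != nrow(mu_ssn))
    stop("embedding row counts differ")
  if (!is.null(rownames(mu_ppi)) && !is.null(rownames(mu_ssn)) &&
      !identical(rownames(mu_ppi), rownames(mu_ssn)))
    stop("embedding protein indices differ")
  cbind(mu_ppi, mu_ssn)
}

#' Hold out a fraction of edges for link-prediction evaluation
#'
#' Removes `fraction` of the off-diagonal edges (sampled without replacement)
#' from a binary adjacency and samples an equal number of non-edges, for
#' evaluating decoded edge probabilities on unseen pairs.
#'
#' @param a Symmetric binary adjacency (self-loops allowed; ignored).
#' @param fraction Fraction of edges to hold out.
#' @param seed Integer seed.
#' @return List with `train` (adjacency minus held-out edges), `heldout`
#'   (m x 2 index matrix of removed edges) and `negatives` (m x 2 index
#'   matrix of sampled non-edges).
#' @export
holdout_edges <- function(a, fraction = 0.1, seed = 1L) {
  set.seed(seed)
  am <- as.matrix(a)
  diag(am) <- 0
  ut <- which(upper.tri(am) & am > 0, arr.ind = TRUE)
  m <- max(1L, round(fraction * nrow(ut)))
  pick <- sample(nrow(ut), m)
  held <- ut[pick, , drop = FALSE]
  train <- am
  train[held] <- 0
  train[held[, c(2, 1), drop = FALSE]] <- 0
  non <- which(upper.tri(am) & am == 0, arr.ind = TRUE)
  neg <- non[sample(nrow(non), min(m, nrow(non))), , drop = FALSE]
  list(train = Matrix::Matrix(train, sparse = TRUE), heldout = held,
       negatives = neg)
}

#' Ranking AUC of positive versus negative scores
#'
#' Mann-Whitney AUC: the probability that a randomly chosen positive scores
#' above a randomly chosen negative (ties count one half).
#'
#' @param pos,neg Numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
ranking_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
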