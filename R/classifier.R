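# Multi-label feed-forward classifier on concatenated embeddings: for each
# hidden layer, dense -> batch normalization -> ReLU -> dropout; output layer
# dense -> elementwise logistic; binary cross-entropy; full-batch Adam.

#' Fit the multi-label GO-term classifier
#'
#' A feed-forward network mapping per-protein embedding vectors to
#' probabilities for every GO term of one namespace. Hidden layers (defaults
#' 1024, 512, 256) each apply a dense map, batch normalization, ReLU and
#' dropout (rate 0.3); the output layer applies an elementwise logistic, and
#' training minimizes the mean binary cross-entropy over all (protein, term)
#' entries with full-batch Adam (default 100 iterations, learning rate
#' 0.001). One classifier is trained per ontology namespace; this function
#' never sees labels from another namespace.
#'
#' @param x N x D numeric matrix of embeddings (rows = proteins).
#' @param y N x F binary label matrix, rows aligned with `x`.
#' @param hidden Integer vector of hidden-layer widths.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param epochs Full-batch Adam iterations.
#' @param learning_rate Adam step size.
#' @param seed Integer seed (initialization and dropout masks).
#' @param verbose Print the loss every 20 epochs.
#' @return Object of class `go_mlp` with elements `layers`, `loss_history`,
#'   `term_index`, `config`.
#' @seealso [predict.go_mlp()], [threshold_predictions()]
#' @export
mlp_classifier <- function(x, y, hidden = c(1024L, 512L, 256L),
                           dropout = 0.3, epochs = 100L,
                           learning_rate = 0.001, seed = 1L,
                           verbose = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y))
    stop("embedding and label row counts differ")
  if (ncol(x) == 0L) stop("zero-width embedding input")
  stopifnot(dropout >= 0, dropout < 1, all(hidden > 0))
  n <- nrow(x); nf <- ncol(y)

  set.seed(seed)
  widths <- c(ncol(x), hidden)
  layers <- vector("list", length(hidden))
  for (l in seq_along(hidden)) {
    layers[[l]] <- list(
      W = glorot_init(widths[l], widths[l + 1]),
      b = rep(0, widths[l + 1]),
      gamma = rep(1, widths[l + 1]),
      beta = rep(0, widths[l + 1]),
      run_mean = rep(0, widths[l + 1]),
      run_var = rep(1, widths[l + 1]))
  }
  out_layer <- list(W = glorot_init(widths[length(widths)], nf),
                    b = rep(0, nf))

  flat <- function() c(lapply(layers, function(l) l[c("W", "b", "gamma", "beta")]),
                       list(out = out_layer))
  params <- unlist_params(flat())
  opt <- adam_state(params, learning_rate)
  history <- numeric(epochs)
  bn_eps <- 1e-5
  momentum <- 0.9

  for (ep in seq_len(epochs)) {
    caches <- vector("list", length(layers))
    h <- x
    for (l in seq_along(layers)) {
      ly <- layers[[l]]
      pre <- sweep(h %*% ly$W, 2, ly$b, "+")
      mu <- colMeans(pre)
      va <- colMeans(sweep(pre, 2, mu)^2)
      sd <- sqrt(va + bn_eps)
      xhat <- sweep(sweep(pre, 2, mu), 2, sd, "/")
      bn <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
      act <- pmax(bn, 0)
      if (dropout > 0) {
        mask <- matrix(stats::runif(length(act)) >= dropout, n) / (1 - dropout)
      } else mask <- 1
      out <- act * mask
      layers[[l]]$run_mean <- momentum * ly$run_mean + (1 - momentum) * mu
      layers[[l]]$run_var <- momentum * ly$run_var + (1 - momentum) * va
      caches[[l]] <- list(input = h, pre = pre, xhat = xhat, sd = sd,
                          bn = bn, mask = mask)
      h <- out
    }
    logits <- sweep(h %*% out_layer$W, 2, out_layer$b, "+")
    p <- plogis(logits)
    pc <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
    if (!is.finite(loss)) stop("non-finite classifier loss at epoch ", ep)
    history[ep] <- loss
    if (verbose && (ep %% 20L == 0L || ep == 1L))
      message(sprintf("epoch %4d  bce %.5f", ep, loss))

    dlogits <- (p - y) / (n * nf)
    grads <- list(out = list(W = crossprod(h, dlogits), b = colSums(dlogits)))
    dh <- tcrossprod(dlogits, out_layer$W)
    for (l in rev(seq_along(layers))) {
      cc <- caches[[l]]
      ly <- layers[[l]]
      dact <- dh * cc$mask
      dbn <- dact * (cc$bn > 0)
      dgamma <- colSums(dbn * cc$xhat)
      dbeta <- colSums(dbn)
      dxhat <- sweep(dbn, 2, ly$gamma, "*")
      # batch-norm backward (population variance, 1/n)
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * cc$xhat)
      dpre <- (dxhat - matrix(m1, n, length(m1), byrow = TRUE) -
                 cc$xhat * matrix(m2, n, length(m2), byrow = TRUE))
      dpre <- sweep(dpre, 2, cc$sd, "/")
      grads[[paste0("layer", l)]] <- list(
        W = crossprod(cc$input, dpre),
        b = colSums(dpre),
        gamma = dgamma, beta = dbeta)
      dh <- tcrossprod(dpre, ly$W)
    }

    gradvec <- unlist_params(c(
      lapply(seq_along(layers),
             function(l) grads[[paste0("layer", l)]][c("W", "b", "gamma", "beta")]),
      list(out = grads$out)))
    upd <- adam_step(opt, params, gradvec)
    params <- upd$params
    opt <- upd$state
    refit <- refit_params(params, layers, out_layer)
    layers <- refit$layers
    out_layer <- refit$out_layer
  }

  structure(
    list(layers = layers, out_layer = out_layer,
         loss_history = data.frame(epoch = seq_len(epochs), bce = history),
         term_index = colnames(y),
         config = list(hidden = hidden, dropout = dropout, epochs = epochs,
                       learning_rate = learning_rate, seed = seed,
                       input_width = ncol(x), output_width = nf,
                       bn_eps = bn_eps)),
    class = "go_mlp")
}

# flatten / restore named parameter lists so one Adam state covers all layers
unlist_params <- function(lst) {
  out <- list()
  for (i in seq_along(lst)) {
    nm <- if (!is.null(names(lst)) && nzchar(names(lst)[i] %||% ""))
      names(lst)[i] else paste0("layer", i)
    for (k in names(lst[[i]]))
      out[[paste0(nm, ".", k)]] <- lst[[i]][[k]]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

refit_params <- function(params, layers, out_layer) {
  for (l in seq_along(layers)) {
    for (k in c("W", "b", "gamma", "beta"))
      layers[[l]][[k]] <- params[[paste0("layer", l, ".", k)]]
  }
  out_layer$W <- params[["out.W"]]
  out_layer$b <- params[["out.b"]]
  list(layers = layers, out_layer = out_layer)
}

#' @export
#' @method print go_mlp
print.go_mlp <- function(x, ...) {
  cat("Multi-label GO classifier (feed-forward)\n")
  cat("  architecture:", x$config$input_width, "->",
      paste(x$config$hidden, collapse = " -> "), "->",
      x$config$output_width, "\n")
  cat("  dropout:", x$config$dropout, " epochs:", x$config$epochs,
      " final BCE:",
      if (x$config$epochs > 0)
        formatC(utils::tail(x$loss_history$bce, 1), digits = 5)
      else "(untrained)", "\n")
  invisible(x)
}

#' Predict GO-term probabilities
#'
#' Deterministic inference pass: dropout disabled, batch normalization using
#' the running moments accumulated during training.
#'
#' @param object A fitted [mlp_classifier()].
#' @param x Embedding matrix with the training input width.
#' @param ... Unused.
#' @return N x F matrix of probabilities in `[0, 1]`, columns named by term.
#' @export
predict.go_mlp <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$config$input_width)
    stop("embedding width ", ncol(x), " does not match trained width ",
         object$config$input_width)
  h <- x
  for (ly in object$layers) {
    pre <- sweep(h %*% ly$W, 2, ly$b, "+")
    xhat <- sweep(sweep(pre, 2, ly$run_mean),
                  2, sqrt(ly$run_var + object$config$bn_eps), "/")
    bn <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    h <- pmax(bn, 0)
  }
  p <- plogis(sweep(h %*% object$out_layer$W, 2, object$out_layer$b, "+"))
  rownames(p) <- rownames(x)
  colnames(p) <- object$term_index
  p
}

#' Threshold a score matrix into binary predictions
#'
#' A (protein, term) pair is predicted iff its probability is greater than or
#' equal to `t` (ties at the threshold count as predicted, so `t = 0`
#' predicts everything).
#'
#' @param scores Numeric matrix of probabilities.
#' @param t Threshold in `[0, 1]`.
#' @return Binary integer matrix of the same shape.
#' @export
threshold_predictions <- function(scores, t = 0.5) {
  stopifnot(t >= 0, t <= 1)
  out <- (scores >= t) + 0L
  dimnames(out) <- dimnames(scores)
  out
}
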