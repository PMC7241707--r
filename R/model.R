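BRANCHES <- c("fused", "gmf_only", "nn_only")
ACTIVATIONS <- c(relu = 0L, tanh = 1L, sigmoid = 2L)

#' Model and training configuration
#'
#' Defaults follow the reference training protocol: 32 latent factors in
#' every embedding layer, a 64/32/16 tower network with rectifier
#' activations and dropout keep probability 0.7, Huber loss with threshold
#' `delta = 0.1`, Adam with learning rate 3e-4, minibatches of 16, and up
#' to 70,000 gradient steps (an iteration is one minibatch update).
#'
#' @param k1 Latent factors of the GMF inbred/tester embeddings.
#' @param k2 Latent factors of the NN inbred/tester embeddings.
#' @param kg,kl Latent factors of the genetic-group / location embeddings.
#' @param nn_layers Integer widths of the tower network's hidden layers.
#' @param activation One of `"relu"`, `"tanh"`, `"sigmoid"`.
#' @param dropout_keep Keep probability in (0, 1]; inverted-dropout scaling
#'   is used, so evaluation mode needs no rescaling.
#' @param delta Huber-loss threshold (> 0).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size; the epoch-end remainder is used as a
#'   short batch.
#' @param max_iterations Number of minibatch gradient steps.
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @param use_parent_ids If `FALSE`, the NN branch sees only the group and
#'   location embeddings (the coarse, no-fine-details model); requires
#'   `branch = "nn_only"`.
#' @param branch `"fused"` (GMF + NN ensemble), `"gmf_only"`, or
#'   `"nn_only"`.
#' @param pretrain If `TRUE`, [fit_predictor()] uses the two-stage
#'   embedding pre-training protocol.
#' @param standardize If `TRUE`, train on centered/scaled yields and map
#'   predictions back to the original scale.
#' @param log_every Record the running training loss every this many
#'   iterations.
#' @return A list of class `ncf_config`.
#' @export
model_config <- function(k1 = 32, k2 = 32, kg = 32, kl = 32,
                         nn_layers = c(64, 32, 16), activation = "relu",
                         dropout_keep = 0.7, delta = 0.1,
                         learning_rate = 3e-4, batch_size = 16,
                         max_iterations = 70000, seed = 1,
                         use_parent_ids = TRUE, branch = "fused",
                         pretrain = FALSE, standardize = FALSE,
                         log_every = 500) {
  branch <- match.arg(branch, BRANCHES)
  activation <- match.arg(activation, names(ACTIVATIONS))
  cfg <- list(k1 = as.integer(k1), k2 = as.integer(k2), kg = as.integer(kg),
              kl = as.integer(kl), nn_layers = as.integer(nn_layers),
              activation = activation, dropout_keep = dropout_keep,
              delta = delta, learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_iterations = as.integer(max_iterations),
              seed = as.integer(seed), use_parent_ids = isTRUE(use_parent_ids),
              branch = branch, pretrain = isTRUE(pretrain),
              standardize = isTRUE(standardize),
              log_every = as.integer(log_every))
  stopifnot(cfg$k1 >= 1, cfg$k2 >= 1, cfg$kg >= 1, cfg$kl >= 1,
            length(cfg$nn_layers) >= 1, all(cfg$nn_layers >= 1),
            cfg$dropout_keep > 0, cfg$dropout_keep <= 1, cfg$delta > 0,
            cfg$learning_rate >= 0, cfg$batch_size >= 1,
            cfg$max_iterations >= 0)
  if (!cfg$use_parent_ids && cfg$branch != "nn_only") {
    stop("use_parent_ids = FALSE requires branch = 'nn_only' (the GMF ",
         "branch is undefined without parent IDs)")
  }
  class(cfg) <- "ncf_config"
  cfg
}

nn_input_dim <- function(config) {
  if (config$use_parent_ids) 2L * config$k2 + config$kg + config$kl else
    config$kg + config$kl
}

# Xavier/Glorot uniform draw for a fan_in x fan_out linear map, stored with
# the requested (nrow, ncol) orientation
xavier <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize model parameters with the Xavier method
#'
#' Every weight matrix is drawn Xavier-uniform (variance 2 / (fan_in +
#' fan_out)); biases start at zero. Embedding matrices of shape `n x k` use
#' fan_in `n`, fan_out `k`; tower layers use their input/output widths.
#'
#' @param config An [model_config()].
#' @param enc A `cross_encoding` supplying the cardinalities.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list of class `ncf_parameters`: `W1b`, `W1t`, `h`, `W2b`,
#'   `W2t`, `Wg`, `Wl`, `nn_W`, `nn_b`, `nn_head_w`, `nn_head_b`,
#'   `fusion_W`, `fusion_b`.
#' @export
init_parameters <- function(config, enc, seed = config$seed) {
  stopifnot(inherits(config, "ncf_config"), inherits(enc, "cross_encoding"))
  if (enc$n_b < 1 || enc$n_t < 1 || enc$n_g < 1 || enc$n_l < 1) {
    stop("encoding has a zero cardinality")
  }
  d_in <- nn_input_dim(config)
  widths <- c(d_in, config$nn_layers)
  local_seed(seed, {
    params <- list(
      W1b = xavier(enc$n_b, config$k1, enc$n_b, config$k1),
      W1t = xavier(enc$n_t, config$k1, enc$n_t, config$k1),
      h = as.numeric(xavier(config$k1, 1, config$k1, 1)),
      W2b = xavier(enc$n_b, config$k2, enc$n_b, config$k2),
      W2t = xavier(enc$n_t, config$k2, enc$n_t, config$k2),
      Wg = xavier(enc$n_g, config$kg, enc$n_g, config$kg),
      Wl = xavier(enc$n_l, config$kl, enc$n_l, config$kl),
      nn_W = lapply(seq_along(config$nn_layers), function(j) {
        xavier(widths[j + 1], widths[j], widths[j], widths[j + 1])
      }),
      nn_b = lapply(config$nn_layers, function(w) numeric(w)),
      nn_head_w = as.numeric(xavier(
        config$nn_layers[length(config$nn_layers)], 1,
        config$nn_layers[length(config$nn_layers)], 1)),
      nn_head_b = 0,
      fusion_W = as.numeric(xavier(2, 1, 2, 1)),
      fusion_b = 0
    )
    class(params) <- "ncf_parameters"
    params
  })
}

#' Embedding lookup
#'
#' Returns row `index` of an embedding matrix; contractually equal to the
#' product of the corresponding one-hot row vector with the matrix.
#'
#' @param matrix An embedding matrix (`n x k`).
#' @param index 0-based row index (vectorized).
#' @return The embedded vector(s); a vector for a single index, otherwise a
#'   matrix with one row per index.
#' @export
embed_lookup <- function(matrix, index) {
  if (any(index < 0 | index >= nrow(matrix))) {
    stop("embedding index out of range [0, ", nrow(matrix) - 1, "]")
  }
  matrix[index + 1L, , drop = length(index) == 1L]
}

#' GMF branch forward pass
#'
#' Computes `q_GMF = (d1b * d1t) . h`, the h-weighted element-wise product
#' of the GMF inbred and tester embeddings. With `h` all ones this is
#' classical matrix factorization.
#'
#' @param params An `ncf_parameters`.
#' @param b,t 0-based inbred / tester indices (vectorized, equal length).
#' @return Numeric vector of branch outputs.
#' @export
gmf_forward <- function(params, b, t) {
  D1b <- params$W1b[b + 1L, , drop = FALSE]
  D1t <- params$W1t[t + 1L, , drop = FALSE]
  as.numeric((D1b * D1t) %*% params$h)
}

apply_activation <- function(z, activation) {
  switch(activation,
         relu = pmax(z, 0),
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)))
}

#' Neural-network branch forward pass (reference implementation)
#'
#' Concatenates the NN inbred, tester, group and location embeddings (group
#' and location only when `use_parent_ids` is `FALSE`), applies the tower
#' layers, and reduces the last hidden layer to the scalar `q_NN` through
#' the branch's output head. In training mode, inverted dropout with keep
#' probability `config$dropout_keep` follows each hidden activation (drawn
#' from R's RNG stream). This pure-R pass mirrors the compiled trainer and
#' serves as its cross-check.
#'
#' @param params An `ncf_parameters`.
#' @param config An `ncf_config`.
#' @param b,t,g,l 0-based indices (vectorized, equal length).
#' @param train_mode If `TRUE`, apply dropout.
#' @return Numeric vector of branch outputs.
#' @export
nn_forward <- function(params, config, b, t, g, l, train_mode = FALSE) {
  X <- if (config$use_parent_ids) {
    cbind(params$W2b[b + 1L, , drop = FALSE],
          params$W2t[t + 1L, , drop = FALSE],
          params$Wg[g + 1L, , drop = FALSE],
          params$Wl[l + 1L, , drop = FALSE])
  } else {
    cbind(params$Wg[g + 1L, , drop = FALSE],
          params$Wl[l + 1L, , drop = FALSE])
  }
  A <- t(X)
  for (j in seq_along(params$nn_W)) {
    Z <- params$nn_W[[j]] %*% A + params$nn_b[[j]]
    A <- apply_activation(Z, config$activation)
    if (train_mode && config$dropout_keep < 1) {
      keep <- config$dropout_keep
      M <- matrix(stats::runif(length(A)) < keep, nrow(A), ncol(A)) / keep
      A <- A * M
    }
  }
  as.numeric(crossprod(params$nn_head_w, A)) + params$nn_head_b
}

#' Full-model forward pass (reference implementation)
#'
#' `fused`: `yhat = fusion_W . [q_GMF, q_NN] + fusion_b`; `gmf_only` /
#' `nn_only` return the respective branch scalar directly.
#'
#' @inheritParams nn_forward
#' @return Numeric vector of predictions.
#' @export
fused_forward <- function(params, config, b, t, g, l, train_mode = FALSE) {
  switch(config$branch,
         gmf_only = gmf_forward(params, b, t),
         nn_only = nn_forward(params, config, b, t, g, l, train_mode),
         fused = {
           qg <- gmf_forward(params, b, t)
           qn <- nn_forward(params, config, b, t, g, l, train_mode)
           params$fusion_W[1] * qg + params$fusion_W[2] * qn +
             params$fusion_b
         })
}

#' Huber loss
#'
#' Elementwise robust loss: `0.5 r^2` for residuals `|r| <= delta`, and
#' `delta |r| - 0.5 delta^2` beyond; continuous and once-differentiable at
#' the knot. The training objective is the mean of this loss over a
#' minibatch.
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length).
#' @param delta Threshold, > 0.
#' @return Numeric vector of elementwise losses.
#' @export
huber_loss <- function(y, yhat, delta = 0.1) {
  if (delta <= 0) stop("delta must be positive")
  if (length(y) != length(yhat) && length(y) != 1L && length(yhat) != 1L) {
    stop("length mismatch")
  }
  r <- abs(y - yhat)
  ifelse(r <= delta, 0.5 * r^2, delta * r - 0.5 * delta^2)
}
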