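# modal observed genetic group per inbred, with a global-modal fallback for
# inbreds never observed in the training data; used to resolve the group
# input when predicting unobserved combinations
modal_group_map <- function(dataset, enc) {
  tab <- table(factor(dataset$b, levels = 0:(enc$n_b - 1)),
               factor(dataset$g, levels = 0:(enc$n_g - 1)))
  counts_g <- table(factor(dataset$g, levels = 0:(enc$n_g - 1)))
  global_modal <- as.integer(names(counts_g)[which.max(counts_g)])
  per_inbred <- apply(tab, 1, function(r) {
    if (sum(r) == 0) NA_integer_ else as.integer(names(r)[which.max(r)])
  })
  n_fallback <- sum(is.na(per_inbred))
  if (n_fallback > 0) {
    message(n_fallback, " inbred(s) without observed group; ",
            "falling back to the global modal group")
    per_inbred[is.na(per_inbred)] <- global_modal
  }
  unname(per_inbred)
}

scale_y <- function(config, y) {
  if (config$standardize) {
    c(center = mean(y), scale = if (stats::sd(y) > 0) stats::sd(y) else 1)
  } else {
    c(center = 0, scale = 1)
  }
}

new_ncf_model <- function(params, enc, config, history, yc, dataset) {
  structure(list(
    params = params, encoding = enc, config = config, history = history,
    y_center = unname(yc["center"]), y_scale = unname(yc["scale"]),
    group_of_inbred = modal_group_map(dataset, enc)
  ), class = "ncf_model")
}

check_shapes <- function(params, enc, config) {
  ok <- nrow(params$W1b) == enc$n_b && nrow(params$W1t) == enc$n_t &&
    nrow(params$W2b) == enc$n_b && nrow(params$W2t) == enc$n_t &&
    nrow(params$Wg) == enc$n_g && nrow(params$Wl) == enc$n_l &&
    ncol(params$W1b) == config$k1 && ncol(params$W2b) == config$k2
  if (!ok) stop("parameter shapes do not match the encoding/config")
  invisible(TRUE)
}

branch_code <- function(branch) match(branch, BRANCHES) - 1L

# arma column vectors come back from the compiled trainer as n x 1 matrices;
# restore the plain-vector/scalar layout of init_parameters()
normalize_params <- function(params) {
  params$h <- as.numeric(params$h)
  params$nn_b <- lapply(params$nn_b, as.numeric)
  params$nn_head_w <- as.numeric(params$nn_head_w)
  params$nn_head_b <- as.numeric(params$nn_head_b)[1]
  params$fusion_W <- as.numeric(params$fusion_W)
  params$fusion_b <- as.numeric(params$fusion_b)[1]
  params
}

#' Train the collaborative-filtering model
#'
#' Minimizes the mean Huber loss by minibatch Adam (moments 0.9/0.999,
#' epsilon 1e-8), reshuffling each epoch, for `config$max_iterations`
#' gradient steps. Training is single-threaded and bit-reproducible from
#' `config$seed`.
#'
#' @param dataset An `indexed_dataset` encoded against `enc`.
#' @param enc The `cross_encoding`.
#' @param config An [model_config()].
#' @param init Optional `ncf_parameters` to start from; Xavier
#'   initialization from `config$seed` otherwise.
#' @return An object of class `ncf_model`: parameters, encoding, config,
#'   training-loss history (data frame `phase`, `iteration`, `loss`), the
#'   response centering used, and the inbred-to-group resolution map.
#' @export
train_ncf <- function(dataset, enc, config, init = NULL) {
  stopifnot(inherits(dataset, "indexed_dataset"),
            inherits(enc, "cross_encoding"), inherits(config, "ncf_config"))
  if (dataset$N < 1) stop("cannot train on an empty dataset")
  params <- if (is.null(init)) init_parameters(config, enc) else init
  check_shapes(params, enc, config)
  yc <- scale_y(config, dataset$y)
  yt <- (dataset$y - yc["center"]) / yc["scale"]
  fit <- ncf_train_cpp(dataset$b, dataset$t, dataset$g, dataset$l, yt,
                       unclass(params), branch_code(config$branch),
                       config$use_parent_ids,
                       ACTIVATIONS[[config$activation]],
                       config$dropout_keep, config$delta,
                       config$learning_rate, config$batch_size,
                       config$max_iterations, config$seed, config$log_every)
  params <- structure(normalize_params(fit$params), class = "ncf_parameters")
  history <- data.frame(phase = rep(config$branch, length(fit$iteration)),
                        iteration = as.numeric(fit$iteration),
                        loss = as.numeric(fit$loss))
  new_ncf_model(params, enc, config, history, yc, dataset)
}

#' Two-stage pre-training followed by fused training
#'
#' Trains a GMF-only model and an NN-only model separately from Xavier
#' initializations, then builds a fused model whose GMF embeddings and `h`
#' come from the first phase and whose NN embeddings, tower weights and
#' output head come from the second, with a freshly Xavier-initialized
#' fusion layer, and trains it. Phase seeds are `seed`, `seed + 1`,
#' `seed + 2`.
#'
#' @inheritParams train_ncf
#' @param fused_iterations Optional override of `config$max_iterations` for
#'   the final fused phase (0 returns the stitched initialization
#'   untrained).
#' @return The fused `ncf_model`; its `history` stacks the three phases
#'   (`gmf_only`, `nn_only`, `fused`).
#' @export
pretrain_then_train <- function(dataset, enc, config,
                                fused_iterations = NULL) {
  stopifnot(inherits(config, "ncf_config"))
  if (config$branch != "fused") stop("pre-training applies to the fused model")
  cfg_gmf <- config
  cfg_gmf$branch <- "gmf_only"
  cfg_nn <- config
  cfg_nn$branch <- "nn_only"
  cfg_nn$seed <- config$seed + 1L
  m_gmf <- train_ncf(dataset, enc, cfg_gmf)
  m_nn <- train_ncf(dataset, enc, cfg_nn)

  cfg_f <- config
  cfg_f$seed <- config$seed + 2L
  if (!is.null(fused_iterations)) {
    cfg_f$max_iterations <- as.integer(fused_iterations)
  }
  init <- init_parameters(cfg_f, enc)
  init$W1b <- m_gmf$params$W1b
  init$W1t <- m_gmf$params$W1t
  init$h <- m_gmf$params$h
  init$W2b <- m_nn$params$W2b
  init$W2t <- m_nn$params$W2t
  init$Wg <- m_nn$params$Wg
  init$Wl <- m_nn$params$Wl
  init$nn_W <- m_nn$params$nn_W
  init$nn_b <- m_nn$params$nn_b
  init$nn_head_w <- m_nn$params$nn_head_w
  init$nn_head_b <- m_nn$params$nn_head_b
  fused <- train_ncf(dataset, enc, cfg_f, init = init)
  fused$history <- rbind(m_gmf$history, m_nn$history, fused$history)
  fused$config$pretrain <- TRUE
  fused
}

#' Predict yields for explicit (inbred, tester, group, location) inputs
#'
#' Deterministic evaluation-mode forward pass (no dropout) through the
#' compiled backend.
#'
#' @param model An `ncf_model`.
#' @param b,t,g,l 0-based index vectors of equal length.
#' @return Numeric vector of predicted yields on the original scale.
#' @export
predict_observations <- function(model, b, t, g, l) {
  UseMethod("predict_observations")
}

#' @export
predict_observations.ncf_model <- function(model, b, t, g, l) {
  raw <- ncf_predict_cpp(as.integer(b), as.integer(t), as.integer(g),
                         as.integer(l), unclass(model$params),
                         branch_code(model$config$branch),
                         model$config$use_parent_ids,
                         ACTIVATIONS[[model$config$activation]])
  raw * model$y_scale + model$y_center
}

#' Location-averaged pair predictions
#'
#' For each (inbred, tester) pair, predicts the yield at every location in
#' the encoding — resolving the genetic group through the model's
#' modal-group map — and returns the arithmetic mean over locations. This
#' single code path serves both the hold-out evaluation harness and the
#' full prediction matrix, so the two agree bit-for-bit.
#'
#' @param model A fitted model (`ncf_model` or `baseline_model`).
#' @param b,t 0-based pair index vectors of equal length.
#' @param chunk_pairs Pairs per prediction chunk (memory control).
#' @return Numeric vector of location-averaged predictions.
#' @export
predict_pair_means <- function(model, b, t, chunk_pairs = 1024L) {
  enc <- model$encoding
  n_l <- enc$n_l
  g <- model$group_of_inbred[b + 1L]
  out <- numeric(length(b))
  locs <- 0:(n_l - 1L)
  for (s in seq(1L, length(b), by = chunk_pairs)) {
    e <- min(s + chunk_pairs - 1L, length(b))
    nb <- e - s + 1L
    bb <- rep(b[s:e], each = n_l)
    tt <- rep(t[s:e], each = n_l)
    gg <- rep(g[s:e], each = n_l)
    ll <- rep(locs, times = nb)
    p <- predict_observations(model, bb, tt, gg, ll)
    out[s:e] <- rowMeans(matrix(p, nrow = nb, byrow = TRUE))
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding every parameter array, the
#' configuration, the encoding maps and the training history; loading is
#' bit-faithful.
#'
#' @param model An `ncf_model` (or `baseline_model`).
#' @param path Checkpoint path (`.rds`).
#' @return `path` invisibly for save; the model for load.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("ncf_model", "baseline_model"))) {
    stop("not a crossyield checkpoint: ", path)
  }
  model
}

#' @method print ncf_model
#' @export
print.ncf_model <- function(x, ...) {
  cat("ncf_model (branch:", x$config$branch,
      if (!x$config$use_parent_ids) ", coarse: no parent IDs" else "",
      ")\n  encoding:", x$encoding$n_b, "x", x$encoding$n_t,
      "parents,", x$encoding$n_g, "groups,", x$encoding$n_l, "locations\n",
      " trained for", max(x$history$iteration), "iterations; final loss",
      format(x$history$loss[nrow(x$history)], digits = 4), "\n")
  invisible(x)
}
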