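#' Baseline predictor specification
#'
#' Three reference predictors bracket the main model: the training-mean
#' constant predictor, an L1-penalized linear model on the concatenated
#' one-hot blocks `[x_b x_t x_g x_l]`, and second-order factorization
#' machines over the same features trained with the same Adam/Huber loop
#' as the main model.
#'
#' @param kind `"constant_mean"`, `"lasso_linear"`, or `"fm"`.
#' @param l1_coef L1 penalty for the lasso (glmnet's `lambda` on the
#'   objective `(1/2N) RSS + lambda * |beta|_1`); default 0.8.
#' @param fm_k Latent dimension of the FM pairwise factors.
#' @param learning_rate,batch_size,max_iterations,delta FM training
#'   hyperparameters (defaults match the main model's).
#' @param seed Integer seed.
#' @return A list of class `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("constant_mean", "lasso_linear", "fm"),
                          l1_coef = 0.8, fm_k = 32, learning_rate = 3e-4,
                          batch_size = 16, max_iterations = 70000,
                          delta = 0.1, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(l1_coef >= 0, fm_k >= 1)
  structure(list(kind = kind, l1_coef = l1_coef, fm_k = as.integer(fm_k),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations), delta = delta,
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

onehot_matrix <- function(dataset, enc) {
  N <- dataset$N
  offs <- c(0L, enc$n_b, enc$n_b + enc$n_t, enc$n_b + enc$n_t + enc$n_g)
  p <- enc$n_b + enc$n_t + enc$n_g + enc$n_l
  j <- c(dataset$b + offs[1], dataset$t + offs[2], dataset$g + offs[3],
         dataset$l + offs[4]) + 1L
  Matrix::sparseMatrix(i = rep(seq_len(N), 4L), j = j, x = 1,
                       dims = c(N, p))
}

#' Fit a baseline predictor
#'
#' @param spec A [baseline_spec()].
#' @param dataset An `indexed_dataset`.
#' @param enc The matching `cross_encoding`.
#' @return An object of class `baseline_model` supporting
#'   [predict_observations()] and [predict_pair_means()].
#' @export
fit_baseline <- function(spec, dataset, enc) {
  stopifnot(inherits(spec, "baseline_spec"),
            inherits(dataset, "indexed_dataset"))
  if (dataset$N < 1) stop("cannot fit a baseline on an empty dataset")
  fit <- switch(spec$kind,
    constant_mean = list(mean = mean(dataset$y)),
    lasso_linear = {
      X <- onehot_matrix(dataset, enc)
      list(glmnet = glmnet::glmnet(X, dataset$y, alpha = 1,
                                   lambda = spec$l1_coef,
                                   standardize = FALSE))
    },
    fm = {
      k <- spec$fm_k
      init <- local_seed(spec$seed, list(
        w0 = mean(dataset$y),
        wb = numeric(enc$n_b), wt = numeric(enc$n_t),
        wg = numeric(enc$n_g), wl = numeric(enc$n_l),
        Vb = xavier(enc$n_b, k, enc$n_b, k),
        Vt = xavier(enc$n_t, k, enc$n_t, k),
        Vg = xavier(enc$n_g, k, enc$n_g, k),
        Vl = xavier(enc$n_l, k, enc$n_l, k)
      ))
      out <- fm_train_cpp(dataset$b, dataset$t, dataset$g, dataset$l,
                          dataset$y, init, spec$delta, spec$learning_rate,
                          spec$batch_size, spec$max_iterations, spec$seed,
                          500L)
      list(params = out$params,
           history = data.frame(phase = "fm",
                                iteration = as.numeric(out$iteration),
                                loss = as.numeric(out$loss)))
    })
  structure(list(spec = spec, fit = fit, encoding = enc,
                 group_of_inbred = modal_group_map(dataset, enc)),
            class = "baseline_model")
}

#' @export
predict_observations.baseline_model <- function(model, b, t, g, l) {
  spec <- model$spec
  enc <- model$encoding
  switch(spec$kind,
    constant_mean = rep(model$fit$mean, length(b)),
    lasso_linear = {
      ds <- structure(list(b = as.integer(b), t = as.integer(t),
                           g = as.integer(g), l = as.integer(l),
                           N = length(b)),
                      class = "indexed_dataset")
      X <- onehot_matrix(ds, enc)
      as.numeric(stats::predict(model$fit$glmnet, newx = X,
                                s = spec$l1_coef))
    },
    fm = fm_predict_cpp(as.integer(b), as.integer(t), as.integer(g),
                        as.integer(l), model$fit$params))
}

#' FM nested-model check helper: zero out the pairwise factors
#'
#' With all interaction factors zero the FM reduces exactly to its linear
#' part; used to verify the nested-model identity.
#'
#' @param model A fitted FM `baseline_model`.
#' @return The model with `Vb`, `Vt`, `Vg`, `Vl` zeroed.
#' @export
zero_fm_factors <- function(model) {
  stopifnot(inherits(model, "baseline_model"), model$spec$kind == "fm")
  for (nm in c("Vb", "Vt", "Vg", "Vl")) {
    model$fit$params[[nm]][] <- 0
  }
  model
}
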