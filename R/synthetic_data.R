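#' Configuration for the sparse factorial cross-design simulator
#'
#' Defaults emulate the shape of a large commercial corn testcross program:
#' 593 inbreds x 496 testers with 10,919 observed combinations (3.71% of
#' the 294,128 possible pairs), about 18.3 plantings per combination spread
#' over 280 locations, 14 genetic groups, and yields on a normalized scale
#' with mean ~1.002 and standard deviation ~0.105.
#'
#' The generating model for one observation of pair (b, t) at location l is
#' \deqn{y = \mu + loc_l + grp_{g(b)} + U_b \cdot V_t +
#'   \gamma \tanh(U_b \cdot V_t)^2 + \epsilon}
#' with i.i.d. normal latent factors, additive effects, and noise. The
#' \eqn{\tanh^2} term injects a high-order interaction beyond the bilinear
#' structure so a nonlinear learner has something a factorization cannot
#' capture.
#'
#' @param n_b,n_t,n_l,n_g Numbers of inbreds, testers, locations, genetic
#'   groups.
#' @param n_combos Number of distinct (inbred, tester) pairs observed.
#' @param mean_obs_per_combo Poisson mean of plantings per pair (floored at
#'   1 so every sampled pair is observed).
#' @param k_true Latent dimension of the ground-truth factors.
#' @param sigma_latent Std. dev. of latent factor entries.
#' @param sigma_loc,sigma_grp Std. dev. of additive location / group
#'   effects.
#' @param gamma_nonlinear Weight of the high-order \eqn{\tanh^2}
#'   interaction.
#' @param sigma_noise Observation noise std. dev.
#' @param mu Baseline yield (normalized units).
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_b = 593, n_t = 496, n_l = 280, n_g = 14,
                             n_combos = 10919, mean_obs_per_combo = 18.3,
                             k_true = 4, sigma_latent = 0.16,
                             sigma_loc = 0.06, sigma_grp = 0.04,
                             gamma_nonlinear = 0.04, sigma_noise = 0.055,
                             mu = 1.002, seed = 1) {
  cfg <- list(n_b = as.integer(n_b), n_t = as.integer(n_t),
              n_l = as.integer(n_l), n_g = as.integer(n_g),
              n_combos = as.integer(n_combos),
              mean_obs_per_combo = mean_obs_per_combo,
              k_true = as.integer(k_true), sigma_latent = sigma_latent,
              sigma_loc = sigma_loc, sigma_grp = sigma_grp,
              gamma_nonlinear = gamma_nonlinear, sigma_noise = sigma_noise,
              mu = mu, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_b >= 1, n_t >= 1, n_l >= 1, n_g >= 1, k_true >= 1,
              mean_obs_per_combo >= 0, sigma_latent >= 0, sigma_loc >= 0,
              sigma_grp >= 0, gamma_nonlinear >= 0, sigma_noise >= 0)
  })
  if (cfg$n_combos < 1 || cfg$n_combos > cfg$n_b * cfg$n_t) {
    stop("n_combos must be in [1, n_b * n_t]")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

id_labels <- function(prefix, n) {
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

#' Generate a synthetic cross-yield dataset with known ground truth
#'
#' Draws ground-truth latent factors and additive effects, samples
#' `n_combos` distinct (inbred, tester) pairs uniformly without
#' replacement, plants each pair `max(1, Poisson(mean_obs_per_combo))`
#' times at uniformly drawn locations, and emits one noisy yield record per
#' planting. Each inbred carries a fixed genetic group, so the group of a
#' record is determined by its inbred parent.
#'
#' @param config A [synthetic_config()].
#' @return `list(table =, truth =)`: an `observation_table` and a
#'   `ground_truth` list with `U` (`n_b x k_true`), `V` (`n_t x k_true`),
#'   `loc_effects`, `grp_effects`, `group_of_inbred` (0-based), the raw ID
#'   labels aligned with those arrays, and the config.
#' @export
generate_crosses <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  local_seed(cfg$seed, {
    U <- matrix(stats::rnorm(cfg$n_b * cfg$k_true, 0, cfg$sigma_latent),
                cfg$n_b, cfg$k_true)
    V <- matrix(stats::rnorm(cfg$n_t * cfg$k_true, 0, cfg$sigma_latent),
                cfg$n_t, cfg$k_true)
    loc_effects <- stats::rnorm(cfg$n_l, 0, cfg$sigma_loc)
    grp_effects <- stats::rnorm(cfg$n_g, 0, cfg$sigma_grp)
    group_of_inbred <- sample.int(cfg$n_g, cfg$n_b, replace = TRUE) - 1L

    cells <- sample.int(cfg$n_b * cfg$n_t, cfg$n_combos)  # without replacement
    pb <- (cells - 1L) %/% cfg$n_t
    pt <- (cells - 1L) %% cfg$n_t
    m <- pmax(1L, stats::rpois(cfg$n_combos, cfg$mean_obs_per_combo))
    b <- rep(pb, m)
    t <- rep(pt, m)
    l <- sample.int(cfg$n_l, sum(m), replace = TRUE) - 1L
    g <- group_of_inbred[b + 1L]
    dotp <- rowSums(U[b + 1L, , drop = FALSE] * V[t + 1L, , drop = FALSE])
    y <- cfg$mu + loc_effects[l + 1L] + grp_effects[g + 1L] + dotp +
      cfg$gamma_nonlinear * tanh(dotp)^2 +
      stats::rnorm(length(b), 0, cfg$sigma_noise)

    truth <- list(
      U = U, V = V, loc_effects = loc_effects, grp_effects = grp_effects,
      group_of_inbred = group_of_inbred,
      inbred_ids = id_labels("I", cfg$n_b),
      tester_ids = id_labels("T", cfg$n_t),
      location_ids = id_labels("L", cfg$n_l),
      group_ids = id_labels("G", cfg$n_g),
      config = cfg
    )
    class(truth) <- "ground_truth"
    table <- as_observation_table(data.frame(
      inbred_id = truth$inbred_ids[b + 1L],
      tester_id = truth$tester_ids[t + 1L],
      location_id = truth$location_ids[l + 1L],
      genetic_group_id = truth$group_ids[g + 1L],
      yield = y,
      stringsAsFactors = FALSE
    ))
    list(table = table, truth = truth)
  })
}

#' Noise-free location-averaged expected yield of a pair
#'
#' The oracle for the hold-out response: the expectation of the pair's
#' yield averaged over *all* locations, i.e.
#' `mu + mean(loc_effects) + grp_effects[group(b)] + U[b].V[t] +
#' gamma * tanh(U[b].V[t])^2`.
#'
#' @param truth A `ground_truth` from [generate_crosses()].
#' @param config The matching [synthetic_config()].
#' @param b,t 0-based inbred / tester indices into the ground-truth arrays
#'   (vectorized).
#' @return Numeric vector of expected pair means.
#' @export
true_pair_mean <- function(truth, config, b, t) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- config
  if (any(b < 0 | b >= cfg$n_b)) stop("inbred index out of range")
  if (any(t < 0 | t >= cfg$n_t)) stop("tester index out of range")
  dotp <- rowSums(truth$U[b + 1L, , drop = FALSE] *
                  truth$V[t + 1L, , drop = FALSE])
  cfg$mu + mean(truth$loc_effects) +
    truth$grp_effects[truth$group_of_inbred[b + 1L] + 1L] +
    dotp + cfg$gamma_nonlinear * tanh(dotp)^2
}

#' Write the ground-truth sidecar as JSON
#'
#' @param truth A `ground_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- truth
  out$config <- unclass(out$config)
  class(out) <- NULL
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
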