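test_that("rmse and pearson_pct match hand-computed values", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(0, 2), c(0, 0)), sqrt(2))
  expect_error(rmse(1:3, 1:2), "length")
  expect_error(rmse(numeric(0), numeric(0)), "empty")

  y <- c(0.8, 1.0, 1.1, 1.3)
  expect_equal(pearson_pct(y, 2 * y + 1), 100)
  expect_equal(pearson_pct(y, -y), -100)
  expect_equal(pearson_pct(y, rep(1, 4)), 0)   # constant predictor
  expect_equal(pearson_pct(rep(1, 4), y), 0)
  expect_error(pearson_pct(1, 1), "at least 2")
  expect_error(pearson_pct(1:3, 1:2), "length")
})

test_that("cross validation pools each observation exactly once", {
  study <- small_study(seed = 61, n_combos = 100, mean_obs = 2)
  rep <- run_cv(study$ds, study$enc, baseline_spec("constant_mean"),
                k = 4, seed = 2)
  expect_s3_class(rep, "eval_report")
  expect_length(rep$predictions, study$ds$N)
  expect_false(anyNA(rep$predictions))
  # within each fold the predictor is constant, so fold correlations take
  # the zero-variance convention (pooled predictions differ across folds)
  expect_equal(rep$per_fold$test_corr_pct, rep(0, 4))
  expect_equal(nrow(rep$per_fold), 4L)
  # pooled metric equals a direct recomputation from the pooled predictions
  expect_equal(rep$test_rmse, rmse(study$ds$y, rep$predictions))
})

test_that("leave-one-out runs at the k = N boundary", {
  tab <- as_observation_table(data.frame(
    inbred_id = rep(c("A", "B"), 3), tester_id = rep(c("X", "Y", "Z"), 2),
    location_id = "L1", genetic_group_id = "G1",
    yield = c(0.9, 1.0, 1.1, 1.05, 0.95, 1.0)))
  enc <- build_encoding(tab)
  ds <- encode_observations(tab, enc)
  rep <- run_cv(ds, enc, baseline_spec("constant_mean"), k = 6, seed = 1)
  expect_length(rep$predictions, 6L)
})

test_that("holdout harness scores location-averaged pair predictions", {
  study <- small_study(seed = 63, n_combos = 150, mean_obs = 3)
  rep <- run_holdout(study$ds, study$enc, baseline_spec("constant_mean"),
                     n_combos = 40, seed = 3)
  # constant model: every pair prediction is the training mean, so the RMSE
  # equals the population std of pair-mean responses around that constant
  resp <- rep$predictions$response
  cpred <- rep$predictions$prediction[1]
  expect_true(all(rep$predictions$prediction == cpred))
  expect_equal(rep$test_rmse, sqrt(mean((resp - cpred)^2)))
  expect_equal(rep$test_corr_pct, 0)
  # self-consistency: metrics recompute from the emitted pairs
  expect_equal(rep$test_rmse,
               rmse(rep$predictions$response, rep$predictions$prediction))
})

test_that("location averaging is the identity on single-location data", {
  study <- small_study(seed = 65, n_l = 1, n_combos = 80, mean_obs = 2)
  cfg <- fast_config(kl = 2, max_iterations = 300)
  m <- train_ncf(study$ds, study$enc, cfg)
  b <- study$ds$b[1:10]
  t <- study$ds$t[1:10]
  g <- m$group_of_inbred[b + 1]
  pm <- predict_pair_means(m, b, t)
  po <- predict_observations(m, b, t, g, rep(0L, 10))
  expect_equal(pm, po)
})

test_that("trained GMF pair predictions track the ground-truth oracle", {
  cfg <- synthetic_config(n_b = 50, n_t = 40, n_l = 6, n_g = 3,
                          n_combos = 900, mean_obs_per_combo = 5,
                          k_true = 3, sigma_latent = 0.3, sigma_loc = 0.03,
                          sigma_grp = 0.03, gamma_nonlinear = 0,
                          sigma_noise = 0.03, mu = 1.0, seed = 66)
  sim <- generate_crosses(cfg)
  enc <- build_encoding(sim$table)
  ds <- encode_observations(sim$table, enc)
  m <- train_ncf(ds, enc, fast_config(branch = "gmf_only", k1 = 6,
                                      max_iterations = 8000,
                                      batch_size = 64,
                                      standardize = TRUE))
  sp <- holdout_split_by_combination(ds, 100, seed = 5)
  pred <- predict_pair_means(m, sp$heldout$b, sp$heldout$t)
  # map encoding indices back to generator indices for the oracle
  raw_b <- names(enc$inbred)[sp$heldout$b + 1]
  raw_t <- names(enc$tester)[sp$heldout$t + 1]
  oracle <- true_pair_mean(sim$truth, cfg,
                           match(raw_b, sim$truth$inbred_ids) - 1L,
                           match(raw_t, sim$truth$tester_ids) - 1L)
  expect_gt(pearson_pct(oracle, pred), 90)
})

test_that("coarse experiment uses group and location only", {
  study <- small_study(seed = 67, n_combos = 120, mean_obs = 3,
                       sigma_latent = 0.25)
  cfg <- fast_config(max_iterations = 800)
  reps <- run_coarse_experiment(study$ds, study$enc, cfg, k = 3,
                                n_combos = 30, seed = 4)
  expect_named(reps, c("cv", "holdout"))
  expect_false(reps$cv$config$use_parent_ids)     # config snapshot marks it
  expect_identical(reps$cv$config$branch, "nn_only")
  expect_match(reps$cv$model_name, "coarse")
})

test_that("coarse model matches the full model when only coarse signal exists", {
  study <- small_study(seed = 69, n_b = 25, n_t = 15, n_l = 8, n_g = 4,
                       n_combos = 200, mean_obs = 4, sigma_latent = 0,
                       gamma_nonlinear = 0, sigma_loc = 0.12,
                       sigma_grp = 0.08, sigma_noise = 0.02)
  cfg <- fast_config(max_iterations = 4000, batch_size = 64,
                     standardize = TRUE)
  full <- run_cv(study$ds, study$enc, cfg, k = 3, seed = 5)
  coarse <- run_coarse_experiment(study$ds, study$enc, cfg,
                                  protocols = "cv", k = 3, seed = 5)$cv
  expect_lt(coarse$test_rmse, full$test_rmse * 1.25)
  expect_gt(coarse$test_corr_pct, 50)
})

test_that("reports serialize to JSON and CSV", {
  study <- small_study(seed = 71, n_combos = 80, mean_obs = 2)
  rep <- run_cv(study$ds, study$enc, baseline_spec("constant_mean"),
                k = 3, seed = 1)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, json_path = jp, csv_path = cp)
  write_report(rep, csv_path = cp)    # appends a second row
  parsed <- jsonlite::read_json(jp)
  expect_equal(parsed$model_name, "constant_mean")
  expect_equal(parsed$test_rmse, rep$test_rmse)
  rows <- utils::read.csv(cp)
  expect_equal(nrow(rows), 2L)
  expect_equal(rows$test_rmse[1], rep$test_rmse, tolerance = 1e-12)
})
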