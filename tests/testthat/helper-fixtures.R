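# programmatic fixtures shared across test files

tiny_table <- function() {
  as_observation_table(data.frame(
    inbred_id = c("A", "A", "B", "B"),
    tester_id = c("X", "Y", "X", "Y"),
    location_id = c("L1", "L2", "L1", "L2"),
    genetic_group_id = c("G1", "G1", "G2", "G2"),
    yield = c(0.9, 1.1, 1.05, 0.85)
  ))
}

tiny_dataset <- function() {
  tab <- tiny_table()
  enc <- build_encoding(tab)
  list(table = tab, enc = enc, ds = encode_observations(tab, enc))
}

# moderately sized synthetic study used by several suites
small_study <- function(seed = 7, n_b = 30, n_t = 20, n_l = 8, n_g = 4,
                        n_combos = 200, mean_obs = 4, ...) {
  cfg <- synthetic_config(n_b = n_b, n_t = n_t, n_l = n_l, n_g = n_g,
                          n_combos = n_combos,
                          mean_obs_per_combo = mean_obs, seed = seed, ...)
  sim <- generate_crosses(cfg)
  enc <- build_encoding(sim$table)
  list(cfg = cfg, sim = sim, enc = enc,
       ds = encode_observations(sim$table, enc))
}

# fast training configuration for tests (small embeddings, larger batches)
fast_config <- function(...) {
  defaults <- list(k1 = 8, k2 = 8, kg = 4, kl = 4, nn_layers = c(16, 8),
                   batch_size = 32, learning_rate = 3e-3,
                   max_iterations = 2000, seed = 42, log_every = 1000)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
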