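test_that("read_observations parses valid files and reports bad input", {
  path <- write_csv_fixture(c(
    "inbred_id,tester_id,location_id,genetic_group_id,yield",
    "A,X,L1,G1,0.95",
    "B,Y,L2,G2,1.05"
  ))
  tab <- read_observations(path)
  expect_s3_class(tab, "observation_table")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$yield, c(0.95, 1.05))
  expect_equal(tab$inbred_id, c("A", "B"))

  bad <- write_csv_fixture(c(
    "inbred_id,tester_id,location_id,genetic_group_id,yield",
    "A,X,L1,G1,0.95", "B,Y,L2,G2,1.05", "C,Z,L3,G3,abc"
  ))
  expect_error(read_observations(bad), "row 3")

  empty <- write_csv_fixture(
    "inbred_id,tester_id,location_id,genetic_group_id,yield")
  expect_error(read_observations(empty), "no data rows")

  nocol <- write_csv_fixture(c("inbred_id,tester_id,location_id,yield",
                               "A,X,L1,0.9"))
  expect_error(read_observations(nocol), "genetic_group_id")
})

test_that("column remapping and the year column are honored", {
  path <- write_csv_fixture(c(
    "parent1,parent2,site,grp,bushels,season",
    "A,X,L1,G1,0.9,2016",
    "B,Y,L2,G2,1.1,2017"
  ))
  tab <- read_observations(path, column_map = c(
    inbred_id = "parent1", tester_id = "parent2", location_id = "site",
    genetic_group_id = "grp", yield = "bushels", year = "season"))
  expect_equal(tab$year, c(2016L, 2017L))
  expect_equal(tab$tester_id, c("X", "Y"))
  expect_error(read_observations(path, column_map = c(nonsense = "foo")),
               "column_map")
})

test_that("write/read round trip reproduces records and order exactly", {
  study <- small_study(seed = 3, n_b = 8, n_t = 6, n_l = 3, n_g = 2,
                       n_combos = 20, mean_obs = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(study$sim$table, path)
  back <- read_observations(path)
  expect_identical(back$inbred_id, study$sim$table$inbred_id)
  expect_identical(back$tester_id, study$sim$table$tester_id)
  expect_identical(back$yield, study$sim$table$yield)
})

test_that("build_encoding assigns first-appearance indices and cardinalities", {
  tab <- as_observation_table(data.frame(
    inbred_id = c("B", "A", "B"), tester_id = c("T1", "T1", "T1"),
    location_id = c("L1", "L2", "L1"), genetic_group_id = c("G", "G", "G"),
    yield = c(1, 1, 1)))
  enc <- build_encoding(tab)
  expect_equal(enc$n_b, 2L)
  expect_equal(enc$n_t, 1L)
  expect_equal(unname(enc$inbred[c("B", "A")]), c(0L, 1L))
  expect_identical(build_encoding(tab), enc)
})

test_that("encode maps IDs to aligned indices and rejects unknown IDs", {
  tt <- tiny_dataset()
  expect_equal(tt$ds$N, 4L)
  one <- as_observation_table(tt$table[1, ])
  enc1 <- build_encoding(one)
  ds1 <- encode_observations(one, enc1)
  expect_equal(c(ds1$b, ds1$t, ds1$g, ds1$l), rep(0L, 4))

  stranger <- as_observation_table(data.frame(
    inbred_id = "ZZZ", tester_id = "X", location_id = "L1",
    genetic_group_id = "G1", yield = 1))
  expect_error(encode_observations(stranger, tt$enc), "ZZZ")
  expect_error(encode_observations(stranger, tt$enc), "inbred")

  back <- decode_observations(tt$ds, tt$enc)
  expect_identical(back$inbred_id, tt$table$inbred_id)
  expect_identical(back$tester_id, tt$table$tester_id)
  expect_identical(back$location_id, tt$table$location_id)
  expect_identical(back$genetic_group_id, tt$table$genetic_group_id)
})

test_that("kfold_split partitions observations with near-equal folds", {
  study <- small_study(seed = 5, n_b = 10, n_t = 8, n_l = 4, n_g = 3,
                       n_combos = 30, mean_obs = 2)
  N <- study$ds$N

  folds <- kfold_split(list(N = 10L), k = 5, seed = 1)
  sizes <- vapply(folds, function(f) length(f$test), integer(1))
  expect_equal(sizes, rep(2L, 5))
  expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), 1:10)

  folds <- kfold_split(study$ds, k = 4, seed = 2)
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(all_test), seq_len(N))          # partition property
  expect_equal(anyDuplicated(all_test), 0L)
  sizes <- vapply(folds, function(f) length(f$test), integer(1))
  expect_lte(max(sizes) - min(sizes), 1L)
  for (f in folds) {
    expect_equal(sort(c(f$train, f$test)), seq_len(N))
  }

  expect_identical(kfold_split(study$ds, 4, seed = 2), folds)
  expect_false(identical(kfold_split(study$ds, 4, seed = 3), folds))
  expect_error(kfold_split(list(N = 3L), k = 4, seed = 1), "exceeds")
  expect_error(kfold_split(study$ds, k = 1, seed = 1), "at least 2")
})

test_that("holdout split withholds whole combinations with mean responses", {
  tt <- tiny_dataset()
  sp <- holdout_split_by_combination(tt$ds, n_combos = 1, seed = 4)
  expect_equal(nrow(sp$heldout), 1L)
  held_pair <- c(sp$heldout$b, sp$heldout$t)
  expect_false(any(sp$train$b == held_pair[1] & sp$train$t == held_pair[2]))
  in_pair <- tt$ds$b == held_pair[1] & tt$ds$t == held_pair[2]
  expect_equal(sp$heldout$response, mean(tt$ds$y[in_pair]))
  expect_equal(sp$train$N + sum(in_pair), tt$ds$N)

  pair_tab <- as_observation_table(data.frame(
    inbred_id = c("A", "A", "B", "B"), tester_id = c("X", "X", "Y", "Y"),
    location_id = c("L1", "L2", "L1", "L2"),
    genetic_group_id = "G1", yield = c(0.9, 1.1, 1.0, 1.0)))
  enc <- build_encoding(pair_tab)
  ds <- encode_observations(pair_tab, enc)
  sp <- holdout_split_by_combination(ds, 1, seed = 1)
  if (sp$heldout$b == 0) expect_equal(sp$heldout$response, 1.0)

  expect_error(holdout_split_by_combination(ds, 3, seed = 1), "exceeds")
})

test_that("holdout split never leaks held pairs into training data", {
  for (seed in 1:5) {
    study <- small_study(seed = seed, n_b = 15, n_t = 10, n_l = 5, n_g = 3,
                         n_combos = 60, mean_obs = 3)
    sp <- holdout_split_by_combination(study$ds, n_combos = 20, seed = seed)
    train_keys <- paste(sp$train$b, sp$train$t)
    held_keys <- paste(sp$heldout$b, sp$heldout$t)
    expect_length(intersect(train_keys, held_keys), 0)
    expect_equal(length(unique(held_keys)), 20L)
  }
})
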