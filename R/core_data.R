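#' Read a cross-yield observation table
#'
#' Reads a delimited text file with one row per planted hybrid plot. The
#' default schema is `inbred_id,tester_id,location_id,genetic_group_id,yield`
#' with an optional `year` column; other column names can be remapped via
#' `column_map`. Yield is on a normalized, dimensionless scale (population
#' mean close to 1 in typical inputs).
#'
#' @param path Path to a comma-delimited UTF-8 file with a header row.
#' @param column_map Optional named character vector mapping canonical names
#'   (`inbred_id`, `tester_id`, `location_id`, `genetic_group_id`, `yield`,
#'   `year`) to the file's column names.
#' @return A data frame of class `observation_table` with character ID
#'   columns and a numeric `yield` column, rows in file order.
#' @export
read_observations <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) stop("format error: file ", path, " has no data rows")
  required <- c("inbred_id", "tester_id", "location_id", "genetic_group_id",
                "yield")
  optional <- "year"
  wanted <- c(required, optional)
  src <- stats::setNames(wanted, wanted)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), wanted)
    if (length(bad)) stop("unknown column_map entries: ",
                          paste(bad, collapse = ", "))
    src[names(column_map)] <- unname(column_map)
  }
  for (cn in required) {
    if (!src[[cn]] %in% names(raw)) {
      stop("format error: missing required column '", src[[cn]], "'")
    }
  }
  tab <- data.frame(
    inbred_id = raw[[src[["inbred_id"]]]],
    tester_id = raw[[src[["tester_id"]]]],
    location_id = raw[[src[["location_id"]]]],
    genetic_group_id = raw[[src[["genetic_group_id"]]]],
    yield = raw[[src[["yield"]]]],
    stringsAsFactors = FALSE
  )
  if (src[["year"]] %in% names(raw)) {
    yr <- suppressWarnings(as.integer(raw[[src[["year"]]]]))
    tab$year <- yr
  }
  y <- suppressWarnings(as.numeric(tab$yield))
  bad <- which(is.na(y) | !is.finite(y))
  if (length(bad)) {
    stop("parse error: non-numeric or non-finite yield '",
         tab$yield[bad[1]], "' on data row ", bad[1])
  }
  tab$yield <- y
  as_observation_table(tab)
}

#' Construct / validate an observation table
#'
#' @param df A data frame with columns `inbred_id`, `tester_id`,
#'   `location_id`, `genetic_group_id` (coerced to character), numeric
#'   `yield`, and optionally integer `year`.
#' @return The validated data frame with class `observation_table`.
#' @export
as_observation_table <- function(df) {
  required <- c("inbred_id", "tester_id", "location_id", "genetic_group_id",
                "yield")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("observation table must have at least one row")
  for (cn in required[1:4]) {
    df[[cn]] <- as.character(df[[cn]])
    if (any(is.na(df[[cn]]) | df[[cn]] == "")) {
      stop("empty or missing values in column '", cn, "'")
    }
  }
  if (!is.numeric(df$yield) || any(!is.finite(df$yield))) {
    stop("yield must be finite numeric")
  }
  class(df) <- c("observation_table", "data.frame")
  df
}

#' Write an observation table to CSV
#'
#' Yields are written with 17 significant digits so a read/write round trip
#' reproduces records exactly.
#'
#' @param table An `observation_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(table, path) {
  stopifnot(inherits(table, "observation_table"))
  out <- as.data.frame(table)
  out$yield <- formatC(out$yield, digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build an ID encoding from an observation table
#'
#' Each distinct raw ID is assigned a dense 0-based integer index in order
#' of first appearance; the one-hot representation of an ID is implied by
#' its index together with the cardinality of its field.
#'
#' @param table An `observation_table`.
#' @return An object of class `cross_encoding`: named integer maps
#'   `inbred`, `tester`, `group`, `location` (raw ID -> 0-based index) and
#'   cardinalities `n_b`, `n_t`, `n_g`, `n_l`.
#' @export
build_encoding <- function(table) {
  stopifnot(inherits(table, "observation_table"))
  if (nrow(table) == 0L) stop("cannot build an encoding from an empty table")
  mk <- function(x) {
    u <- unique(x)
    stats::setNames(seq_along(u) - 1L, u)
  }
  enc <- list(
    inbred = mk(table$inbred_id),
    tester = mk(table$tester_id),
    group = mk(table$genetic_group_id),
    location = mk(table$location_id)
  )
  enc$n_b <- length(enc$inbred)
  enc$n_t <- length(enc$tester)
  enc$n_g <- length(enc$group)
  enc$n_l <- length(enc$location)
  class(enc) <- "cross_encoding"
  enc
}

map_ids <- function(ids, map, field) {
  idx <- unname(map[ids])
  if (anyNA(idx)) {
    bad <- ids[which(is.na(idx))[1]]
    stop("unknown ", field, " ID '", bad, "' not present in the encoding")
  }
  as.integer(idx)
}

#' Encode an observation table against an encoding
#'
#' @param table An `observation_table` whose raw IDs all appear in `enc`.
#' @param enc A `cross_encoding`.
#' @return An `indexed_dataset`: 0-based integer index vectors `b`, `t`,
#'   `g`, `l`, numeric response `y`, and length `N`, aligned with the row
#'   order of `table`.
#' @export
encode_observations <- function(table, enc) {
  stopifnot(inherits(table, "observation_table"),
            inherits(enc, "cross_encoding"))
  ds <- list(
    b = map_ids(table$inbred_id, enc$inbred, "inbred"),
    t = map_ids(table$tester_id, enc$tester, "tester"),
    g = map_ids(table$genetic_group_id, enc$group, "genetic group"),
    l = map_ids(table$location_id, enc$location, "location"),
    y = as.numeric(table$yield)
  )
  ds$N <- length(ds$y)
  class(ds) <- "indexed_dataset"
  ds
}

#' Decode an indexed dataset back to raw IDs
#'
#' Inverse of [encode_observations()] on the ID columns.
#'
#' @param dataset An `indexed_dataset`.
#' @param enc The `cross_encoding` it was encoded with.
#' @return A data frame of raw ID columns plus `yield`.
#' @export
decode_observations <- function(dataset, enc) {
  stopifnot(inherits(dataset, "indexed_dataset"),
            inherits(enc, "cross_encoding"))
  inv <- function(map, idx) names(map)[match(idx, unname(map))]
  data.frame(
    inbred_id = inv(enc$inbred, dataset$b),
    tester_id = inv(enc$tester, dataset$t),
    location_id = inv(enc$location, dataset$l),
    genetic_group_id = inv(enc$group, dataset$g),
    yield = dataset$y,
    stringsAsFactors = FALSE
  )
}

#' Subset an indexed dataset by row positions
#'
#' @param dataset An `indexed_dataset`.
#' @param i 1-based row positions.
#' @return The subsetted `indexed_dataset`.
#' @export
subset_dataset <- function(dataset, i) {
  stopifnot(inherits(dataset, "indexed_dataset"))
  out <- list(b = dataset$b[i], t = dataset$t[i], g = dataset$g[i],
              l = dataset$l[i], y = dataset$y[i])
  out$N <- length(out$y)
  class(out) <- "indexed_dataset"
  out
}

#' k-fold split at the observation level
#'
#' Observations are partitioned into `k` folds of near-equal size (sizes
#' differ by at most one; the `N %% k` larger folds come first). Shuffling
#' is driven only by `seed`.
#'
#' @param dataset An `indexed_dataset` (or anything with element `N`).
#' @param k Number of folds, `2 <= k <= N`.
#' @param seed Integer seed for the shuffle.
#' @return A list of `k` elements, each `list(train =, test =)` of 1-based
#'   row positions; the test sets partition `seq_len(N)`.
#' @export
kfold_split <- function(dataset, k, seed) {
  N <- if (is.list(dataset) && !is.null(dataset$N)) dataset$N else
    length(dataset)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > N) stop("k = ", k, " exceeds the number of observations N = ", N)
  perm <- local_seed(seed, sample.int(N))
  base <- N %/% k
  extra <- N %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(f) {
    test <- sort(perm[starts[f]:ends[f]])
    list(train = setdiff(seq_len(N), test), test = test)
  })
}

pair_key <- function(b, t, n_t) as.numeric(b) * n_t + as.numeric(t)

#' Hold-out split by cross combination
#'
#' Withholds entire (inbred, tester) combinations: `n_combos` distinct
#' observed pairs are drawn uniformly without replacement, every
#' observation of a held pair is removed from the training data, and the
#' response for each held pair is the arithmetic mean of its observed
#' yields (the location-averaged response used to score hold-out
#' predictions).
#'
#' @param dataset An `indexed_dataset`.
#' @param n_combos Number of combinations to hold out.
#' @param seed Integer seed.
#' @return `list(train =, heldout =)` where `train` is an
#'   `indexed_dataset` and `heldout` a data frame with 0-based `b`, `t` and
#'   numeric `response`.
#' @export
holdout_split_by_combination <- function(dataset, n_combos, seed) {
  stopifnot(inherits(dataset, "indexed_dataset"))
  n_t_span <- max(dataset$t) + 1
  key <- pair_key(dataset$b, dataset$t, n_t_span)
  ukey <- unique(key)
  if (n_combos > length(ukey)) {
    stop("n_combos = ", n_combos, " exceeds the number of distinct observed ",
         "combinations (", length(ukey), ")")
  }
  held <- local_seed(seed, sample(ukey, n_combos))
  is_held <- key %in% held
  means <- tapply(dataset$y[is_held], key[is_held], mean)
  hk <- as.numeric(names(means))
  heldout <- data.frame(
    b = as.integer(hk %/% n_t_span),
    t = as.integer(hk %% n_t_span),
    response = as.numeric(means)
  )
  list(train = subset_dataset(dataset, which(!is_held)), heldout = heldout)
}

#' @method print cross_encoding
#' @export
print.cross_encoding <- function(x, ...) {
  cat("cross_encoding: n_b =", x$n_b, "inbreds, n_t =", x$n_t,
      "testers, n_g =", x$n_g, "genetic groups, n_l =", x$n_l,
      "locations\n")
  invisible(x)
}

#' @method print indexed_dataset
#' @export
print.indexed_dataset <- function(x, ...) {
  cat("indexed_dataset:", x$N, "observations,",
      length(unique(pair_key(x$b, x$t, max(x$t) + 1))),
      "distinct (inbred, tester) combinations\n")
  invisible(x)
}
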