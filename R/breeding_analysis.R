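#' Predict the full cross-combination matrix
#'
#' Location-averaged predicted yield for every (inbred, tester) cell of the
#' encoding's full grid, via the same [predict_pair_means()] path the
#' hold-out harness uses (genetic group resolved through the model's
#' modal-group map).
#'
#' @param model A fitted model whose encoding defines the grid.
#' @param chunk_pairs Pairs per prediction chunk.
#' @return A `prediction_matrix`: `values` (`n_b x n_t`, dimnames = raw
#'   IDs), `inbred_ids`, `tester_ids`.
#' @export
predict_full_matrix <- function(model, chunk_pairs = 1024L) {
  enc <- model$encoding
  grid_b <- rep(0:(enc$n_b - 1L), each = enc$n_t)
  grid_t <- rep(0:(enc$n_t - 1L), times = enc$n_b)
  vals <- predict_pair_means(model, grid_b, grid_t,
                             chunk_pairs = chunk_pairs)
  values <- matrix(vals, nrow = enc$n_b, ncol = enc$n_t, byrow = TRUE,
                   dimnames = list(names(enc$inbred), names(enc$tester)))
  structure(list(values = values, inbred_ids = names(enc$inbred),
                 tester_ids = names(enc$tester)),
            class = "prediction_matrix")
}

#' Write a prediction matrix as labeled CSV
#'
#' First column inbred ID, header row tester IDs, body = location-averaged
#' predictions.
#'
#' @param matrix A `prediction_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prediction_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "prediction_matrix"))
  df <- data.frame(inbred_id = matrix$inbred_ids, matrix$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a heatmap over a random parent subset
#'
#' Uniformly samples `n_rows` inbreds and `n_cols` testers without
#' replacement (seeded), writes the sub-matrix as labeled CSV and
#' optionally renders a heatmap image (rows/columns kept in sampled order,
#' no clustering).
#'
#' @param matrix A `prediction_matrix`.
#' @param n_rows,n_cols Numbers of inbreds / testers to sample.
#' @param seed Integer seed for the sampling.
#' @param csv_path Optional CSV output path.
#' @param image_path Optional PNG output path.
#' @return The sampled sub-matrix as a `prediction_matrix`, invisibly.
#' @export
export_heatmap <- function(matrix, n_rows = 100, n_cols = 100, seed = 1,
                           csv_path = NULL, image_path = NULL) {
  stopifnot(inherits(matrix, "prediction_matrix"))
  n_b <- length(matrix$inbred_ids)
  n_t <- length(matrix$tester_ids)
  if (n_rows > n_b) stop("n_rows exceeds the number of inbreds (", n_b, ")")
  if (n_cols > n_t) stop("n_cols exceeds the number of testers (", n_t, ")")
  sel <- local_seed(seed, list(r = sort(sample.int(n_b, n_rows)),
                               c = sort(sample.int(n_t, n_cols))))
  sub <- structure(list(values = matrix$values[sel$r, sel$c, drop = FALSE],
                        inbred_ids = matrix$inbred_ids[sel$r],
                        tester_ids = matrix$tester_ids[sel$c]),
                   class = "prediction_matrix")
  if (!is.null(csv_path)) write_prediction_matrix(sub, csv_path)
  if (!is.null(image_path)) {
    pheatmap::pheatmap(sub$values, cluster_rows = FALSE,
                       cluster_cols = FALSE, show_rownames = n_rows <= 50,
                       show_colnames = n_cols <= 50, filename = image_path,
                       silent = TRUE)
  }
  invisible(sub)
}

#' Categorize parents by marginal yield tertiles
#'
#' A parent's marginal yield is the mean of its observed yields over all
#' its crosses. Parents are split into low/medium/high classes at the 1/3
#' and 2/3 empirical quantiles (equal-count tertiles; ties broken by parent
#' index), and `per_category` parents are sampled uniformly from each class
#' — or all of them, with a message, when a class is smaller.
#'
#' @param dataset An `indexed_dataset` of observed crosses.
#' @param enc The `cross_encoding`.
#' @param side `"inbred"` or `"tester"`.
#' @param per_category Parents to sample per class.
#' @param seed Integer seed for the sampling.
#' @return A data frame of the sampled parents: `parent_id`, 0-based
#'   `index`, `marginal_yield`, `category` (factor low/medium/high). The
#'   full categorization of all observed parents is attached as attribute
#'   `"all"`.
#' @export
categorize_parents <- function(dataset, enc, side = c("inbred", "tester"),
                               per_category = 50, seed = 1) {
  side <- match.arg(side)
  idx <- if (side == "inbred") dataset$b else dataset$t
  ids <- if (side == "inbred") names(enc$inbred) else names(enc$tester)
  marg <- tapply(dataset$y, idx, mean)
  observed <- as.integer(names(marg))
  n <- length(observed)
  if (n < 3) stop("need at least 3 observed ", side, "s to form tertiles")
  ord <- order(as.numeric(marg), observed)
  bounds <- floor(seq(0, n, length.out = 4))
  sizes <- diff(bounds)
  category <- rep(c("low", "medium", "high"), times = sizes)
  all_tab <- data.frame(
    parent_id = ids[observed[ord] + 1L],
    index = observed[ord],
    marginal_yield = as.numeric(marg)[ord],
    category = factor(category, levels = c("low", "medium", "high"))
  )
  picked <- local_seed(seed, {
    do.call(rbind, lapply(split(all_tab, all_tab$category), function(cl) {
      if (nrow(cl) <= per_category) {
        message("category '", cl$category[1], "' has only ", nrow(cl),
                " parents; taking all of them")
        cl
      } else {
        cl[sort(sample.int(nrow(cl), per_category)), ]
      }
    }))
  })
  rownames(picked) <- NULL
  attr(picked, "all") <- all_tab
  picked
}

#' Export embedding vectors for external visualization
#'
#' One row per parent: raw ID plus the k latent values of the requested
#' embedding matrix (`gmf` uses the GMF-branch embeddings `W1b`/`W1t`;
#' `nn` the NN-branch embeddings `W2b`/`W2t`), with the yield category
#' joined in when supplied. The output is directly consumable by an
#' external t-SNE/UMAP tool.
#'
#' @param model An `ncf_model`.
#' @param side `"inbred"` or `"tester"`.
#' @param component `"gmf"` or `"nn"`.
#' @param categories Optional output of [categorize_parents()] to merge.
#' @return A data frame: `parent_id`, latent columns `f1..fk`, optionally
#'   `category`.
#' @export
export_embeddings <- function(model, side = c("inbred", "tester"),
                              component = c("gmf", "nn"),
                              categories = NULL) {
  side <- match.arg(side)
  component <- match.arg(component)
  W <- model$params[[paste0(if (component == "gmf") "W1" else "W2",
                            if (side == "inbred") "b" else "t")]]
  ids <- if (side == "inbred") names(model$encoding$inbred) else
    names(model$encoding$tester)
  out <- data.frame(parent_id = ids, W, stringsAsFactors = FALSE)
  names(out) <- c("parent_id", paste0("f", seq_len(ncol(W))))
  if (!is.null(categories)) {
    out$category <- categories$category[match(out$parent_id,
                                              categories$parent_id)]
  }
  out
}
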