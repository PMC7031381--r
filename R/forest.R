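#' Random-forest protocol configuration
#'
#' @param n_trees Trees per forest (default 1000).
#' @param repeats Cross-validation repeats (default 10).
#' @param folds Folds per repeat (default 5).
#' @param mtry Features tried per split; `NULL` means
#'   `floor(sqrt(n_features))`.
#' @param seed Integer seed controlling bootstraps, splits and
#'   permutations.
#' @return A `forest_config`.
#' @export
forest_config <- function(n_trees = 1000L, repeats = 10L, folds = 5L,
                          mtry = NULL, seed = 1L) {
  stopifnot(n_trees >= 1L, folds >= 2L, repeats >= 1L)
  structure(list(n_trees = as.integer(n_trees), repeats = as.integer(repeats),
                 folds = as.integer(folds),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Train a seeded random forest
#'
#' Binary-classification forest: bootstrap samples, CART/Gini trees grown
#' to purity, majority-vote leaves. Bit-reproducible under `seed`.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Binary 0/1 labels.
#' @param n_trees Number of trees.
#' @param mtry Features tried per split (default `floor(sqrt(ncol(x)))`).
#' @param seed Integer seed.
#' @return A `neopred_rf` object.
#' @export
random_forest <- function(x, y, n_trees = 500L, mtry = NULL, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    np_stop("labels must contain both classes", "neopred_degenerate_labels")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- rf_fit_cpp(x, y, as.integer(n_trees), as.integer(mtry), 1L,
                    as.integer(seed))
  structure(list(fit = fit, features = colnames(x), x = x, y = y,
                 mtry = as.integer(mtry), seed = as.integer(seed)),
            class = "neopred_rf")
}

#' Vote-ratio predictions from a random forest
#'
#' @param object A `neopred_rf`.
#' @param newdata Feature matrix; defaults to the training matrix.
#' @param ... Unused.
#' @return Numeric vector of vote ratios in `[0, 1]` (fraction of trees
#'   voting for the positive class).
#' @export
predict.neopred_rf <- function(object, newdata = object$x, ...) {
  nd <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(nd)))
    nd <- nd[, object$features, drop = FALSE]
  rf_predict_cpp(object$fit, nd)
}

#' Functional / synonymous mutation feature matrix
#'
#' Builds the samples x genes binary matrix of mutation status. The
#' `functional` class keeps records called simultaneously damaging by SIFT
#' and deleterious by PROVEAN; the `synonymous` class keeps synonymous
#' records. A gene is retained only when its mutation frequency across the
#' sample set strictly exceeds `min_freq`.
#'
#' @param mutations Data frame of mutation records (columns `sample`,
#'   `gene`, `class`, `sift_damaging`, `provean_deleterious`).
#' @param samples Character vector fixing the row set and order.
#' @param class `"functional"` or `"synonymous"`.
#' @param min_freq Strict frequency threshold (default 0.05).
#' @return A `mutation_matrix`: list with `values` (binary matrix),
#'   `class`, `threshold`.
#' @export
build_mutation_matrix <- function(mutations, samples,
                                  class = c("functional", "synonymous"),
                                  min_freq = 0.05) {
  class <- match.arg(class)
  stopifnot(length(samples) > 0)
  keep <- if (class == "functional") {
    mutations$class != "synonymous" &
      mutations$sift_damaging %in% TRUE &
      mutations$provean_deleterious %in% TRUE
  } else {
    mutations$class == "synonymous"
  }
  mut <- mutations[keep & mutations$sample %in% samples, , drop = FALSE]
  genes <- sort(unique(mut$gene))
  values <- matrix(0L, length(samples), length(genes),
                   dimnames = list(samples, genes))
  if (nrow(mut) > 0) {
    idx <- cbind(match(mut$sample, samples), match(mut$gene, genes))
    values[idx] <- 1L
  }
  freq <- colMeans(values)
  values <- values[, freq > min_freq, drop = FALSE]
  if (ncol(values) == 0)
    np_stop(sprintf("no gene exceeds mutation frequency %.3g", min_freq),
            "neopred_empty_feature_set")
  structure(list(values = values, class = class, threshold = min_freq),
            class = "mutation_matrix")
}

#' Synonymous control matrix with matched feature count
#'
#' Builds the negative-control feature matrix from synonymous mutations
#' over the same samples, with exactly as many gene features as the
#' functional matrix. The frequency threshold is scanned for the smallest
#' gene count at or above the target; any excess genes are trimmed
#' deterministically, dropping the most frequent first (alphabetical among
#' ties).
#'
#' @param functional A functional-class `mutation_matrix`.
#' @param mutations Mutation data frame containing synonymous records.
#' @return A synonymous-class `mutation_matrix` with
#'   `ncol == ncol(functional$values)`.
#' @export
matched_control <- function(functional, mutations) {
  samples <- rownames(functional$values)
  target <- ncol(functional$values)
  syn <- mutations[mutations$class == "synonymous" &
                     mutations$sample %in% samples, , drop = FALSE]
  genes <- sort(unique(syn$gene))
  if (length(genes) < target)
    np_stop(sprintf("only %d synonymous genes available, %d needed",
                    length(genes), target), "neopred_insufficient_control")
  values <- matrix(0L, length(samples), length(genes),
                   dimnames = list(samples, genes))
  values[cbind(match(syn$sample, samples), match(syn$gene, genes))] <- 1L
  freq <- colMeans(values)
  # counts achievable with a strict > threshold; scan candidate thresholds
  cand <- sort(unique(c(0, freq)))
  counts <- vapply(cand, function(t) sum(freq > t), integer(1))
  ok <- which(counts >= target)
  if (length(ok) == 0)
    np_stop(sprintf("no threshold yields %d synonymous features", target),
            "neopred_insufficient_control")
  # smallest achievable count >= target (closest from above)
  thr <- cand[ok[which.min(counts[ok])]]
  kept <- names(freq)[freq > thr]
  if (length(kept) > target) {
    ord <- order(-freq[kept], kept)   # most frequent first, ties by name
    kept <- sort(setdiff(kept, kept[ord][seq_len(length(kept) - target)]))
  }
  structure(list(values = values[, kept, drop = FALSE], class = "synonymous",
                 threshold = thr),
            class = "mutation_matrix")
}

# Stratified fold assignment, seeded; returns integer folds of length n.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Repeated cross-validated random forest
#'
#' Runs the resistance-classification protocol: for each repeat a
#' stratified k-fold split; one forest per training fold; out-of-fold vote
#' ratios collected per repeat and averaged over repeats; AUC per repeat
#' and the mean reported. Fully deterministic under the config seed.
#'
#' @param matrix A `mutation_matrix` (or bare feature matrix).
#' @param labels Logical/0-1 labels (e.g. resistant), both classes present.
#' @param config A [forest_config()].
#' @return List with `scores` (per-sample mean out-of-fold vote ratio),
#'   `auc_per_repeat`, `mean_auc`.
#' @export
cv_rf <- function(matrix, labels, config = forest_config()) {
  x <- if (inherits(matrix, "mutation_matrix")) matrix$values else
    as.matrix(matrix)
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2)
    np_stop("labels must contain both classes", "neopred_degenerate_labels")
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(x)))) else
    config$mtry
  score_mat <- base::matrix(NA_real_, nrow(x), config$repeats)
  aucs <- numeric(config$repeats)
  for (r in seq_len(config$repeats)) {
    folds <- stratified_folds(y, config$folds, np_seed(config$seed, r, 0L))
    oof <- numeric(nrow(x))
    for (f in seq_len(config$folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      fit <- rf_fit_cpp(x[tr, , drop = FALSE], y[tr], config$n_trees,
                        mtry, 1L, np_seed(config$seed, r, f))
      oof[te] <- rf_predict_cpp(fit, x[te, , drop = FALSE])
    }
    score_mat[, r] <- oof
    aucs[r] <- evaluate_scores(oof, y)$auc
  }
  scores <- rowMeans(score_mat)
  names(scores) <- rownames(x)
  list(scores = scores, auc_per_repeat = aucs, mean_auc = mean(aucs))
}

#' Leave-one-sample-out vote ratios
#'
#' Each sample's score comes from a forest trained with that sample held
#' out; used to feed unbiased exomic prediction scores into the downstream
#' regressions.
#'
#' @inheritParams cv_rf
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
loo_scores <- function(matrix, labels, config = forest_config()) {
  x <- if (inherits(matrix, "mutation_matrix")) matrix$values else
    as.matrix(matrix)
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2)
    np_stop("labels must contain both classes", "neopred_degenerate_labels")
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(x)))) else
    config$mtry
  scores <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    fit <- rf_fit_cpp(x[-i, , drop = FALSE], y[-i], config$n_trees, mtry,
                      1L, np_seed(config$seed, i))
    scores[i] <- rf_predict_cpp(fit, x[i, , drop = FALSE])
  }
  names(scores) <- rownames(x)
  scores
}

#' Permutation variable importance
#'
#' Trains one forest on the full matrix and measures, per feature, the
#' mean decrease in out-of-bag accuracy when that feature's values are
#' randomly permuted, z-scaled over trees (mean divided by its standard
#' error), matching the conventional scaled mean-decrease-in-accuracy
#' importance.
#'
#' @inheritParams cv_rf
#' @return A `variable_importance` data frame: `gene`, `importance`
#'   (z-scaled), `raw`, sorted by decreasing importance.
#' @export
variable_importance <- function(matrix, labels, config = forest_config()) {
  x <- if (inherits(matrix, "mutation_matrix")) matrix$values else
    as.matrix(matrix)
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2)
    np_stop("labels must contain both classes", "neopred_degenerate_labels")
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(x)))) else
    config$mtry
  fit <- rf_fit_cpp(x, y, config$n_trees, mtry, 1L, config$seed)
  imp <- rf_importance_cpp(fit, x, y, np_seed(config$seed, 99L))
  out <- data.frame(gene = colnames(x), importance = imp$scaled,
                    raw = imp$raw, stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("variable_importance", "data.frame")
  out
}

#' Select genes above the importance cutoff
#'
#' @param table A [variable_importance()] result.
#' @param cutoff Exclusive cutoff on the z-scaled importance (default 3).
#' @return Character vector of gene names with importance strictly greater
#'   than `cutoff`.
#' @export
select_important <- function(table, cutoff = 3) {
  table$gene[table$importance > cutoff]
}

#' Expand a gene set through an interactome
#'
#' Returns the input genes plus all their first-degree neighbours in an
#' undirected gene-gene interaction graph; genes absent from the graph pass
#' through with zero neighbours.
#'
#' @param genes Character vector of seed genes.
#' @param edges Data frame with two columns of gene names (undirected
#'   edges); self-loops are ignored.
#' @return Sorted character vector of the expanded, deduplicated gene set.
#' @export
expand_interactome <- function(genes, edges) {
  if (nrow(edges) == 0) return(sort(unique(genes)))
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  nb <- c(b[a %in% genes], a[b %in% genes])
  sort(unique(c(genes, nb)))
}
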