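#' Binding-model configuration
#'
#' Hyperparameters of the two-convolution-layer binding classifier. The
#' defaults follow the optimized setting: 50 first-layer kernels, 10
#' second-layer kernels, kernel window 5 spanning the full 183-residue HLA
#' axis, stride 1, mini-batches of 1000 examples, no pooling and no dropout.
#' `lambda1` is the L2 weight penalty, `lambda2` the L1 penalty on the last
#' hidden layer's activations, and `lambda3` the max-norm bound on each
#' neuron's incoming weight vector.
#'
#' @param n_kernels1,n_kernels2 Kernel counts of the two convolution layers.
#' @param window Kernel window size along the peptide axis (1-5).
#' @param n_hidden Width of the fully connected layer.
#' @param batch_size Mini-batch size in examples.
#' @param learning_rate,momentum SGD-with-momentum settings.
#' @param lambda1,lambda2,lambda3 Regularization strengths (see above).
#' @param epochs Number of passes over the training data.
#' @param seed Integer seed controlling initialization and batching.
#' @param hla_window Fraction of the HLA axis spanned by kernels: `"full"`
#'   (default), `"1/2"` or `"2/3"`.
#' @return A `model_config` list.
#' @export
model_config <- function(n_kernels1 = 50L, n_kernels2 = 10L, window = 5L,
                         n_hidden = 32L, batch_size = 1000L,
                         learning_rate = 0.01, momentum = 0.9,
                         lambda1 = 0.0001, lambda2 = 0.0001, lambda3 = 3,
                         epochs = 20L, seed = 1L,
                         hla_window = c("full", "1/2", "2/3")) {
  hla_window <- match.arg(hla_window)
  stopifnot(window >= 1L, window <= 5L, lambda3 > 0, batch_size >= 1L,
            n_kernels1 >= 1L, n_kernels2 >= 1L, n_hidden >= 1L, epochs >= 1L)
  structure(list(n_kernels1 = as.integer(n_kernels1),
                 n_kernels2 = as.integer(n_kernels2),
                 window = as.integer(window), stride = 1L,
                 n_hidden = as.integer(n_hidden),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 hla_window = hla_window),
            class = "model_config")
}

#' Binary binding label from affinity
#'
#' Applies the conventional binder threshold: IC50/EC50 below 500 nM is
#' binding (1), at or above 500 nM is non-binding (0).
#'
#' @param affinity_nM Positive affinity value(s) in nM.
#' @return Integer 0/1 vector.
#' @export
label_from_affinity <- function(affinity_nM) {
  if (any(!is.finite(affinity_nM)) || any(affinity_nM <= 0))
    np_stop("affinity must be positive", "neopred_value_error")
  as.integer(affinity_nM < 500)
}

#' Training set container
#'
#' @param maps `n x P x 183` array of interaction maps (see
#'   [encode_batch()]).
#' @param labels Binary 0/1 vector of length `n`.
#' @param key Character `c(locus, peptide_length)`, e.g. `c("A", "9")`.
#' @return A `training_set`.
#' @export
training_set <- function(maps, labels, key = c("A", "9")) {
  stopifnot(length(dim(maps)) == 3, dim(maps)[1] == length(labels))
  if (!all(labels %in% c(0, 1)))
    np_stop("labels must be binary 0/1", "neopred_value_error")
  structure(list(maps = maps, labels = as.integer(labels),
                 key = as.character(key)),
            class = "training_set")
}

# Effective HLA-axis width for a given config.
hla_span <- function(config) {
  switch(config$hla_window,
         "full" = HLA_LENGTH,
         "1/2" = as.integer(floor(HLA_LENGTH / 2)),
         "2/3" = as.integer(floor(2 * HLA_LENGTH / 3)))
}

# Layer geometry for peptide length P under a config.
model_dims <- function(config, P) {
  Cw <- hla_span(config)
  M1 <- config$window
  P1 <- P - M1 + 1L
  if (P1 < 1L) np_stop("kernel larger than input", "neopred_shape_error")
  M2 <- min(5L, P1)               # layer-2 window: min(5, positions left)
  P2 <- P1 - M2 + 1L
  list(P = P, C = Cw, M1 = M1, P1 = P1, M2 = M2, P2 = P2,
       n1 = config$n_kernels1, n2 = config$n_kernels2, h = config$n_hidden)
}

init_weight <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize a binding model
#'
#' Seeded uniform initialization in `+/- sqrt(6 / (fan_in + fan_out))`.
#' The model has no bias terms: every layer is `ReLU(W x)` and the output
#' layer `sigmoid(w x)`.
#'
#' @param config A [model_config()].
#' @param peptide_length 9 or 10.
#' @param key `c(locus, length)` identity of the model.
#' @return A `binding_model`: configuration, geometry and the weight
#'   matrices `W1` (M1*C x n1), `W2` (M2*n1 x n2), `Wfc` (P2*n2 x h),
#'   `Wout` (h x 1). Kernels are the columns of `W1`/`W2`.
#' @export
init_binding_model <- function(config, peptide_length = 9L,
                               key = c("A", as.character(peptide_length))) {
  d <- model_dims(config, as.integer(peptide_length))
  withr::with_seed(config$seed, {
    model <- list(
      config = config, dims = d, key = as.character(key),
      W1 = init_weight(d$M1 * d$C, d$n1),
      W2 = init_weight(d$M2 * d$n1, d$n2),
      Wfc = init_weight(d$P2 * d$n2, d$h),
      Wout = init_weight(d$h, 1L))
  })
  class(model) <- "binding_model"
  model
}

#' @exportS3Method base::print
print.binding_model <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "<binding_model> key=(%s,%s) conv1 %dx%d x%d -> conv2 %dx%d x%d -> fc %d -> sigmoid\n",
    x$key[1], x$key[2], d$M1, d$C, d$n1, d$M2, d$n1, d$n2, d$h))
  invisible(x)
}

#' Single convolution layer (reference form)
#'
#' Computes `out[i, k] = ReLU( sum_m sum_n W_k[m, n] * X[i + m - 1, n] )`
#' with stride 1 and no pooling, for kernels spanning the full second axis.
#' This is the user-facing single-map form; training uses a batched
#' equivalent.
#'
#' @param X Input matrix (positions x channels).
#' @param kernels List of `M x ncol(X)` kernel matrices, or a 3-d array
#'   `(M, ncol(X), k)`.
#' @return Matrix of dimension `(nrow(X) - M + 1) x n_kernels`.
#' @export
conv_forward <- function(X, kernels) {
  if (is.array(kernels) && length(dim(kernels)) == 3)
    kernels <- lapply(seq_len(dim(kernels)[3]), function(k) kernels[, , k])
  M <- nrow(kernels[[1]])
  if (M > nrow(X) || ncol(kernels[[1]]) != ncol(X))
    np_stop("kernel does not fit input", "neopred_shape_error")
  P1 <- nrow(X) - M + 1L
  out <- matrix(0, P1, length(kernels))
  for (k in seq_along(kernels)) {
    Wk <- kernels[[k]]
    for (i in seq_len(P1))
      out[i, k] <- sum(Wk * X[i:(i + M - 1L), , drop = FALSE])
  }
  pmax(out, 0)
}

# --- batched forward / backward ------------------------------------------

# im2col over the position axis: (n, P, C) -> (n*Pout, M*C), layout
# matching vec(W[m, c]) with m fastest.
im2col <- function(arr, M) {
  n <- dim(arr)[1]; P <- dim(arr)[2]; C <- dim(arr)[3]
  Pout <- P - M + 1L
  out <- array(0, c(n, Pout, M * C))
  for (m in seq_len(M))
    out[, , (seq_len(C) - 1L) * M + m] <- arr[, m:(m + Pout - 1L), ,
                                              drop = FALSE]
  dim(out) <- c(n * Pout, M * C)
  out
}

# inverse scatter of im2col for gradients: (n*Pout, M*C) -> (n, P, C)
col2im <- function(mat, n, P, C, M) {
  Pout <- P - M + 1L
  dim(mat) <- c(n, Pout, M * C)
  out <- array(0, c(n, P, C))
  for (m in seq_len(M))
    out[, m:(m + Pout - 1L), ] <- out[, m:(m + Pout - 1L), , drop = FALSE] +
      mat[, , (seq_len(C) - 1L) * M + m, drop = FALSE]
  out
}

forward_pass <- function(model, maps) {
  d <- model$dims
  n <- dim(maps)[1]
  if (dim(maps)[2] != d$P)
    np_stop("input peptide length does not match model", "neopred_shape_error")
  X <- maps[, , seq_len(d$C), drop = FALSE]   # hla_window restriction
  A <- im2col(X, d$M1)                        # (n*P1, M1*C)
  Z1 <- A %*% model$W1
  C1 <- pmax(Z1, 0)
  C1a <- C1; dim(C1a) <- c(n, d$P1, d$n1)
  B <- im2col(C1a, d$M2)                      # (n*P2, M2*n1)
  Z2 <- B %*% model$W2
  C2 <- pmax(Z2, 0)
  F2 <- C2; dim(F2) <- c(n, d$P2 * d$n2)
  Z3 <- F2 %*% model$Wfc
  H <- pmax(Z3, 0)
  Z4 <- H %*% model$Wout
  p <- 1 / (1 + exp(-Z4))
  list(A = A, Z1 = Z1, B = B, Z2 = Z2, F2 = F2, Z3 = Z3, H = H,
       prob = as.numeric(p), n = n)
}

#' Forward pass of the binding model
#'
#' Runs conv1 -> ReLU -> conv2 -> ReLU -> fully connected -> ReLU ->
#' sigmoid on one interaction map (or a batch) and retains the last hidden
#' activations `H` needed by the activation penalty.
#'
#' @param model A `binding_model`.
#' @param X An `interaction_map`, a `P x 183` matrix, or an `n x P x 183`
#'   array.
#' @return A `forward_trace`: list with `conv1`, `conv2`, `H` and `prob`.
#' @export
model_forward <- function(model, X) {
  if (inherits(X, "interaction_map")) X <- X$values
  if (is.matrix(X)) { dim(X) <- c(1L, dim(X)) }
  fp <- forward_pass(model, X)
  d <- model$dims
  conv1 <- pmax(fp$Z1, 0); dim(conv1) <- c(fp$n, d$P1, d$n1)
  conv2 <- pmax(fp$Z2, 0); dim(conv2) <- c(fp$n, d$P2, d$n2)
  structure(list(conv1 = conv1, conv2 = conv2, H = fp$H, prob = fp$prob),
            class = "forward_trace")
}

#' Predict binding probabilities
#'
#' @param object A `binding_model`.
#' @param maps `n x P x 183` array (or single map/matrix).
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.binding_model <- function(object, maps, ...) {
  model_forward(object, maps)$prob
}

all_weights <- function(model) {
  list(W1 = model$W1, W2 = model$W2, Wfc = model$Wfc, Wout = model$Wout)
}

#' Regularized training objective
#'
#' The objective is the sum of the negative log likelihood over the batch,
#' an L2 penalty `lambda1 * sum(W^2)` over all weight entries, and an L1
#' penalty `lambda2 * sum(|H|)` on the last hidden layer's outputs.
#' Probabilities are clamped to `[1e-12, 1 - 1e-12]` inside the log.
#' Additionally the max-norm constraint `||W_neuron||_2 <= lambda3` is
#' checked per neuron (columns of each weight matrix) and violations are
#' listed; the constraint is enforced during training by projection.
#'
#' @param model A `binding_model`.
#' @param maps Input array `n x P x 183`.
#' @param labels Binary labels.
#' @param lambda1,lambda2,lambda3 Override the model config when given.
#' @return List with `loss`, `nll` and `violations` (data frame of layer,
#'   neuron, norm).
#' @export
binding_objective <- function(model, maps, labels,
                              lambda1 = model$config$lambda1,
                              lambda2 = model$config$lambda2,
                              lambda3 = model$config$lambda3) {
  if (is.matrix(maps)) dim(maps) <- c(1L, dim(maps))
  fp <- forward_pass(model, maps)
  eps <- 1e-12
  p <- pmin(pmax(fp$prob, eps), 1 - eps)
  y <- as.numeric(labels)
  nll <- -sum(log(y * p + (1 - y) * (1 - p)))
  l2 <- sum(vapply(all_weights(model), function(w) sum(w^2), numeric(1)))
  loss <- nll + lambda1 * l2 + lambda2 * sum(abs(fp$H))
  viol <- list()
  for (nm in names(all_weights(model))) {
    W <- all_weights(model)[[nm]]
    norms <- sqrt(colSums(W^2))
    bad <- which(norms > lambda3)
    if (length(bad) > 0)
      viol[[nm]] <- data.frame(layer = nm, neuron = bad, norm = norms[bad])
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(layer = character(0), neuron = integer(0), norm = numeric(0))
  list(loss = loss, nll = nll, violations = violations)
}

#' Analytic gradient of the training objective
#'
#' Backpropagation through the full model for the objective of
#' [binding_objective()] (sum form over the batch). Used by the SGD trainer
#' and checkable against finite differences.
#'
#' @inheritParams binding_objective
#' @return List of gradients `W1`, `W2`, `Wfc`, `Wout`.
#' @export
binding_gradient <- function(model, maps, labels,
                             lambda1 = model$config$lambda1,
                             lambda2 = model$config$lambda2) {
  if (is.matrix(maps)) dim(maps) <- c(1L, dim(maps))
  d <- model$dims
  fp <- forward_pass(model, maps)
  n <- fp$n
  y <- as.numeric(labels)
  dZ4 <- matrix(fp$prob - y, n, 1)            # d(NLL)/d(logit)
  gWout <- t(fp$H) %*% dZ4 + 2 * lambda1 * model$Wout
  dH <- dZ4 %*% t(model$Wout) + lambda2       # + d(lambda2 * sum H)/dH
  dZ3 <- dH * (fp$Z3 > 0)
  gWfc <- t(fp$F2) %*% dZ3 + 2 * lambda1 * model$Wfc
  dF2 <- dZ3 %*% t(model$Wfc)
  dC2 <- dF2; dim(dC2) <- c(n * d$P2, d$n2)
  dZ2 <- dC2 * (fp$Z2 > 0)
  gW2 <- t(fp$B) %*% dZ2 + 2 * lambda1 * model$W2
  dB <- dZ2 %*% t(model$W2)
  dC1a <- col2im(dB, n, d$P1, d$n1, d$M2)
  dC1 <- dC1a; dim(dC1) <- c(n * d$P1, d$n1)
  dZ1 <- dC1 * (fp$Z1 > 0)
  gW1 <- t(fp$A) %*% dZ1 + 2 * lambda1 * model$W1
  list(W1 = gW1, W2 = gW2, Wfc = gWfc, Wout = gWout)
}

# Project every neuron (column) onto the L2 ball of radius lambda3.
max_norm_project <- function(W, lambda3) {
  norms <- sqrt(colSums(W^2))
  over <- norms > lambda3
  if (any(over))
    W[, over] <- sweep(W[, over, drop = FALSE], 2,
                       lambda3 / norms[over], "*")
  W
}

#' Train the binding CNN by SGD with momentum
#'
#' Minimizes the regularized objective by mini-batch stochastic gradient
#' descent with momentum; after every update each neuron's incoming weight
#' vector is projected onto the L2 ball of radius `lambda3`. Dropout is not
#' used. Fully deterministic under the config seed.
#'
#' @param config A [model_config()].
#' @param data A [training_set()].
#' @param trace Logical; record the per-epoch objective and, after every
#'   single update, the maximum neuron norm (`norm_trace`), so the max-norm
#'   contract can be audited continuously.
#' @return The trained `binding_model` (with `history` and `norm_trace`
#'   elements when `trace = TRUE`).
#' @export
train_binding_model <- function(config, data, trace = FALSE) {
  if (length(unique(data$labels)) < 2)
    np_stop("training data must contain both classes",
            "neopred_degenerate_labels")
  n <- dim(data$maps)[1]
  P <- dim(data$maps)[2]
  model <- init_binding_model(config, P, key = data$key)
  vel <- lapply(all_weights(model), function(w) w * 0)
  lr <- config$learning_rate
  mom <- config$momentum
  history <- numeric(0)
  norm_trace <- numeric(0)
  withr::with_seed(np_seed(config$seed, 1L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        g <- binding_gradient(model, data$maps[idx, , , drop = FALSE],
                              data$labels[idx])
        for (nm in names(g)) {
          vel[[nm]] <- mom * vel[[nm]] - lr * g[[nm]]
          model[[nm]] <- max_norm_project(model[[nm]] + vel[[nm]],
                                          config$lambda3)
        }
        if (trace)
          norm_trace[length(norm_trace) + 1L] <-
            max(vapply(all_weights(model),
                       function(w) max(sqrt(colSums(w^2))), numeric(1)))
      }
      if (trace)
        history[ep] <- binding_objective(model, data$maps, data$labels)$loss
    }
  })
  if (trace) {
    model$history <- history
    model$norm_trace <- norm_trace
  }
  model
}

#' Classifier evaluation: AUC and F1
#'
#' AUC is computed from the rank (Mann-Whitney) statistic with ties sharing
#' mid-ranks; F1 uses the fixed score threshold 0.5 (scores at the boundary
#' count as positive calls).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels (both classes required).
#' @param threshold F1 decision threshold.
#' @return An `eval_report`: list with `auc`, `f1`, `threshold`, `n_pos`,
#'   `n_neg`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    np_stop("both classes required for evaluation",
            "neopred_degenerate_labels")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  structure(list(auc = auc, f1 = f1, threshold = threshold,
                 n_pos = n_pos, n_neg = n_neg),
            class = "eval_report")
}

#' @exportS3Method base::print
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> AUC=%.4f F1=%.4f (threshold %.2f, %d+/%d-)\n",
              x$auc, x$f1, x$threshold, x$n_pos, x$n_neg))
  invisible(x)
}

#' Hyperparameter grid search
#'
#' Trains one model per point of the hyperparameter grid and returns the
#' configuration maximizing validation AUC. Grid points are enumerated in
#' lexicographic order of the supplied grids (first grid most significant),
#' and ties are broken by the first point in that order.
#'
#' @param grids Named list of hyperparameter value vectors; names must be
#'   [model_config()] argument names (e.g. `learning_rate`, `momentum`,
#'   `lambda1`, `lambda2`).
#' @param train_data,val_data Disjoint [training_set()]s.
#' @param base_config Config supplying all non-gridded settings.
#' @param seed Seed applied to every trained model.
#' @return List with `config` (the winning `model_config`), `auc`, and
#'   `results` (a data frame of all grid points with validation AUC).
#' @export
grid_search <- function(grids, train_data, val_data,
                        base_config = model_config(), seed = 1L) {
  stopifnot(length(grids) > 0, all(lengths(grids) > 0))
  if (dim(val_data$maps)[1] == 0)
    np_stop("empty validation set", "neopred_config_error")
  # expand.grid varies the first column fastest; feed reversed grids so the
  # row order is lexicographic in the original listing.
  g <- do.call(expand.grid,
               c(rev(grids), list(KEEP.OUT.ATTRS = FALSE,
                                  stringsAsFactors = FALSE)))
  g <- g[, rev(seq_along(grids)), drop = FALSE]
  names(g) <- names(grids)
  aucs <- numeric(nrow(g))
  for (r in seq_len(nrow(g))) {
    cfg <- base_config
    for (nm in names(g)) cfg[[nm]] <- g[[nm]][r]
    cfg$seed <- as.integer(seed)
    m <- train_binding_model(cfg, train_data)
    aucs[r] <- evaluate_scores(predict(m, val_data$maps),
                               val_data$labels)$auc
  }
  best <- which.max(aucs)      # first maximum = lexicographic tie-break
  cfg <- base_config
  for (nm in names(g)) cfg[[nm]] <- g[[nm]][best]
  cfg$seed <- as.integer(seed)
  list(config = cfg, auc = aucs[best], results = cbind(g, auc = aucs))
}
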