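#' Immune marker gene sets
#'
#' The immune-score marker genes, grouped as cytolytic markers, HLA
#' molecules, IFN-gamma pathway genes, chemokines and adhesion molecules.
#'
#' @return Named list of character vectors.
#' @export
immune_marker_sets <- function() {
  list(
    cytolytic = c("GZMA", "GZMB", "PRF1", "GNLY"),
    hla = c("HLA-A", "HLA-B", "HLA-C", "HLA-E", "HLA-F", "HLA-G", "HLA-H",
            "HLA-DMA", "HLA-DMB", "HLA-DOA", "HLA-DOB", "HLA-DPA1",
            "HLA-DPB1", "HLA-DQA1", "HLA-DQA2", "HLA-DQB1", "HLA-DRA",
            "HLA-DRB1"),
    ifng = c("IFNG", "IFNGR1", "IFNGR2", "IRF1", "STAT1", "PSMB9"),
    chemokines = c("CCR5", "CCL3", "CCL4", "CCL5", "CXCL9", "CXCL10",
                   "CXCL11"),
    adhesion = c("ICAM1", "ICAM2", "ICAM3", "ICAM4", "ICAM5", "VCAM1"))
}

#' Immune score of one sample
#'
#' Geometric mean of the expression levels of the marker genes:
#' `exp(mean(log(x + delta)))` on the (log2-normalized) expression values,
#' with a pseudocount `delta` guarding zeros (default 1; use 0 for strictly
#' positive inputs).
#'
#' @param expr Named numeric vector of one sample's expression values.
#' @param markers Character vector of marker genes (default: all groups of
#'   [immune_marker_sets()]).
#' @param delta Pseudocount added before the log.
#' @return Numeric scalar.
#' @export
immune_score <- function(expr, markers = unlist(immune_marker_sets()),
                         delta = 1) {
  present <- intersect(markers, names(expr))
  if (is.null(names(expr)) && length(markers) == length(expr)) {
    present <- markers
    names(expr) <- markers
  }
  if (length(present) == 0)
    np_stop("no marker genes present in the expression vector",
            "neopred_marker_error")
  x <- expr[present] + delta
  if (any(x <= 0))
    np_stop("marker expression must be positive after pseudocount",
            "neopred_value_error")
  exp(mean(log(x)))
}

#' Select immune markers by correlation with neoantigen load
#'
#' Ranks the candidate marker genes by Spearman correlation between their
#' expression column and the per-sample neoantigen load, and keeps the top
#' `n_markers` genes with strictly positive correlation (ties broken
#' alphabetically).
#'
#' @param expr Samples x genes expression matrix (sample rows aligned with
#'   `loads`).
#' @param loads Per-sample neoantigen counts.
#' @param n_markers Number of markers to keep.
#' @param candidates Candidate gene list (default: the printed marker
#'   sets).
#' @return Character vector of selected genes (<= `n_markers`).
#' @export
select_markers <- function(expr, loads, n_markers = 5,
                           candidates = unlist(immune_marker_sets())) {
  stopifnot(nrow(expr) == length(loads))
  cand <- intersect(candidates, colnames(expr))
  if (length(cand) == 0)
    np_stop("no candidate markers in the expression table",
            "neopred_marker_error")
  rho <- vapply(cand, function(g)
    suppressWarnings(cor(expr[, g], loads, method = "spearman")),
    numeric(1))
  rho[is.na(rho)] <- 0
  pos <- rho > 0
  if (!any(pos))
    np_stop("no marker positively correlated with load",
            "neopred_marker_error")
  ord <- order(-rho[pos], names(rho)[pos])
  head(names(rho)[pos][ord], n_markers)
}

#' Immune-evasion labels from load and signature percentiles
#'
#' A sample evades immunity when its neoantigen load is strictly above the
#' 70th percentile of loads and its immune signature (mean of the selected
#' markers) is strictly below the 30th percentile of signatures.
#' Percentiles use the linear-interpolation convention.
#'
#' @param loads Per-sample neoantigen counts (length >= 10).
#' @param signatures Per-sample immune signature, aligned with `loads`.
#' @param load_pct,sig_pct Percentile cutoffs (defaults 0.70 / 0.30).
#' @return Logical vector of evasion labels.
#' @export
evasion_labels <- function(loads, signatures, load_pct = 0.70,
                           sig_pct = 0.30) {
  stopifnot(length(loads) == length(signatures), length(loads) >= 10)
  if (max(loads) == min(loads) || max(signatures) == min(signatures))
    np_stop("constant load or signature vector",
            "neopred_degenerate_distribution")
  qload <- quantile(loads, load_pct, type = 7, names = FALSE)
  qsig <- quantile(signatures, sig_pct, type = 7, names = FALSE)
  loads > qload & signatures < qsig
}

#' Min-max scaling of a resistance parameter
#'
#' Scales raw parameter values to `[0, 1]`:
#' `scaled(e_i) = (e_i - E_min) / (E_max - E_min)`. Prediction scores that
#' already live in `[0, 1]` (forest vote ratios) are passed through
#' unchanged with `is_score = TRUE`.
#'
#' @param values Numeric vector of one parameter's raw values.
#' @param is_score Logical; skip scaling for probability-scale scores.
#' @return Numeric vector in `[0, 1]`.
#' @export
scale_parameter <- function(values, is_score = FALSE) {
  if (is_score) return(values)
  rng <- range(values)
  if (rng[2] == rng[1])
    np_stop("constant parameter vector cannot be scaled",
            "neopred_degenerate_distribution")
  (values - rng[1]) / (rng[2] - rng[1])
}

# Cross-validated linear-probability predictions for the "simple" method.
cv_lm_predictions <- function(x, y, foldid) {
  oof <- numeric(length(y))
  for (f in sort(unique(foldid))) {
    tr <- foldid != f
    dtr <- data.frame(y = y[tr], x[tr, , drop = FALSE], check.names = FALSE)
    fit <- stats::lm(y ~ ., data = dtr)
    dte <- data.frame(x[!tr, , drop = FALSE], check.names = FALSE)
    oof[!tr] <- predict(fit, newdata = dte)
  }
  oof
}

#' Regularized regression of resistance / evasion on parameters
#'
#' Fits the binary outcome by four linear-model variants -- simple
#' (unpenalized linear probability model), lasso, elastic net (mixing 0.5)
#' and ridge -- with a shared stratified 5-fold split. Penalties are chosen
#' by cross-validation; AUC is computed from the cross-validated
#' predictions; variable importance is the ranking of absolute standardized
#' coefficients at the CV-optimal penalty.
#'
#' @param features Samples x parameters numeric matrix, already scaled to
#'   `[0, 1]` (see [scale_parameter()]).
#' @param labels Logical/0-1 outcome, both classes present.
#' @param folds Number of CV folds.
#' @param seed Integer seed for the fold split.
#' @return A `regression_report`: per-method list with `auc`,
#'   `coefficients` (named, no intercept) and `importance` (data frame of
#'   feature, standardized coefficient magnitude, rank).
#' @export
fit_regressions <- function(features, labels, folds = 5L, seed = 1L) {
  x <- as.matrix(features)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as.numeric(as.logical(labels))
  if (length(unique(y)) < 2)
    np_stop("labels must contain both classes", "neopred_degenerate_labels")
  foldid <- stratified_folds(y, folds, np_seed(seed, 17L))

  # glmnet needs >= 2 columns; pad single-parameter designs with a dummy.
  xg <- x
  padded <- FALSE
  if (ncol(xg) < 2) {
    xg <- cbind(xg, .dummy = 0)
    padded <- TRUE
  }
  sds <- apply(x, 2, sd)

  importance_from <- function(beta) {
    std <- abs(beta) * sds
    data.frame(feature = names(beta), std_coef = unname(std),
               rank = rank(-std, ties.method = "min"),
               stringsAsFactors = FALSE)
  }

  report <- list()
  # simple: unpenalized linear probability model
  oof <- cv_lm_predictions(as.data.frame(x), y, foldid)
  full <- stats::lm(y ~ ., data = data.frame(y = y, x, check.names = FALSE))
  beta <- coef(full)[-1]
  names(beta) <- colnames(x)
  beta[is.na(beta)] <- 0
  report$simple <- list(auc = evaluate_scores(oof, y)$auc,
                        coefficients = beta,
                        importance = importance_from(beta))

  for (m in c("lasso", "elastic_net", "ridge")) {
    alpha <- switch(m, lasso = 1, elastic_net = 0.5, ridge = 0)
    cvfit <- glmnet::cv.glmnet(xg, y, family = "gaussian", alpha = alpha,
                               foldid = foldid, keep = TRUE)
    ilam <- match(cvfit$lambda.min, cvfit$lambda)
    oof <- cvfit$fit.preval[, ilam]
    beta <- as.numeric(coef(cvfit, s = "lambda.min"))[-1]
    names(beta) <- colnames(xg)
    if (padded) beta <- beta[colnames(x)]
    report[[m]] <- list(auc = evaluate_scores(oof, y)$auc,
                        coefficients = beta,
                        importance = importance_from(beta),
                        lambda = cvfit$lambda.min)
  }
  structure(report, class = "regression_report")
}

#' @exportS3Method base::print
print.regression_report <- function(x, ...) {
  cat("<regression_report>\n")
  for (m in names(x))
    cat(sprintf("  %-12s AUC=%.4f\n", m, x[[m]]$auc))
  invisible(x)
}
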