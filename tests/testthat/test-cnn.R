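test_that("label_from_affinity applies the 500 nM convention", {
  expect_identical(label_from_affinity(499), 1L)
  expect_identical(label_from_affinity(500), 0L)
  expect_identical(label_from_affinity(c(10, 499.999, 500, 50000)),
                   c(1L, 1L, 0L, 0L))
  expect_error(label_from_affinity(-1), class = "neopred_value_error")
  expect_error(label_from_affinity(0), class = "neopred_value_error")
})

test_that("conv_forward matches the nested-loop form", {
  # all-zero input -> all-zero output
  X0 <- matrix(0, 9, 183)
  k1 <- list(matrix(1, 5, 183))
  expect_true(all(conv_forward(X0, k1) == 0))
  # all-ones kernel on all-ones map: every output is 5 * 183 = 915
  expect_true(all(conv_forward(matrix(1, 9, 183), k1) == 915))
  expect_equal(dim(conv_forward(matrix(1, 9, 183), k1)), c(5, 1))

  # random instances vs an explicit double-sum oracle
  for (seed in 1:5) {
    withr::with_seed(seed, {
      P <- sample(6:10, 1); C <- sample(4:8, 1)
      M <- sample(1:min(5, P), 1); K <- sample(1:3, 1)
      X <- matrix(rnorm(P * C), P, C)
      kern <- lapply(seq_len(K), function(k) matrix(rnorm(M * C), M, C))
    })
    got <- conv_forward(X, kern)
    ref <- matrix(0, P - M + 1, K)
    for (k in seq_len(K)) for (i in seq_len(P - M + 1)) {
      acc <- 0
      for (m in seq_len(M)) for (n in seq_len(C))
        acc <- acc + kern[[k]][m, n] * X[i + m - 1, n]
      ref[i, k] <- max(acc, 0)
    }
    expect_equal(got, ref, tolerance = 1e-12)
  }
  expect_error(conv_forward(matrix(0, 3, 183), k1),
               class = "neopred_shape_error")
})

test_that("model_forward composes the layers; zero model gives 0.5", {
  cfg <- tiny_config()
  m <- init_binding_model(cfg, 9)
  maps <- withr::with_seed(3, array(rnorm(2 * 9 * 183), c(2, 9, 183)))
  tr <- model_forward(m, maps)
  expect_true(all(tr$prob > 0 & tr$prob < 1))
  expect_true(all(tr$conv1 >= 0) && all(tr$conv2 >= 0) && all(tr$H >= 0))

  m0 <- m
  for (nm in c("W1", "W2", "Wfc", "Wout")) m0[[nm]][] <- 0
  expect_equal(model_forward(m0, maps)$prob, c(0.5, 0.5))

  # composition equals layer-level oracles
  d <- m$dims
  X <- maps[1, , ]
  c1 <- conv_forward(X, lapply(seq_len(d$n1), function(k)
    matrix(m$W1[, k], d$M1, d$C)))
  c2 <- conv_forward(c1, lapply(seq_len(d$n2), function(k)
    matrix(m$W2[, k], d$M2, d$n1)))
  H <- pmax(as.numeric(c2) %*% m$Wfc, 0)
  p <- 1 / (1 + exp(-(H %*% m$Wout)))
  expect_equal(model_forward(m, X)$prob, as.numeric(p), tolerance = 1e-12)

  expect_error(model_forward(m, array(0, c(1, 10, 183))),
               class = "neopred_shape_error")
})

test_that("objective has the stated closed forms and gradient", {
  cfg <- tiny_config(lambda1 = 0, lambda2 = 0)
  m <- init_binding_model(cfg, 9)
  m0 <- m
  for (nm in c("W1", "W2", "Wfc", "Wout")) m0[[nm]][] <- 0
  map1 <- array(withr::with_seed(1, rnorm(9 * 183)), c(1, 9, 183))
  # one sample, y = 1, f = 0.5, no regularization -> loss = ln 2
  expect_equal(binding_objective(m0, map1, 1, lambda1 = 0,
                                 lambda2 = 0)$loss, log(2))

  # analytic gradient matches central finite differences
  cfg2 <- tiny_config(lambda1 = 1e-3, lambda2 = 1e-2)
  m2 <- init_binding_model(cfg2, 9)
  maps <- array(withr::with_seed(2, rnorm(3 * 9 * 183)), c(3, 9, 183))
  y <- c(1, 0, 1)
  g <- binding_gradient(m2, maps, y)
  f <- function(mod) binding_objective(mod, maps, y)$loss
  h <- 1e-5
  for (nm in c("W1", "W2", "Wfc", "Wout")) {
    idx <- withr::with_seed(5, sample(length(m2[[nm]]),
                                      min(4, length(m2[[nm]]))))
    for (ii in idx) {
      mp <- m2; mp[[nm]][ii] <- mp[[nm]][ii] + h
      mm <- m2; mm[[nm]][ii] <- mm[[nm]][ii] - h
      num <- (f(mp) - f(mm)) / (2 * h)
      expect_lt(abs(num - g[[nm]][ii]) / max(abs(num), 1e-8), 1e-5)
    }
  }
})

test_that("training is deterministic, respects max-norm, reduces loss", {
  E <- fixture_energy()
  hla <- fixture_hla()
  motif <- motif_from_energy(E, hla, anchors = c(2, 9))
  dat <- gen_binding_data(200, motif, fixture_hla_pool(), seed = 31)
  maps <- encode_batch(dat$table$peptide, hla, E)
  ts <- training_set(maps, dat$table$label)

  cfg <- tiny_config(epochs = 3L, lambda3 = 1.0, seed = 8)
  m1 <- train_binding_model(cfg, ts, trace = TRUE)
  m2 <- train_binding_model(cfg, ts)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$Wout, m2$Wout)

  # every neuron norm bounded by lambda3 after every update
  expect_true(all(m1$norm_trace <= 1.0 + 1e-12))
  for (nm in c("W1", "W2", "Wfc", "Wout"))
    expect_true(all(sqrt(colSums(m1[[nm]]^2)) <= 1.0 + 1e-12))

  # loss decreases on separable data at a small learning rate
  expect_lt(m1$history[length(m1$history)], m1$history[1] * 1.01)

  ts_one <- training_set(maps[dat$table$label == 1, , ],
                         dat$table$label[dat$table$label == 1])
  expect_error(train_binding_model(cfg, ts_one),
               class = "neopred_degenerate_labels")
})

test_that("evaluate_scores: rank AUC with mid-rank ties, F1 at 0.5", {
  # perfectly separated scores
  expect_equal(evaluate_scores(c(0.9, 0.8, 0.2, 0.1),
                               c(1, 1, 0, 0))$auc, 1)
  # TP=2, FP=1, FN=1 -> F1 = 2/3
  r <- evaluate_scores(c(0.9, 0.8, 0.7, 0.3), c(1, 1, 0, 1))
  expect_equal(r$f1, 2 * 2 / (2 * 2 + 1 + 1))
  # constant scores tie everywhere -> AUC 0.5
  expect_equal(evaluate_scores(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  # 10 scores vs the all-pairs concordance oracle (with ties = 1/2)
  withr::with_seed(7, {
    sc <- round(runif(10), 1)
    lb <- rbinom(10, 1, 0.5)
  })
  if (length(unique(lb)) > 1) {
    pos <- sc[lb == 1]; neg <- sc[lb == 0]
    conc <- 0
    for (a in pos) for (b in neg)
      conc <- conc + (a > b) + 0.5 * (a == b)
    expect_equal(evaluate_scores(sc, lb)$auc,
                 conc / (length(pos) * length(neg)))
  }
  expect_error(evaluate_scores(1:3 / 4, c(1, 1, 1)),
               class = "neopred_degenerate_labels")
})

test_that("grid_search enumerates the product and breaks ties first", {
  E <- fixture_energy()
  hla <- fixture_hla()
  dat <- gen_binding_data(60, motif_from_energy(E, hla),
                          fixture_hla_pool(), seed = 41)
  maps <- encode_batch(dat$table$peptide, hla, E)
  tr <- training_set(maps[1:40, , ], dat$table$label[1:40])
  va <- training_set(maps[41:60, , ], dat$table$label[41:60])
  grids <- list(learning_rate = c(1e-4, 1e-3), momentum = c(0.1, 0.5))
  res <- grid_search(grids, tr, va, tiny_config(epochs = 1L), seed = 2)
  expect_equal(nrow(res$results), 4)
  # lexicographic order: first grid most significant
  expect_equal(res$results$learning_rate, c(1e-4, 1e-4, 1e-3, 1e-3))
  expect_equal(res$results$momentum, c(0.1, 0.5, 0.1, 0.5))
  expect_equal(res$auc, max(res$results$auc))
  first_best <- which.max(res$results$auc)
  expect_equal(res$config$learning_rate,
               res$results$learning_rate[first_best])
  expect_equal(res$config$momentum, res$results$momentum[first_best])
})

test_that("binding model serialization round trip is bit-exact", {
  cfg <- tiny_config(seed = 9)
  m <- init_binding_model(cfg, 9, key = c("B", "9"))
  path <- withr::local_tempfile(fileext = ".json")
  write_binding_model(m, path)
  m2 <- read_binding_model(path)
  expect_identical(m2$W1, m$W1)
  expect_identical(m2$W2, m$W2)
  expect_identical(m2$Wfc, m$Wfc)
  expect_identical(m2$Wout, m$Wout)
  expect_identical(m2$key, c("B", "9"))
  maps <- array(withr::with_seed(1, rnorm(9 * 183)), c(1, 9, 183))
  expect_identical(predict(m, maps), predict(m2, maps))
})
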