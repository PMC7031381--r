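mutrec <- function(sample, gene, class = "missense", sift = TRUE,
                   prov = TRUE) {
  data.frame(sample = sample, gene = gene, position = 10, ref = "A",
             alt = if (class == "synonymous") "A" else "V", class = class,
             sift_damaging = sift, provean_deleterious = prov,
             stringsAsFactors = FALSE)
}

test_that("build_mutation_matrix applies the strict >5% filter and flags", {
  samples <- sprintf("S%02d", 1:20)
  muts <- rbind(
    mutrec(c("S01", "S02"), "KEEP"),          # 2/20 = 10% > 5%
    mutrec("S01", "DROP"),                    # 1/20 = 5%, strict > drops it
    mutrec(c("S01", "S02"), "HALF", sift = TRUE, prov = FALSE))
  mm <- build_mutation_matrix(muts, samples, "functional")
  expect_identical(colnames(mm$values), "KEEP")
  expect_equal(sum(mm$values[, "KEEP"]), 2)
  expect_true(all(colMeans(mm$values) > 0.05))

  # boundary sensitivity: removing one mutated sample drops the gene
  muts2 <- mutrec(c("S01", "S02"), "KEEP")
  expect_error(build_mutation_matrix(muts2[1, ], samples, "functional"),
               class = "neopred_empty_feature_set")

  syn <- rbind(mutrec(c("S01", "S02", "S03"), "SYNG", "synonymous",
                      NA, NA))
  sm <- build_mutation_matrix(syn, samples, "synonymous")
  expect_identical(colnames(sm$values), "SYNG")
})

test_that("matched_control matches the functional feature count", {
  co <- gen_cohort(cohort_spec(seed = 3))
  fm <- build_mutation_matrix(co$mutations, co$samples, "functional")
  sm <- matched_control(fm, co$mutations)
  expect_equal(ncol(sm$values), ncol(fm$values))
  expect_identical(sm$class, "synonymous")
  expect_identical(rownames(sm$values), rownames(fm$values))
  # raising the threshold never increases the count (monotone filter)
  syn_freq <- colMeans(sm$values)
  expect_true(all(syn_freq > sm$threshold))

  # insufficient synonymous genes -> error
  few <- co$mutations[co$mutations$class != "synonymous" |
                        co$mutations$gene %in% co$genes[1:3], ]
  expect_error(matched_control(fm, few),
               class = "neopred_insufficient_control")
})

test_that("cv_rf is seeded, bounded and near-chance under permuted labels", {
  co <- gen_cohort(cohort_spec(n_samples = 80, n_genes = 40, seed = 5))
  fm <- build_mutation_matrix(co$mutations, co$samples, "functional")
  cfg <- forest_config(n_trees = 100, repeats = 2, folds = 5, seed = 4)
  r1 <- cv_rf(fm, co$truth$resistant, cfg)
  r2 <- cv_rf(fm, co$truth$resistant, cfg)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$auc_per_repeat, r2$auc_per_repeat)
  expect_true(all(r1$scores >= 0 & r1$scores <= 1))
  expect_equal(r1$mean_auc, mean(r1$auc_per_repeat))

  # permuted labels (seeded) -> mean AUC within 0.5 +/- 0.1 over 10 draws
  perm_auc <- vapply(1:10, function(i) {
    yp <- withr::with_seed(100 + i, sample(co$truth$resistant))
    cv_rf(fm, yp, forest_config(n_trees = 60, repeats = 1, folds = 5,
                                seed = i))$mean_auc
  }, numeric(1))
  expect_gt(mean(perm_auc), 0.4)
  expect_lt(mean(perm_auc), 0.6)

  expect_error(cv_rf(fm, rep(TRUE, 80), cfg),
               class = "neopred_degenerate_labels")
})

test_that("variable importance: constants ~0, selection strictly > 3", {
  co <- gen_cohort(cohort_spec(n_samples = 80, n_genes = 30, seed = 6))
  fm <- build_mutation_matrix(co$mutations, co$samples, "functional")
  x <- cbind(fm$values, CONST = 0L)
  imps <- lapply(1:20, function(s)
    variable_importance(x, co$truth$resistant,
                        forest_config(n_trees = 80, seed = s)))
  const_imp <- vapply(imps, function(t) t$importance[t$gene == "CONST"],
                      numeric(1))
  expect_true(all(abs(const_imp) < 1))

  tab <- data.frame(gene = c("A", "B", "C"),
                    importance = c(5, 3, 2.9), raw = c(1, 1, 1) / 100)
  expect_identical(select_important(tab, 3), "A")
})

test_that("loo_scores holds each sample out deterministically", {
  co <- gen_cohort(cohort_spec(n_samples = 40, n_genes = 20, seed = 9))
  fm <- build_mutation_matrix(co$mutations, co$samples, "functional")
  cfg <- forest_config(n_trees = 50, seed = 2)
  s1 <- loo_scores(fm, co$truth$resistant, cfg)
  s2 <- loo_scores(fm, co$truth$resistant, cfg)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_length(s1, 40)
})

test_that("expand_interactome adds first-degree neighbours symmetrically", {
  edges <- data.frame(a = c("A", "A", "B", "D"),
                      b = c("B", "C", "C", "D"))
  expect_identical(expand_interactome("A", edges), c("A", "B", "C"))
  expect_identical(expand_interactome("Z", edges), "Z")
  expect_identical(expand_interactome("Z", edges[0, ]), "Z")
  # undirected symmetry: B in N(A) iff A in N(B)
  for (g1 in c("A", "B", "C")) for (g2 in c("A", "B", "C")) {
    in12 <- g2 %in% expand_interactome(g1, edges)
    in21 <- g1 %in% expand_interactome(g2, edges)
    expect_equal(in12, in21)
  }
})

test_that("random_forest separates a strongly predictive binary feature", {
  withr::with_seed(11, {
    x <- matrix(rbinom(200 * 10, 1, 0.3), 200, 10)
    colnames(x) <- paste0("G", 1:10)
    y <- as.integer(runif(200) < ifelse(x[, 1] == 1, 0.9, 0.1))
  })
  fit <- random_forest(x[1:150, ], y[1:150], n_trees = 150, seed = 3)
  auc <- evaluate_scores(predict(fit, x[151:200, ]), y[151:200])$auc
  expect_gt(auc, 0.75)
  expect_error(random_forest(x, rep(0L, 200)),
               class = "neopred_degenerate_labels")
})
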