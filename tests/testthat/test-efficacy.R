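test_that("Emax labeling uses the strict 50% agonist threshold", {
  expect_equal(label_from_emax(c(100, 10, 50, 50.01)),
               c("agonist", "nonagonist", "nonagonist", "agonist"))
  lig <- tibble::tibble(ligand_id = c("a", "b", "c"),
                        emax = c(80, NA, 20))
  expect_message(out <- label_ligands(lig), "missing Emax")
  expect_equal(out$ligand_id, c("a", "c"))
  expect_equal(out$label, c("agonist", "nonagonist"))
  expect_error(label_ligands(tibble::tibble(ligand_id = "x", emax = -5)),
               "negative")
})

test_that("feature concatenation preserves conformation block order", {
  m <- matrix(1:6, 2, 3, byrow = TRUE)  # conf1 = 1,2,3; conf2 = 4,5,6
  expect_equal(concat_features(m), 1:6)
  expect_equal(concat_features(m[1, , drop = FALSE]), 1:3)
  # permuting conformations permutes blocks
  expect_equal(concat_features(m[2:1, ]), c(4:6, 1:3))
  fe <- gen_feature_ensemble(n_ligands = 4, n_conformations = 2,
                             dim_p = 3, seed = 1)
  X <- stack_features(fe)
  expect_equal(dim(X), c(4L, 6L))
  fe$features[[2]] <- fe$features[[2]][, 1:2]
  expect_error(stack_features(fe), "ragged")
})

test_that("the TL head learns a strong signal and stays calibrated to it", {
  fe <- gen_feature_ensemble(n_ligands = 120, delta = 2, mode = "uniform",
                             seed = 101)
  X <- stack_features(fe)
  set.seed(202)
  te <- sample(nrow(X), 40)
  cls <- train_tl_head(X[-te, ], fe$labels[-te], seed = 303)
  pred <- predict_tl(cls, X[te, ])
  expect_true(all(pred$prob > 0 & pred$prob < 1))
  expect_gte(auc_midrank(pred$prob, fe$labels[te]), 0.9)
  # reproducibility: same seed, same predictions
  cls2 <- train_tl_head(X[-te, ], fe$labels[-te], seed = 303)
  expect_identical(predict_tl(cls2, X[te, ])$prob, pred$prob)
  # batch prediction equals per-item prediction
  one <- predict_tl(cls, X[te[1], , drop = FALSE])$prob
  expect_equal(one, pred$prob[1])
  expect_error(predict_tl(cls, X[te, 1:5]), "dimension mismatch")
  expect_error(train_tl_head(X, rep("agonist", nrow(X))), "both classes")
})

test_that("head gradients match finite differences", {
  set.seed(51)
  X <- matrix(stats::rnorm(40), 8, 5)
  y <- matrix(rep(c(0, 1), 4), ncol = 1)
  p <- dyneff:::mlp_init(5, 6, 4, seed = 1)
  fwd <- dyneff:::mlp_forward(p, X)
  g <- dyneff:::mlp_grads(p, X, y, fwd)
  bce <- function(pp) {
    pr <- dyneff:::mlp_forward(pp, X)$prob
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }
  eps <- 1e-6
  for (nm in names(p)) {
    i <- 1; j <- 1
    pp <- p; pp[[nm]][i, j] <- pp[[nm]][i, j] + eps
    pm <- p; pm[[nm]][i, j] <- pm[[nm]][i, j] - eps
    fd <- (bce(pp) - bce(pm)) / (2 * eps)
    expect_equal(g[[nm]][i, j], fd, tolerance = 1e-5)
  }
})

test_that("static and two-states baselines follow the sign conventions", {
  # perfectly separated scores give AUC 1 under the default orientation
  scores <- c(a1 = -7, a2 = -6.8, n1 = -5, n2 = -4.9)
  labels <- c("agonist", "agonist", "nonagonist", "nonagonist")
  r <- static_classifier(scores)
  expect_equal(auc_midrank(r$ranking, labels), 1)
  # flipping the orientation reverses the AUC
  r2 <- static_classifier(scores, orientation = "higher_is_agonist")
  expect_equal(auc_midrank(r2$ranking, labels), 0)
  expect_message(static_classifier(c(-7, NA)), "missing")
  # two-states: serotonin-like (-6.53 vs -6.02) ranks above
  # methiothepin-like (-4.95 vs -5.36)
  two <- two_states_classifier(score_active = c(-6.53, -4.95),
                               score_inactive = c(-6.02, -5.36),
                               ligand_id = c("serotonin", "methiothepin"))
  expect_equal(two$delta, c(-0.51, 0.41))
  expect_gt(two$ranking[1], two$ranking[2])
  expect_equal(two_states_classifier(-6, -6)$delta, 0)
  expect_message(two_states_classifier(c(-6, NA), c(-5, -5)), "missing")
})

test_that("the RF ensemble baseline separates state-patterned score tables", {
  st <- gen_score_table(n_ligands_per_class = 15,
                        n_conformations_per_state = 40, seed = 61)
  plan <- make_split(nrow(st$score_matrix), "random", k = 3, seed = 1)
  rf <- rf_ensemble_classifier(st$score_matrix, st$ligands$label, plan,
                               ntree = 200, seed = 2)
  expect_gte(auc_midrank(rf$prob, st$ligands$label[rf$ligand]), 0.8)
  # label permutation lands near chance
  set.seed(62)
  perm <- sample(st$ligands$label)
  rfp <- rf_ensemble_classifier(st$score_matrix, perm, plan, ntree = 200,
                                seed = 2)
  expect_lt(abs(auc_midrank(rfp$prob, perm[rfp$ligand]) - 0.5), 0.25)
  # reproducible under a fixed seed; all-missing columns dropped
  rf2 <- rf_ensemble_classifier(st$score_matrix, st$ligands$label, plan,
                                ntree = 200, seed = 2)
  expect_identical(rf$prob, rf2$prob)
  sm <- st$score_matrix; sm[, 3] <- NA
  expect_warning(rf_ensemble_classifier(sm, st$ligands$label, plan,
                                        ntree = 50, seed = 2),
                 "all-missing")
})

test_that("welch_test matches the closed-form statistic on random pairs", {
  set.seed(71)
  for (rep in 1:100) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    a <- stats::rnorm(n1, stats::runif(1, -8, -4), stats::runif(1, .2, 1))
    b <- stats::rnorm(n2, stats::runif(1, -8, -4), stats::runif(1, .2, 1))
    w <- welch_test(a, b)
    se <- sqrt(stats::var(a) / n1 + stats::var(b) / n2)
    t_oracle <- (mean(a) - mean(b)) / se
    df_oracle <- se^4 / ((stats::var(a) / n1)^2 / (n1 - 1) +
                           (stats::var(b) / n2)^2 / (n2 - 1))
    p_oracle <- 2 * stats::pt(-abs(t_oracle), df_oracle)
    expect_equal(w$t, t_oracle, tolerance = 1e-10)
    expect_equal(w$df, df_oracle, tolerance = 1e-10)
    expect_equal(w$p_value, p_oracle, tolerance = 1e-10)
  }
  # identical samples: t = 0, p = 1
  x <- c(1, 1, 1)
  w0 <- welch_test(x, x)
  expect_equal(w0$t, 0)
  expect_equal(w0$p_value, 1)
})

test_that("split plans partition ligands and never split a scaffold cluster", {
  plan <- make_split(9, "random", k = 3, seed = 1)
  expect_equal(sort(table(plan$fold)), sort(c(3L, 3L, 3L)),
               ignore_attr = TRUE)
  expect_setequal(plan$ligand, 1:9)
  # identical fingerprints share a fold
  fp <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1))
  plan2 <- suppressWarnings(  # 2-of-3 cluster is deliberately oversized
    make_split(3, "tanimoto", k = 2, fingerprints = fp, seed = 1))
  expect_equal(plan2$fold[1], plan2$fold[2])
  # three planted clusters, k = 3: clusters whole, one per fold
  gen <- gen_fingerprints(n = 30, n_clusters = 3, seed = 7)
  plan3 <- make_split(30, "tanimoto", k = 3,
                      fingerprints = gen$fingerprints, seed = 1)
  tab <- table(plan3$cluster, plan3$fold)
  expect_true(all(rowSums(tab > 0) == 1L))   # cluster atomicity
  expect_equal(length(unique(plan3$fold)), 3L)
  # an oversized cluster triggers the imbalance warning
  fp_one <- gen_fingerprints(n = 12, n_clusters = 1, seed = 3)$fingerprints
  expect_warning(make_split(12, "tanimoto", k = 3, fingerprints = fp_one),
                 "unbalanced")
})

test_that("tanimoto similarity matches the bit-set definition", {
  fp <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 0), c(0, 0, 0, 0))
  sim <- tanimoto_matrix(fp)
  expect_equal(sim[1, 2], 2 / 3)
  expect_equal(sim[1, 3], 0)
  expect_equal(diag(sim), rep(1, 3))
  expect_equal(sim, t(sim))
})

test_that("AUC equals the O(n^2) pair-count oracle and survives monotone maps", {
  set.seed(81)
  pair_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
    tot / (length(pos) * length(neg))
  }
  for (rep in 1:5) {
    n <- 60
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # with ties
    y <- stats::rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_midrank(s, y), pair_auc(s, y))
    # strictly monotone transform leaves AUC unchanged
    expect_equal(auc_midrank(exp(3 * s) - 1, y), auc_midrank(s, y))
  }
  expect_warning(expect_true(is.na(auc_midrank(1:3, c(1, 1, 1)))),
                 "single class")
})

test_that("confusion-count metrics match hand-evaluated formulas", {
  m <- metrics_from_counts(tp = 3, tn = 3, fp = 1, fn = 1)
  expect_equal(m$acc, 0.75)
  expect_equal(m$mcc, 0.5)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  # perfect separation
  perfect <- compute_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$mcc, 1)
  # class-swap symmetry of MCC; zero denominator -> 0
  set.seed(82)
  for (rep in 1:20) {
    cnt <- sample(0:6, 4, replace = TRUE)
    m1 <- metrics_from_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    m2 <- metrics_from_counts(cnt[2], cnt[1], cnt[4], cnt[3])
    expect_equal(m1$mcc, m2$mcc)
  }
  expect_equal(metrics_from_counts(0, 5, 0, 3)$mcc, 0)
})

test_that("repeated cross-validated evaluation reports mean and SD", {
  fe <- gen_feature_ensemble(n_ligands = 60, n_conformations = 4,
                             dim_p = 8, delta = 2, mode = "uniform",
                             seed = 91)
  X <- stack_features(fe)
  plan <- make_split(60, "random", k = 3, seed = 92)
  rep <- evaluate_tl(X, fe$labels, plan, n_rep = 3, base_seed = 500)
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep$per_rep), 3L)
  expect_equal(nrow(rep$per_fold), 9L)
  expect_true(all(c("auc", "acc", "mcc", "precision", "recall") %in%
                    rep$summary$metric))
  expect_true(all(rep$per_rep$auc >= 0 & rep$per_rep$auc <= 1))
  expect_true(all(rep$per_rep$mcc >= -1 & rep$per_rep$mcc <= 1))
  # deterministic given the same base seed
  rep2 <- evaluate_tl(X, fe$labels, plan, n_rep = 3, base_seed = 500)
  expect_identical(rep$per_rep, rep2$per_rep)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(glance(rep)), 1L)
})
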