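planted_fixture <- function(n = 120, p = 60, n_signal = 5, noise_sd = 1,
                            seed = 1) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n, p,
                            dimnames = list(NULL, sprintf("taxa%03d", 1:p))))
  signal <- sprintf("taxa%03d", seq_len(n_signal))
  y <- as.vector(as.matrix(x[, signal]) %*%
                   seq(3, 2, length.out = n_signal)) +
    rnorm(n, 0, noise_sd)
  list(x = x, y = y, signal = signal)
}

test_that("stratified split balances outcome quantiles and is reproducible", {
  set.seed(2)
  y <- rnorm(40)
  sp <- stratified_split(y, 0.8, seed = 3)
  expect_true(abs(length(sp$train) - 32) <= 1)
  expect_equal(sort(c(sp$train, sp$test)), 1:40)
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  # each quartile contributes its share of the training set (+- 1 sample)
  qs <- cut(y, quantile(y, 0:4 / 4), include.lowest = TRUE, labels = FALSE)
  per_bin <- table(qs[sp$train])
  expect_true(all(abs(per_bin - 8) <= 1))

  expect_identical(stratified_split(y, 0.8, seed = 3), sp)
  expect_error(stratified_split(rnorm(5)), "at least 10")
  # an isolated extreme value leaves a singleton top bin, which is merged
  y_out <- c(1:9, 9, 9, 100)
  expect_message(sp2 <- stratified_split(y_out, n_bins = 4, seed = 1),
                 "merged")
  expect_equal(sort(c(sp2$train, sp2$test)), seq_along(y_out))
  # heavy ties collapse the quantile breaks entirely without error
  sp3 <- stratified_split(c(rep(0, 11), 5), n_bins = 4, seed = 1)
  expect_equal(length(sp3$train) + length(sp3$test), 12)
})

test_that("a perfectly learnable outcome is learned and tuning is seed-stable", {
  fx <- planted_fixture(n = 80, p = 10, n_signal = 1, noise_sd = 0, seed = 4)
  sp <- stratified_split(fx$y, 0.8, seed = 5)
  tt <- tune_and_train(fx$x[sp$train, ], fx$y[sp$train], mtry_grid = c(3, 10),
                       k = 4, repeats = 1, num_trees = 200, seed = 6)
  ev <- evaluate_model(tt$model, fx$x[sp$test, ], fx$y[sp$test])
  expect_gt(ev$spearman_rho, 0.95)

  tt2 <- tune_and_train(fx$x[sp$train, ], fx$y[sp$train], mtry_grid = c(3, 10),
                        k = 4, repeats = 1, num_trees = 200, seed = 6)
  expect_identical(tt$cv, tt2$cv)
  expect_identical(tt$best_mtry, tt2$best_mtry)

  expect_error(tune_and_train(fx$x, rep(1, nrow(fx$x))), "constant")
})

test_that("cross-validated RMSE on pure noise approaches the outcome sd", {
  set.seed(7)
  x <- as.data.frame(matrix(rnorm(90 * 20), 90, 20))
  y <- rnorm(90)
  tt <- tune_and_train(x, y, mtry_grid = c(2, 20), k = 5, repeats = 2,
                       num_trees = 200, seed = 8)
  expect_true(all(abs(tt$cv$rmse - sd(y)) / sd(y) < 0.2))
})

test_that("evaluation reports rank agreement and rejects tiny test sets", {
  set.seed(30)
  x <- data.frame(f = seq(0, 1, length.out = 60))
  y <- 3 * x$f + rnorm(60, 0, 0.05)
  fit <- ranger::ranger(x = x, y = y, num.trees = 200, min.node.size = 2,
                        num.threads = 1, seed = 1)
  ev <- evaluate_model(fit, x, y)
  expect_gt(ev$spearman_rho, 0.9)
  expect_gt(ev$r2, 0.8)
  expect_equal(length(ev$predictions), 60)

  # the reported measure is Spearman: exact on monotone transforms
  expect_equal(cor(y, exp(y), method = "spearman"), 1)
  expect_equal(cor(y, -y, method = "spearman"), -1)
  expect_error(evaluate_model(fit, x[1:2, , drop = FALSE], y[1:2]),
               "at least 3")
})

test_that("permutation importance surfaces planted signal and ignores noise", {
  fx <- planted_fixture(n = 150, p = 60, seed = 9)
  tt <- tune_and_train(fx$x, fx$y, mtry_grid = 20, k = 3, repeats = 1,
                       num_trees = 300, seed = 10)
  imp <- permutation_importance(tt$model, fx$x, fx$y, n_permutations = 3,
                                seed = 11)
  expect_equal(sort(imp$rank), seq_len(ncol(fx$x)))  # ranks are a permutation
  planted_ranks <- imp$rank[match(fx$signal, imp$variable)]
  expect_true(all(planted_ranks <= 10))
  # noise features sit far below the planted block
  noise_imp <- imp$importance[!imp$variable %in% fx$signal]
  expect_lt(max(noise_imp), min(imp$importance[imp$variable %in% fx$signal]))

  # deterministic under the same seed
  imp_rep <- permutation_importance(tt$model, fx$x, fx$y, n_permutations = 3,
                                    seed = 11)
  expect_identical(imp_rep, imp)
  # the planted block stays on top when the feature columns are reordered
  perm <- sample(ncol(fx$x))
  imp2 <- permutation_importance(tt$model, fx$x[, perm], fx$y,
                                 n_permutations = 3, seed = 11)
  expect_true(all(imp2$rank[match(fx$signal, imp2$variable)] <= 10))
})

test_that("partial dependence recovers a linear marginal effect and flatness", {
  set.seed(12)
  x <- data.frame(a = runif(200, 0, 1), b = runif(200, 0, 1))
  y <- 2 * x$a + rnorm(200, 0, 0.01)
  fit <- ranger::ranger(x = x, y = y, num.trees = 400, min.node.size = 3,
                        num.threads = 1, seed = 2)
  pd <- partial_dependence(fit, x, "a", grid_size = 21)
  inner <- pd[pd$value > 0.15 & pd$value < 0.85, ]
  slope <- coef(lm(prediction ~ value, inner))[2]
  expect_gt(slope, 1.5)
  expect_lt(slope, 2.5)
  # additivity: PD at the feature mean sits near the mean prediction
  pd_mid <- partial_dependence(fit, x, "a", grid_size = 3)
  mid <- mean(predict(fit, data = x, num.threads = 1)$predictions)
  expect_lt(abs(pd$prediction[which.min(abs(pd$value - mean(x$a)))] - mid),
            0.2 * sd(y))

  # the unused feature's profile is flat relative to the real effect's span
  flat <- partial_dependence(fit, x, "b", grid_size = 11)
  expect_lt(diff(range(flat$prediction)), 0.15 * diff(range(pd$prediction)))

  x$c <- 1
  expect_warning(one <- partial_dependence(fit, x, "c"), "constant")
  expect_equal(nrow(one), 1)
})
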