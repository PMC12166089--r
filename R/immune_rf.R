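# Random-forest harness for predicting faecal immune measures (f-IgA,
# f-mucin) from cASV relative abundances plus host, social and
# environmental covariates. The tree ensemble itself is ranger
# (splitrule = variance); the harness around it — stratified train/test
# split, repeated k-fold cross-validation over mtry, permutation
# importance, partial dependence and rank-based evaluation — lives here.

#' Assemble the feature matrix for immune prediction
#'
#' Joins cASV relative abundances with host covariates (age, individual
#' and mother identity, clan, rank, season, batch) and selects the
#' outcome. Categorical covariates are encoded as factors with fixed
#' levels so train and test splits are encoded consistently. Identity
#' features can memorise repeatedly sampled individuals; they are included
#' because the study design calls for them, and that caveat is logged as a
#' message.
#'
#' @param casv_table samples x cASVs relative-abundance matrix.
#' @param metadata sample metadata with host covariates.
#' @param outcome `"iga"` or `"mucin"`.
#' @return list with `x` (data.frame of features) and `y` (outcome).
#' @export
build_feature_matrix <- function(casv_table, metadata,
                                 outcome = c("iga", "mucin")) {
  outcome <- match.arg(outcome)
  check_that(all(c("clan", "rank", "mother_id") %in% names(metadata)),
             "metadata lacks host covariates; join them first (with_host_covariates)")
  md <- metadata[match(rownames(casv_table), metadata$sample_id), ]
  check_that(!anyNA(md$sample_id), "metadata must cover every sample")
  y <- if (outcome == "iga") md$f_iga else md$f_mucin
  check_that(!anyNA(y), "missing outcome values")
  x <- as.data.frame(casv_table)
  colnames(x) <- make.names(colnames(x))
  x$age_days <- md$age_days
  x$individual_id <- factor(md$individual_id)
  x$mother_id <- factor(ifelse(is.na(md$mother_id), "unknown", md$mother_id))
  x$clan <- factor(md$clan)
  x$rank <- md$rank
  x$season <- factor(md$season, levels = c("dry", "wet"))
  x$batch <- factor(md$batch)
  message("identity features (individual, mother) included; they can memorise repeated individuals")
  list(x = x, y = y)
}

#' Outcome-stratified train/test split
#'
#' Bins the continuous outcome into quantile bins and draws the training
#' fraction within each bin, so both sets see the outcome's full range.
#' Bins with fewer than 2 members are merged with their neighbour.
#'
#' @param y outcome vector (n >= 10).
#' @param train_fraction fraction of samples in the training set.
#' @param n_bins number of quantile bins (default 4 = quartiles).
#' @param seed integer RNG seed.
#' @return list with integer vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(y, train_fraction = 0.8, n_bins = 4, seed = 1) {
  n <- length(y)
  check_that(n >= 10, "need at least 10 samples to split")
  check_that(train_fraction > 0 && train_fraction < 1,
             "train_fraction must be in (0, 1)")
  br <- unique(quantile(y, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- if (length(br) > 2)
    cut(y, breaks = br, include.lowest = TRUE, labels = FALSE)
  else rep(1L, n)
  # merge undersized bins into the neighbour below (or above for the first)
  repeat {
    sizes <- table(bins)
    small <- names(sizes)[sizes < 2]
    if (length(small) == 0 || length(sizes) == 1) break
    b <- as.integer(small[1])
    tgt <- if (any(bins < b)) max(bins[bins < b]) else min(bins[bins > b])
    message(sprintf("stratification bin %d has <2 members; merged with bin %d",
                    b, tgt))
    bins[bins == b] <- tgt
  }
  train <- with_seed(seed, {
    unlist(lapply(unique(bins), function(b) {
      idx <- which(bins == b)
      k <- max(1, round(train_fraction * length(idx)))
      sample(idx, min(k, length(idx) - 1))
    }))
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Tune mtry by repeated cross-validation and train the forest
#'
#' For every value in the mtry grid, computes the mean RMSE over
#' `k`-fold cross-validation repeated `repeats` times (fold assignments
#' fixed by the seed and shared across grid points), then refits the best
#' (lowest-RMSE) configuration on the full training set with
#' splitrule = variance.
#'
#' @param x training features (data.frame).
#' @param y training outcome.
#' @param mtry_grid candidate numbers of candidate-split variables.
#' @param k folds (>= 2); `repeats` repetitions.
#' @param min_node_size ranger minimal node size (default 10).
#' @param num_trees trees per forest.
#' @param seed integer RNG seed.
#' @return list with `model` (ranger fit on all of `x`), `best_mtry`,
#'   `cv` (data.frame: mtry, rmse).
#' @export
tune_and_train <- function(x, y, mtry_grid = NULL, k = 10, repeats = 10,
                           min_node_size = 10, num_trees = 500, seed = 1) {
  check_that(k >= 2, "k must be >= 2")
  check_that(var(y) > 0, "outcome is constant; nothing to learn")
  p <- ncol(x)
  if (is.null(mtry_grid))
    mtry_grid <- unique(pmax(1, round(c(sqrt(p), p / 3, p / 2))))
  mtry_grid <- unique(pmin(pmax(1, round(mtry_grid)), p))
  check_that(length(mtry_grid) >= 1, "empty mtry grid")
  n <- length(y)
  cv <- with_seed(seed, {
    folds <- replicate(repeats, sample(rep_len(seq_len(k), n)),
                       simplify = FALSE)
    res <- matrix(NA_real_, length(mtry_grid), k * repeats)
    for (mi in seq_along(mtry_grid)) {
      col <- 0L
      for (r in seq_len(repeats)) {
        for (f in seq_len(k)) {
          col <- col + 1L
          hold <- folds[[r]] == f
          if (!any(hold) || all(hold)) next
          fit <- ranger::ranger(
            x = x[!hold, , drop = FALSE], y = y[!hold],
            mtry = mtry_grid[mi], min.node.size = min_node_size,
            splitrule = "variance", num.trees = num_trees,
            num.threads = 1, seed = sample.int(1e6, 1))
          pred <- predict(fit, data = x[hold, , drop = FALSE],
                          num.threads = 1)$predictions
          res[mi, col] <- sqrt(mean((pred - y[hold])^2))
        }
      }
    }
    data.frame(mtry = mtry_grid, rmse = rowMeans(res, na.rm = TRUE))
  })
  best <- cv$mtry[which.min(cv$rmse)]
  model <- with_seed(seed + 1, ranger::ranger(
    x = x, y = y, mtry = best, min.node.size = min_node_size,
    splitrule = "variance", num.trees = num_trees, num.threads = 1,
    seed = sample.int(1e6, 1)))
  list(model = model, best_mtry = best, cv = cv)
}

#' Evaluate predictions on the held-out test set
#'
#' @param model a fitted ranger model.
#' @param x_test,y_test held-out features and observed outcome (n >= 3).
#' @return list with `r2` (1 - SSres/SStot), `spearman_rho` and `p`
#'   (two-sided).
#' @export
evaluate_model <- function(model, x_test, y_test) {
  check_that(length(y_test) >= 3, "need at least 3 test samples")
  pred <- predict(model, data = x_test, num.threads = 1)$predictions
  r2 <- 1 - sum((y_test - pred)^2) / sum((y_test - mean(y_test))^2)
  ct <- suppressWarnings(stats::cor.test(pred, y_test, method = "spearman"))
  list(r2 = r2, spearman_rho = unname(ct$estimate), p = ct$p.value,
       predictions = pred)
}

#' Permutation importance of every feature
#'
#' Importance of a variable is the mean increase in prediction error (MSE)
#' when that variable's column is permuted, averaged over
#' `n_permutations` shuffles; ranks are 1 = most important.
#'
#' @param model a fitted ranger model.
#' @param x,y data to measure the error increase on.
#' @param n_permutations shuffles per variable.
#' @param seed integer RNG seed.
#' @return data.frame (variable, importance, rank) sorted by rank.
#' @export
permutation_importance <- function(model, x, y, n_permutations = 5, seed = 1) {
  base_pred <- predict(model, data = x, num.threads = 1)$predictions
  base_mse <- mean((base_pred - y)^2)
  imp <- with_seed(seed, {
    vapply(colnames(x), function(v) {
      mean(vapply(seq_len(n_permutations), function(i) {
        xp <- x
        xp[[v]] <- sample(xp[[v]])
        mean((predict(model, data = xp, num.threads = 1)$predictions - y)^2)
      }, numeric(1))) - base_mse
    }, numeric(1))
  })
  out <- data.frame(variable = colnames(x), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$importance, ties.method = "first")
  out[order(out$rank), ]
}

#' Partial-dependence curve of one numeric feature
#'
#' For each grid value g, the curve point is the mean model prediction
#' over the dataset with the feature set to g everywhere (marginal
#' effect).
#'
#' @param model a fitted ranger model.
#' @param x data over which the marginal mean is taken.
#' @param variable numeric feature name.
#' @param grid_size number of grid points over the observed range.
#' @return data.frame (value, prediction); a constant feature yields a
#'   single-point curve with a warning.
#' @export
partial_dependence <- function(model, x, variable, grid_size = 20) {
  check_that(variable %in% colnames(x), "unknown variable '%s'", variable)
  v <- x[[variable]]
  check_that(is.numeric(v), "partial dependence requires a numeric variable")
  rng <- range(v)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    warning(sprintf("variable '%s' is constant; single-point curve", variable))
    grid <- rng[1]
  } else {
    grid <- seq(rng[1], rng[2], length.out = grid_size)
  }
  pd <- vapply(grid, function(g) {
    xg <- x
    xg[[variable]] <- g
    mean(predict(model, data = xg, num.threads = 1)$predictions)
  }, numeric(1))
  data.frame(value = grid, prediction = pd)
}
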