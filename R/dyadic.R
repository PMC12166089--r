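# Dyadic (pairwise-sample) dataset construction and Bayesian
# multi-membership regression of microbiome similarity.
#
# Each unordered pair of samples contributes one row: the response is the
# community similarity of the pair; the predictors are covariate distances
# (age, f-IgA, f-mucin, rank, collection date) min-max scaled to [0, 1],
# same/different indicators (mother, clan, season, batch, optionally sex)
# and the two age x immune interactions. Because the same individual
# appears in many pairs, the model carries a multi-membership random
# effect: the pair's intercept offset is the average of its two
# individuals' effects. The posterior is sampled by a blocked Gibbs
# sampler (conjugate normal updates for coefficients and individual
# effects; half-t priors on the two scale parameters via their
# inverse-gamma mixture representation).

#' Attach host covariates to sample metadata
#'
#' @param metadata sample metadata from [simulate_hosts()].
#' @param hosts host table (individual_id, clan, mother_id, sex, rank).
#' @return metadata with clan, mother_id, sex and rank columns joined.
#' @export
with_host_covariates <- function(metadata, hosts) {
  i <- match(metadata$individual_id, hosts$individual_id)
  check_that(!anyNA(i), "every sample's individual must appear in hosts")
  metadata$clan <- hosts$clan[i]
  metadata$mother_id <- hosts$mother_id[i]
  metadata$sex <- hosts$sex[i]
  metadata$rank <- hosts$rank[i]
  metadata
}

#' Build the dyadic pairwise dataset
#'
#' One row per unordered sample pair (within-sample comparisons excluded;
#' two samples of the same individual are a valid pair). Continuous
#' distance predictors are min-max scaled to \[0, 1\] over the pair set
#' before the interactions are formed; indicators are coded 1 = same,
#' 0 = different.
#'
#' @param metadata sample metadata including host covariates
#'   (see [with_host_covariates()]); required columns: sample_id,
#'   individual_id, age_days, date, season, batch, f_iga, f_mucin, clan,
#'   rank, mother_id (sex when `include_sex`).
#' @param similarity sample x sample similarity matrix (response).
#' @param include_sex add a same-sex indicator (used for the
#'   juveniles-only variant).
#' @param extra_similarities named list of further similarity matrices
#'   (e.g. the other community components) added as scaled predictors.
#' @return data.frame of class `dyadic_dataset` with columns sample_a/b,
#'   individual_a/b, `response`, and the predictors listed in
#'   `attr(, "predictors")`.
#' @export
build_dyadic <- function(metadata, similarity, include_sex = FALSE,
                         extra_similarities = NULL) {
  n <- nrow(metadata)
  check_that(n >= 3, "need at least 3 samples for a dyadic dataset")
  need <- c("sample_id", "individual_id", "age_days", "date", "season",
            "batch", "f_iga", "f_mucin", "clan", "rank", "mother_id")
  if (include_sex) need <- c(need, "sex")
  miss <- setdiff(need, colnames(metadata))
  check_that(length(miss) == 0, "metadata lacks columns: %s",
             paste(miss, collapse = ", "))
  cov_cols <- setdiff(need, c("sample_id", "mother_id"))
  bad <- !complete.cases(metadata[, cov_cols])
  check_that(!any(bad), "missing covariates for samples: %s",
             paste(metadata$sample_id[bad], collapse = ", "))
  check_that(all(metadata$sample_id %in% rownames(similarity)),
             "similarity matrix must cover every sample")
  sim <- similarity[metadata$sample_id, metadata$sample_id]

  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- ij[, 1]; b <- ij[, 2]
  dd <- data.frame(
    sample_a = metadata$sample_id[a], sample_b = metadata$sample_id[b],
    individual_a = metadata$individual_id[a],
    individual_b = metadata$individual_id[b],
    response = sim[cbind(a, b)], stringsAsFactors = FALSE)
  dd$age_dist <- minmax01(abs(metadata$age_days[a] - metadata$age_days[b]))
  dd$iga_dist <- minmax01(abs(metadata$f_iga[a] - metadata$f_iga[b]))
  dd$mucin_dist <- minmax01(abs(metadata$f_mucin[a] - metadata$f_mucin[b]))
  dd$rank_dist <- minmax01(abs(metadata$rank[a] - metadata$rank[b]))
  dd$temporal_dist <- minmax01(abs(as.numeric(as.Date(metadata$date[a]) -
                                                as.Date(metadata$date[b]))))
  same <- function(x) as.integer(x[a] == x[b])
  dd$same_mother <- as.integer(!is.na(metadata$mother_id[a]) &
                                 !is.na(metadata$mother_id[b]) &
                                 metadata$mother_id[a] == metadata$mother_id[b])
  dd$same_clan <- same(metadata$clan)
  dd$same_season <- same(metadata$season)
  dd$same_batch <- same(metadata$batch)
  preds <- c("age_dist", "iga_dist", "mucin_dist", "rank_dist",
             "temporal_dist", "same_mother", "same_clan", "same_season",
             "same_batch")
  if (include_sex) {
    dd$same_sex <- same(metadata$sex)
    preds <- c(preds, "same_sex")
  }
  dd$age_x_iga <- dd$age_dist * dd$iga_dist
  dd$age_x_mucin <- dd$age_dist * dd$mucin_dist
  preds <- c(preds, "age_x_iga", "age_x_mucin")
  for (nm in names(extra_similarities)) {
    s <- extra_similarities[[nm]]
    check_that(all(metadata$sample_id %in% rownames(s)),
               "extra similarity '%s' must cover every sample", nm)
    s <- s[metadata$sample_id, metadata$sample_id]
    col <- paste0("sim_", nm)
    dd[[col]] <- minmax01(s[cbind(a, b)])
    preds <- c(preds, col)
  }
  attr(dd, "predictors") <- preds
  class(dd) <- c("dyadic_dataset", "data.frame")
  dd
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends register as non-convergence.
#'
#' @param draws iterations x chains matrix of posterior draws for one
#'   parameter (>= 2 chains, >= 4 draws each).
#' @return R-hat; `NA` when within-chain variance is zero (flagged
#'   undefined).
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  check_that(ncol(draws) >= 2, "need at least 2 chains")
  check_that(nrow(draws) >= 4, "need at least 4 draws per chain")
  n <- floor(nrow(draws) / 2)
  halves <- cbind(draws[seq_len(n), , drop = FALSE],
                  draws[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  W <- mean(apply(halves, 2, var))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  B <- n * var(colMeans(halves))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Univariate stepping-out slice sampler (Neal 2003).
slice_sample1 <- function(x0, logf, w = 1, m = 50) {
  y0 <- logf(x0) - stats::rexp(1)
  L <- x0 - runif(1) * w
  R <- L + w
  k <- m
  while (k > 0 && logf(L) > y0) { L <- L - w; k <- k - 1 }
  k <- m
  while (k > 0 && logf(R) > y0) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= y0) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# One Gibbs chain for y = X beta + Z u + eps.
# Flat prior on beta; sigma_u, sigma_e ~ half-t(nu, A) via the
# inverse-gamma mixture  sigma^2 | a ~ IG(nu/2, nu/a), a ~ IG(1/2, 1/A^2).
# The individual-effect variance is updated with u integrated out (slice
# sampling on log sigma_u^2 against the marginal likelihood, using the
# eigendecomposition of Z'Z), then u is drawn conjugately; this blocked
# update avoids the small-variance funnel that cripples naive Gibbs.
gibbs_chain <- function(y, X, Z, iter, warmup, nu = 3, A = NULL,
                        init_scale = 1, random_effect = TRUE) {
  n <- length(y); p <- ncol(X)
  if (is.null(A)) A <- 2.5 * max(sd(y), 1e-3)
  XtX <- crossprod(X)
  cXtX <- chol(XtX + diag(1e-10, p))
  Xty <- crossprod(X, y)
  if (random_effect) {
    q <- ncol(Z)
    ZtZ <- crossprod(Z)
    ZtX <- crossprod(Z, X)
    Zty <- crossprod(Z, y)
    eig <- eigen(ZtZ, symmetric = TRUE)
    lam <- pmax(eig$values, 0)
    V <- eig$vectors
    VtZtX <- crossprod(V, ZtX)
    VtZty <- as.vector(crossprod(V, Zty))
    # null eigendirections of Z'Z have Zv = 0, so their projections vanish
    # exactly; zero the numerical dust so huge sigma_u cannot amplify it
    null_dir <- lam < 1e-8 * max(lam)
    lam[null_dir] <- 0
    VtZtX[null_dir, ] <- 0
    VtZty[null_dir] <- 0
  }
  beta <- backsolve(cXtX, backsolve(cXtX, Xty, transpose = TRUE)) +
    rnorm(p, 0, 0.1 * init_scale)
  u <- if (random_effect) rep(0, ncol(Z)) else NULL
  sig2_e <- (sd(y) * init_scale)^2 + 1e-6
  sig2_u <- (0.1 * sd(y) * init_scale)^2 + 1e-6
  a_e <- a_u <- 1
  # loop-invariant slice domain for log sigma_u^2, and a purely numerical
  # floor on sigma_e^2 relative to the response magnitude: under a perfect
  # fit (e.g. a constant response) sigma_e^2 would otherwise collapse to
  # zero while sigma_u^2 cannot, and the exploding variance ratio destroys
  # the conditioning of the marginal beta update
  vy <- max(var(y), 1e-12)
  x_lo <- log(vy) - 30
  x_hi <- log(vy) + 10
  e_floor <- 1e-10 * (vy + mean(y)^2 + 1e-12)
  keep <- iter - warmup
  out <- matrix(NA_real_, keep,
                p + if (random_effect) 2 else 1)
  for (it in seq_len(iter)) {
    if (random_effect) {
      # update sigma_u^2 with beta AND u integrated out of the likelihood
      # (marginal covariance sigma_e^2 I + sigma_u^2 Z Z', handled through
      # the eigenvalues of Z'Z), slice sampling on log sigma_u^2; then draw
      # beta from its GLS posterior given the scales and u from its
      # conjugate conditional given beta. (beta, u) is thereby an exact
      # joint draw given the scales, so the additive confounding of the
      # intercept with the mean individual effect, and the small-variance
      # funnel of sigma_u, never enter the chain's dynamics.
      r0 <- y - as.vector(X %*% beta)
      t0 <- as.vector(crossprod(Z, r0))
      vt <- as.vector(crossprod(V, t0))
      vt[null_dir] <- 0
      rtr <- sum(r0^2)
      logf <- function(x) {
        if (x < x_lo || x > x_hi) return(-Inf)
        cc <- exp(x) / sig2_e
        -0.5 * sum(log1p(cc * lam)) -
          0.5 * (rtr - sum(cc * vt^2 / (1 + cc * lam))) / sig2_e -
          (nu / 2) * x - nu / (a_u * exp(x))
      }
      sig2_u <- exp(slice_sample1(min(max(log(sig2_u), x_lo), x_hi), logf))
      a_u <- 1 / rgamma(1, (nu + 1) / 2, nu / sig2_u + 1 / A^2)
      # beta | sigma_u^2, sigma_e^2 (u marginalised; GLS precision by
      # Woodbury in the Z'Z eigenbasis)
      cc <- sig2_u / sig2_e
      D <- cc / (1 + cc * lam)
      # work on the sigma_e-free scale so the ridge jitter stays relative
      # to the matrix (dividing by a tiny sigma_e^2 would swamp an absolute
      # jitter and cancellation could make chol fail)
      M <- XtX - crossprod(VtZtX, D * VtZtX)
      M <- (M + t(M)) / 2
      cM <- chol(M + diag(1e-10 * max(diag(M)), p))
      rhsb <- Xty - crossprod(VtZtX, D * VtZty)
      beta <- as.vector(backsolve(cM, backsolve(cM, rhsb, transpose = TRUE)) +
                          sqrt(sig2_e) * backsolve(cM, rnorm(p)))
      fit_x <- as.vector(X %*% beta)
      # u | beta, scales
      t0 <- as.vector(Zty - ZtX %*% beta)
      P <- ZtZ / sig2_e + diag(1 / sig2_u, ncol(Z))
      cP <- chol(P)
      mu_u <- backsolve(cP, backsolve(cP, t0 / sig2_e, transpose = TRUE))
      u <- as.vector(mu_u + backsolve(cP, rnorm(ncol(Z))))
      resid <- y - fit_x - as.vector(Z %*% u)
    } else {
      mu_b <- backsolve(cXtX, backsolve(cXtX, Xty, transpose = TRUE))
      beta <- as.vector(mu_b + sqrt(sig2_e) * backsolve(cXtX, rnorm(p)))
      fit_x <- as.vector(X %*% beta)
      resid <- y - fit_x
    }
    sig2_e <- max(1 / rgamma(1, (nu + n) / 2, nu / a_e + sum(resid^2) / 2),
                  e_floor)
    a_e <- 1 / rgamma(1, (nu + 1) / 2, nu / sig2_e + 1 / A^2)
    if (it > warmup)
      out[it - warmup, ] <- c(beta, sqrt(sig2_e),
                              if (random_effect) sqrt(sig2_u))
  }
  out
}

#' Fit the Bayesian dyadic multi-membership model
#'
#' Gaussian-likelihood linear model of pair similarity on the dyadic
#' predictors with a multi-membership random effect: each pair's offset is
#' the mean of its two individuals' effects (`mm_weights = "sum"` adds
#' them instead). Coefficients carry improper flat priors; the residual
#' and individual scales carry half-Student-t(3, 0, 2.5 sd(y)) priors.
#' Sampling is by blocked Gibbs; warmup draws are discarded. A parameter
#' is flagged significant when its central 95% credible interval excludes
#' zero; fits with any R-hat above 1.01 are flagged as not converged (the
#' result is returned, not silently accepted).
#'
#' @param dataset a `dyadic_dataset`.
#' @param chains number of chains (>= 2).
#' @param iter iterations per chain, including warmup.
#' @param warmup warmup iterations discarded per chain.
#' @param seed integer RNG seed.
#' @param predictors predictor columns (default: the dataset's).
#' @param random_effect include the multi-membership term (FALSE gives a
#'   flat-prior linear regression whose posterior mean is the OLS fit).
#' @param mm_weights `"mean"` (default) or `"sum"` of the two members.
#' @return list of class `dyadic_fit`: `summary` (data.frame: parameter,
#'   mean, sd, q2.5, q97.5, rhat, significant), `draws` (iterations x
#'   chains x parameters array), `converged`, `dropped` (zero-variance
#'   predictors removed, with a warning at fit time).
#' @export
fit_dyadic <- function(dataset, chains = 4, iter = 3000, warmup = 1000,
                       seed = 1, predictors = attr(dataset, "predictors"),
                       random_effect = TRUE,
                       mm_weights = c("mean", "sum")) {
  mm_weights <- match.arg(mm_weights)
  check_that(chains >= 2, "need at least 2 chains")
  check_that(iter > warmup, "iter must exceed warmup")
  y <- dataset$response
  keep <- predictors[vapply(predictors, function(v) var(dataset[[v]]) > 0,
                            logical(1))]
  dropped <- setdiff(predictors, keep)
  if (length(dropped))
    warning(sprintf("zero-variance predictor(s) dropped: %s",
                    paste(dropped, collapse = ", ")))
  X <- cbind(intercept = 1, as.matrix(dataset[, keep, drop = FALSE]))
  inds <- sort(unique(c(dataset$individual_a, dataset$individual_b)))
  w <- if (mm_weights == "mean") 0.5 else 1
  Z <- matrix(0, nrow(dataset), length(inds),
              dimnames = list(NULL, inds))
  ia <- match(dataset$individual_a, inds)
  ib <- match(dataset$individual_b, inds)
  for (r in seq_len(nrow(dataset))) {
    Z[r, ia[r]] <- Z[r, ia[r]] + w
    Z[r, ib[r]] <- Z[r, ib[r]] + w
  }
  par_names <- c("intercept", keep, "sigma_residual",
                 if (random_effect) "sigma_individual")
  draws <- with_seed(seed, {
    sims <- lapply(seq_len(chains), function(ch)
      gibbs_chain(y, X, Z, iter, warmup,
                  init_scale = c(0.5, 1, 2, 4)[(ch - 1) %% 4 + 1],
                  random_effect = random_effect))
    arr <- array(NA_real_, c(iter - warmup, chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
    for (ch in seq_len(chains)) arr[, ch, ] <- sims[[ch]]
    arr
  })
  summ <- do.call(rbind, lapply(par_names, function(pn) {
    d <- draws[, , pn]
    pooled <- as.vector(d)
    q <- quantile(pooled, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = pn, mean = mean(pooled), sd = sd(pooled),
               q2.5 = q[1], q97.5 = q[2], rhat = rhat(d),
               significant = q[1] > 0 | q[2] < 0,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- summ$parameter
  converged <- all(is.na(summ$rhat) | summ$rhat < 1.01)
  if (!converged)
    warning("fit flagged: R-hat >= 1.01 for some parameters")
  structure(list(summary = summ, draws = draws, converged = converged,
                 dropped = dropped, predictors = keep),
            class = "dyadic_fit")
}

#' @export
print.dyadic_fit <- function(x, ...) {
  cat(sprintf("Dyadic multi-membership fit (%s)\n",
              if (x$converged) "converged" else "NOT converged"))
  print(format(x$summary, digits = 3), ...)
  invisible(x)
}

#' Per-component dyadic models with cross-component similarity predictors
#'
#' For each community component, fits the dyadic model with that
#' component's similarity as response and the other components'
#' similarities added as (scaled) predictors.
#'
#' @param similarities named list of similarity matrices (e.g. bacteria,
#'   parasites, fungi) over the same samples.
#' @param metadata sample metadata with host covariates.
#' @param ... passed to [fit_dyadic()] (chains, iter, warmup, seed, ...).
#' @return named list of `dyadic_fit` objects.
#' @export
fit_component_models <- function(similarities, metadata, ...) {
  comps <- names(similarities)
  check_that(length(comps) >= 2, "need at least two components")
  samp <- lapply(similarities, rownames)
  for (k in seq_along(samp))
    check_that(setequal(samp[[k]], metadata$sample_id),
               "component '%s' similarity does not match the sample set",
               comps[k])
  out <- list()
  for (cmp in comps) {
    dd <- build_dyadic(metadata, similarities[[cmp]],
                       extra_similarities = similarities[setdiff(comps, cmp)])
    out[[cmp]] <- fit_dyadic(dd, ...)
  }
  out
}

#' Simulate a dyadic dataset with known coefficients
#'
#' Parameter-recovery generator: hosts, samples and immune measures are
#' simulated, the full dyadic predictor set is built, and the response is
#' drawn from the model itself, `alpha + X beta + (u_A + u_B)/2 + eps`,
#' with individual effects of sd `sigma_u` and residual sd `sigma_e`.
#' Unnamed effects default to zero.
#'
#' @param n_samples approximate number of samples (individuals are drawn
#'   with a repeat fraction so some pairs share an individual).
#' @param beta named true coefficients on the \[0, 1\]-scaled predictors.
#' @param alpha true intercept.
#' @param sigma_u,sigma_e individual-effect and residual sds.
#' @param seed integer RNG seed.
#' @return list: `dataset` (a `dyadic_dataset`), `truth` (named vector of
#'   all true coefficients incl. intercept), `sigma_u`, `sigma_e`.
#' @export
simulate_dyadic <- function(n_samples = 60,
                            beta = c(age_dist = -0.15, mucin_dist = -0.11,
                                     iga_dist = -0.05),
                            alpha = 0.6, sigma_u = 0.02, sigma_e = 0.05,
                            seed = 1) {
  n_ind <- max(3, round(n_samples / 1.3))
  sim <- simulate_hosts(n_ind, n_clans = 3, repeat_fraction = 0.3, seed = seed)
  md <- sim$metadata[seq_len(min(n_samples, nrow(sim$metadata))), ]
  md <- simulate_immune(md, age_slope = 0.4, noise_sd = 0.3, seed = seed + 1)
  md <- with_host_covariates(md, sim$hosts)
  zero_sim <- matrix(0, nrow(md), nrow(md),
                     dimnames = list(md$sample_id, md$sample_id))
  dd <- build_dyadic(md, zero_sim)
  preds <- attr(dd, "predictors")
  b <- stats::setNames(rep(0, length(preds)), preds)
  b[names(beta)] <- beta
  inds <- sort(unique(c(dd$individual_a, dd$individual_b)))
  with_seed(seed + 2, {
    u <- stats::setNames(rnorm(length(inds), 0, sigma_u), inds)
    dd$response <- alpha +
      as.vector(as.matrix(dd[, preds]) %*% b) +
      (u[dd$individual_a] + u[dd$individual_b]) / 2 +
      rnorm(nrow(dd), 0, sigma_e)
  })
  list(dataset = dd, truth = c(intercept = alpha, b),
       sigma_u = sigma_u, sigma_e = sigma_e)
}
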