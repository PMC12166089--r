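# Sparse microbial co-occurrence network by neighbourhood selection.
#
# Compositional counts are CLR-transformed, then each taxon's CLR profile
# is regressed on all others with an L1 penalty (Meinshausen-Buhlmann
# neighbourhood selection, the "mb" scheme of SPIEC-EASI-style inference)
# at a fixed sparsity penalty lambda. An edge is kept under the OR rule
# (either direction selected; AND available), signed by the fitted
# coefficients. Centralities (Kleinberg hub, degree, closeness,
# betweenness) position each taxon in the network, and a one-way ANOVA
# compares centrality between immune-predictive taxa and the rest.

#' Centred log-ratio transform
#'
#' Per sample: log(x + pseudocount) minus the sample mean of the logs.
#' Rows sum to zero and the transform is invariant to sample-wise
#' rescaling of the raw abundances.
#'
#' @param table samples x taxa non-negative matrix.
#' @param pseudocount positive offset added before the log.
#' @return real matrix of the same shape.
#' @export
clr_transform <- function(table, pseudocount = 1e-6) {
  check_that(all(table >= 0), "abundances must be non-negative")
  check_that(pseudocount > 0 || (pseudocount == 0 && all(table > 0)),
             "pseudocount must be positive when zeros are present")
  lg <- log(table + pseudocount)
  sweep(lg, 1, rowMeans(lg), `-`)
}

#' Neighbourhood-selection co-occurrence network
#'
#' Columns are standardised, then each node is lasso-regressed on all
#' other nodes at penalty `lambda` (glmnet path ending at `lambda`).
#' Under the default OR rule an edge (a, b) exists when either direction's
#' coefficient is nonzero ("and" requires both); the sign is the sign of
#' the mean coefficient. Increasing lambda can only shrink the edge set.
#'
#' @param clr_matrix samples x taxa real matrix (typically
#'   [clr_transform()] output; >= 10 samples).
#' @param lambda L1 penalty (> 0) on the standardised scale. The default
#'   0.055 annotates the scale used for full-size gut communities, not a
#'   claim about any particular dataset.
#' @param symmetrize `"or"` (default) or `"and"`.
#' @return object of class `taxon_network`: `nodes`, `edges` (node_a,
#'   node_b, weight, sign), `lambda`, `symmetrize`, `dropped`
#'   (zero-variance columns, removed with a warning).
#' @export
mb_network <- function(clr_matrix, lambda = 0.055,
                       symmetrize = c("or", "and")) {
  symmetrize <- match.arg(symmetrize)
  check_that(lambda > 0, "lambda must be positive")
  check_that(nrow(clr_matrix) >= 10, "need at least 10 samples")
  keep <- apply(clr_matrix, 2, function(x) var(x) > 0)
  dropped <- colnames(clr_matrix)[!keep]
  if (length(dropped))
    warning(sprintf("zero-variance column(s) dropped: %s",
                    paste(dropped, collapse = ", ")))
  m <- clr_matrix[, keep, drop = FALSE]
  p <- ncol(m)
  check_that(p >= 2, "need at least 2 non-degenerate taxa")
  z <- scale(m)
  n <- nrow(z)
  B <- matrix(0, p, p, dimnames = list(colnames(m), colnames(m)))
  for (j in seq_len(p)) {
    xj <- z[, -j, drop = FALSE]
    yj <- z[, j]
    lmax <- max(abs(crossprod(xj, yj)) / n)
    path <- if (lmax > lambda)
      exp(seq(log(lmax), log(lambda), length.out = 25)) else lambda
    fit <- glmnet::glmnet(xj, yj, lambda = path, standardize = FALSE,
                          intercept = TRUE)
    b <- as.vector(stats::coef(fit, s = lambda))[-1]
    B[j, -j] <- b
  }
  edges <- NULL
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      sel <- if (symmetrize == "or") B[a, b] != 0 || B[b, a] != 0
             else B[a, b] != 0 && B[b, a] != 0
      if (!sel) next
      w <- mean(c(B[a, b], B[b, a])[c(B[a, b], B[b, a]) != 0])
      edges <- rbind(edges, data.frame(
        node_a = colnames(m)[a], node_b = colnames(m)[b],
        weight = w, sign = ifelse(w >= 0, "positive", "negative"),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges))
    edges <- data.frame(node_a = character(), node_b = character(),
                        weight = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
  structure(list(nodes = colnames(m), edges = edges, lambda = lambda,
                 symmetrize = symmetrize, dropped = dropped),
            class = "taxon_network")
}

# Internal: taxon_network -> igraph with isolated nodes retained.
network_to_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges[, c("node_a", "node_b")],
                                directed = FALSE, vertices = network$nodes)
}

#' Node centralities of a co-occurrence network
#'
#' Degree (incident edge count), closeness (reciprocal of the summed
#' shortest-path lengths; computed over reachable nodes on disconnected
#' graphs, which is flagged), betweenness (unnormalised shortest-path pair
#' counts) and Kleinberg hub score (for an undirected graph, the
#' principal-eigenvector score of the adjacency matrix, normalised so the
#' maximum is 1).
#'
#' @param network a `taxon_network` (>= 2 nodes).
#' @return data.frame, one row per node: node, degree, closeness,
#'   betweenness, kleinberg_hub; attribute `disconnected` flags
#'   per-component closeness.
#' @export
centralities <- function(network) {
  check_that(length(network$nodes) >= 2, "network needs at least 2 nodes")
  g <- network_to_igraph(network)
  disconnected <- !igraph::is_connected(g)
  cl <- suppressWarnings(igraph::closeness(g, mode = "all"))
  hub <- if (nrow(network$edges) == 0) {
    rep(0, length(network$nodes))
  } else {
    # principal eigenvector of the adjacency matrix, computed densely so
    # the result is deterministic (ARPACK's iterative solver is not, in
    # its last digits); sign-fixed and scaled so the maximum is 1
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    v <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
    v / max(v)
  }
  out <- data.frame(
    node = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    closeness = as.numeric(cl),
    betweenness = as.numeric(igraph::betweenness(g, normalized = FALSE)),
    kleinberg_hub = as.numeric(hub),
    stringsAsFactors = FALSE)
  attr(out, "disconnected") <- disconnected
  rownames(out) <- NULL
  out
}

#' Compare centrality between predictive taxa and the rest
#'
#' One-way ANOVA per centrality metric between the immune-predictive group
#' and all other nodes; for two groups the F statistic equals the squared
#' equal-variance two-sample t statistic.
#'
#' @param report centrality table from [centralities()].
#' @param predictive_ids node ids of the predictive group.
#' @param metrics centrality columns to compare.
#' @return data.frame per metric: mean/sd of the predictive group
#'   (`mean_predictive`, `sd_predictive`), of the others, F and p.
#' @export
compare_centrality <- function(report, predictive_ids,
                               metrics = c("kleinberg_hub", "degree",
                                           "closeness", "betweenness")) {
  grp <- factor(ifelse(report$node %in% predictive_ids, "predictive", "other"),
                levels = c("predictive", "other"))
  check_that(all(table(grp) >= 2),
             "both groups need at least 2 nodes for an F test")
  out <- do.call(rbind, lapply(metrics, function(mt) {
    v <- report[[mt]]
    ok <- is.finite(v)
    fit <- stats::aov(v[ok] ~ grp[ok])
    s <- summary(fit)[[1]]
    data.frame(metric = mt,
               mean_predictive = mean(v[grp == "predictive"], na.rm = TRUE),
               sd_predictive = sd(v[grp == "predictive"], na.rm = TRUE),
               mean_other = mean(v[grp == "other"], na.rm = TRUE),
               sd_other = sd(v[grp == "other"], na.rm = TRUE),
               F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a three-variable Markov chain community
#'
#' Generator for conditional-independence checks: A is standard normal,
#' B = rho * A + noise, C = rho * B + noise. The generating precision
#' matrix links A-B and B-C only, so a correct neighbourhood-selection
#' network recovers those two edges and leaves A-C absent.
#'
#' @param n samples.
#' @param rho chain coefficient.
#' @param seed integer RNG seed.
#' @return n x 3 matrix with columns A, B, C.
#' @export
simulate_markov_triplet <- function(n = 300, rho = 0.7, seed = 1) {
  with_seed(seed, {
    A <- rnorm(n)
    B <- rho * A + rnorm(n, 0, sqrt(1 - rho^2))
    C <- rho * B + rnorm(n, 0, sqrt(1 - rho^2))
    cbind(A = A, B = B, C = C)
  })
}
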