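# Beta-diversity, similarity transforms, component subsets and
# distance-based repeatability (dICC).

#' Pairwise beta-diversity between samples
#'
#' Bray-Curtis and Jaccard dissimilarities are computed with
#' \code{vegan::vegdist} (Jaccard on presence/absence, the
#' (b+c)/(a+b+c) form); the Aitchison distance is the Euclidean distance
#' between CLR-transformed compositions after adding a pseudocount.
#'
#' @param table samples x taxa non-negative abundance matrix.
#' @param metric one of `"bray"`, `"jaccard"`, `"aitchison"`.
#' @param pseudocount added before the log for the Aitchison metric
#'   (default 1e-6, suited to relative abundances).
#' @return symmetric n x n matrix with zero diagonal and a `metric`
#'   attribute. A Bray-Curtis distance between two all-zero samples is
#'   defined as 0, with a warning.
#' @export
beta_diversity <- function(table, metric = c("bray", "jaccard", "aitchison"),
                           pseudocount = 1e-6) {
  metric <- match.arg(metric)
  check_that(all(table >= 0), "abundances must be non-negative")
  if (metric == "aitchison") {
    check_that(pseudocount > 0 || (pseudocount == 0 && all(table > 0)),
               "pseudocount must be positive when zeros are present")
    d <- stats::dist(clr_transform(table, pseudocount))
  } else if (metric == "bray") {
    zero <- rowSums(table) == 0
    d <- suppressWarnings(vegan::vegdist(table, method = "bray"))
    if (any(zero)) {
      warning("all-zero sample(s): Bray-Curtis distance to them set to 0")
      m <- as.matrix(d)
      m[zero, ] <- 0
      m[, zero] <- 0
      d <- stats::as.dist(m)
    }
  } else {
    d <- vegan::vegdist(table, method = "jaccard", binary = TRUE)
  }
  out <- as.matrix(d)
  diag(out) <- 0
  dimnames(out) <- list(rownames(table), rownames(table))
  attr(out, "metric") <- metric
  out
}

#' Similarity transform of a distance matrix
#'
#' Bounded metrics (Bray-Curtis, Jaccard) map as s = 1 - d. Unbounded
#' metrics (Aitchison) are min-max normalised over all entries to \[0, 1\]
#' before the complement, so the largest observed distance maps to
#' similarity 0 and identical samples to 1.
#'
#' @param dm distance matrix from [beta_diversity()] (or any symmetric
#'   matrix with a `metric` attribute).
#' @return similarity matrix in \[0, 1\] with unit diagonal.
#' @export
to_similarity <- function(dm) {
  metric <- attr(dm, "metric")
  if (is.null(metric)) metric <- if (max(dm) <= 1) "bray" else "aitchison"
  if (metric %in% c("bray", "jaccard")) {
    s <- 1 - dm
  } else {
    rng <- range(dm)
    s <- if (rng[2] - rng[1] < .Machine$double.eps) {
      matrix(1, nrow(dm), ncol(dm), dimnames = dimnames(dm))
    } else 1 - (dm - rng[1]) / (rng[2] - rng[1])
  }
  attr(s, "metric") <- metric
  s
}

#' Select cASVs belonging to one community component
#'
#' The community is decomposed into bacteria (domain Bacteria), known
#' eukaryotic parasites (a configurable genus/order list) and fungi
#' (kingdom Fungi); `overall` returns every cASV.
#'
#' @param mapping cASV mapping from [merge_casvs()] (casv_id, asv_id).
#' @param taxonomy per-ASV taxonomy (asv_id, domain, kingdom, genus, ...).
#' @param name component name.
#' @param parasite_taxa genus/clade labels identifying parasites.
#' @return character vector of cASV ids whose members belong to the
#'   component.
#' @export
component_subset <- function(mapping, taxonomy,
                             name = c("overall", "bacteria", "parasites", "fungi"),
                             parasite_taxa = c("Ancylostoma", "Sarcocystis",
                                               "Spirurida", "Cystoisospora",
                                               "Cryptosporidium", "Ascaridida",
                                               "Diphyllobothriidea",
                                               "Cyclophyllidea")) {
  name <- match.arg(name)
  if (name == "overall") return(unique(mapping$casv_id))
  tx <- taxonomy[match(mapping$asv_id, taxonomy$asv_id), ]
  in_comp <- switch(name,
    bacteria = !is.na(tx$domain) & tx$domain == "Bacteria",
    fungi = !is.na(tx$kingdom) & tx$kingdom == "Fungi",
    parasites = {
      hit <- rep(FALSE, nrow(tx))
      for (col in intersect(c("genus", "family", "order", "class"), colnames(tx)))
        hit <- hit | (!is.na(tx[[col]]) &
                        sub("_.*$", "", tx[[col]]) %in% parasite_taxa)
      hit
    })
  unique(mapping$casv_id[in_comp])
}

# Core dICC computation on a distance matrix with group labels.
# One-way-ANOVA decomposition on squared distances:
#   SSW = sum over groups of (1/n_i) * sum of within-group pair d^2
#   SST = (1/N) * sum of all-pair d^2, SSB = SST - SSW
#   dICC = (MSB - MSW) / (MSB + (n0 - 1) MSW), n0 the design-balanced size.
# On 1-D Euclidean data this equals the classical one-way ICC exactly.
dicc_point <- function(d2, groups) {
  N <- length(groups)
  g_lv <- unique(groups)
  g <- length(g_lv)
  n_i <- as.numeric(table(factor(groups, levels = g_lv)))
  ssw <- 0
  for (k in seq_len(g)) {
    idx <- which(groups == g_lv[k])
    if (length(idx) > 1)
      ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  sst <- sum(d2[upper.tri(d2)]) / N
  ssb <- sst - ssw
  msb <- ssb / (g - 1)
  msw <- ssw / (N - g)
  n0 <- (N - sum(n_i^2) / N) / (g - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

#' Distance-based intraclass correlation (repeatability)
#'
#' Quantifies how repeatable an individual's community composition is over
#' time: the one-way ANOVA intraclass correlation computed directly from a
#' distance matrix via its squared-distance decomposition. The bootstrap
#' resamples individuals (with all their samples) with replacement and
#' reports the standard deviation of bootstrap dICCs as the SE.
#'
#' @param dm distance matrix over samples.
#' @param individual_ids individual label per sample (row of `dm`).
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer RNG seed for the bootstrap.
#' @return list of class `dicc_result`: `dicc`, `se`, `n_boot`,
#'   `n_samples`, `n_individuals`.
#' @export
dicc <- function(dm, individual_ids, n_boot = 1000, seed = 1) {
  check_that(nrow(dm) == length(individual_ids),
             "one individual id per sample required")
  counts <- table(individual_ids)
  check_that(sum(counts >= 2) >= 2,
             "need at least two individuals with repeated samples")
  d2 <- dm^2
  est <- dicc_point(d2, individual_ids)
  ids <- names(counts)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      draw <- sample(ids, length(ids), replace = TRUE)
      idx <- integer(0)
      grp <- character(0)
      for (k in seq_along(draw)) {
        w <- which(individual_ids == draw[k])
        idx <- c(idx, w)
        grp <- c(grp, rep(sprintf("bg%d", k), length(w)))
      }
      if (length(unique(grp[duplicated(grp) | duplicated(grp, fromLast = TRUE)])) < 2)
        return(NA_real_)
      dicc_point(d2[idx, idx, drop = FALSE], grp)
    }, numeric(1))
  })
  structure(list(dicc = est, se = sd(boots, na.rm = TRUE), n_boot = n_boot,
                 n_samples = nrow(dm), n_individuals = length(ids)),
            class = "dicc_result")
}

#' @export
print.dicc_result <- function(x, ...) {
  cat(sprintf("dICC = %.4f (SE %.4f, %d bootstrap iterations; %d samples, %d individuals)\n",
              x$dicc, x$se, x$n_boot, x$n_samples, x$n_individuals))
  invisible(x)
}
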