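# Merging ASVs into combined ASVs (cASVs).
#
# A multi-marker design targets several loci of the same organism, so one
# taxon can surface as several ASVs (within and across amplicons). ASVs
# annotated to the same genus whose relative abundances co-vary positively
# and significantly across samples are taken to represent one taxon: a
# within-genus co-abundance network is built (Pearson r > 0, BH-adjusted
# p < 0.01), fast-greedy modularity communities are found, and each
# community's abundances are summed into one cASV. ASVs that cluster with
# nothing pass through unchanged.

#' Benjamini-Hochberg step-up adjustment
#'
#' Direct implementation of the textbook step-up: sort ascending, scale
#' the i-th order statistic by m/i, enforce monotonicity by a running
#' minimum from the top, cap at 1 and restore the input order. (Written
#' out rather than delegating so the arithmetic follows the canonical
#' p_(i) * m / i order; \code{stats::p.adjust} is numerically equal up to
#' association of the multiply and divide.)
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  check_that(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
             "p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  scaled <- pvalues[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(scaled))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Vectorised Pearson r and two-sided p (exact t transform, n-2 df) for all
# column pairs of a samples x ASVs matrix. Zero-variance columns excluded.
pairwise_pearson <- function(mat) {
  keep <- apply(mat, 2, function(x) var(x) > 0)
  excluded <- colnames(mat)[!keep]
  mat <- mat[, keep, drop = FALSE]
  p_n <- ncol(mat)
  if (p_n < 2)
    return(list(stats = data.frame(asv_a = character(), asv_b = character(),
                                   pearson_r = numeric(), p = numeric(),
                                   stringsAsFactors = FALSE),
                excluded = excluded))
  n <- nrow(mat)
  r <- stats::cor(mat)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[idx]
  rv <- pmin(pmax(rv, -1), 1)
  tt <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  pv <- 2 * pt(-abs(tt), df = n - 2)
  pv[abs(rv) >= 1 - 1e-15] <- 0
  list(stats = data.frame(asv_a = colnames(mat)[idx[, 1]],
                          asv_b = colnames(mat)[idx[, 2]],
                          pearson_r = rv, p = pv, stringsAsFactors = FALSE),
       excluded = excluded)
}

#' Within-genus co-abundance network
#'
#' Computes Pearson correlations between all pairs of ASVs annotated to one
#' genus across all retained samples, adjusts the genus's pair p-values with
#' Benjamini-Hochberg, and keeps an edge where r > 0 and adjusted p < alpha.
#'
#' @param table samples x ASVs relative-abundance matrix (collated).
#' @param genus genus label to build the network for.
#' @param taxonomy per-ASV taxonomy (columns `asv_id`, `genus`).
#' @param alpha significance cutoff on the adjusted p-value (default 0.01).
#' @return object of class `coabundance_network`: list with `genus`,
#'   `nodes` (ASVs entering the correlation, zero-variance ones excluded
#'   and listed in `excluded`), and `edges`
#'   (asv_a, asv_b, pearson_r, p, p_adj).
#' @export
genus_correlation_network <- function(table, genus, taxonomy, alpha = 0.01) {
  check_that(nrow(table) >= 3, "need at least 3 samples for correlations")
  asvs <- intersect(taxonomy$asv_id[!is.na(taxonomy$genus) &
                                      taxonomy$genus == genus],
                    colnames(table))
  check_that(length(asvs) >= 2, "genus %s has fewer than 2 ASVs in the table",
             genus)
  pw <- pairwise_pearson(table[, asvs, drop = FALSE])
  ed <- pw$stats
  ed$p_adj <- bh_adjust(ed$p)
  ed <- ed[ed$pearson_r > 0 & ed$p_adj < alpha, , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(genus = genus, nodes = setdiff(asvs, pw$excluded),
                 excluded = pw$excluded, edges = ed),
            class = "coabundance_network")
}

#' Cluster co-abundance networks and merge members into cASVs
#'
#' Runs fast-greedy modularity community detection on each genus network
#' (deterministic: vertices enter in lexicographic order) and sums each
#' community's per-sample abundances into one cASV column. Every ASV not in
#' a multi-member community passes through as its own cASV, so per-sample
#' totals are conserved exactly.
#'
#' @param networks a `coabundance_network` or list of them (one per genus).
#' @param table samples x ASVs abundance matrix covering all network nodes.
#' @return list with `casv_table` (samples x cASVs) and `mapping`
#'   (data.frame: casv_id, asv_id, genus, singleton).
#' @export
cluster_and_merge <- function(networks, table) {
  if (inherits(networks, "coabundance_network")) networks <- list(networks)
  asv_ids <- colnames(table)
  casv_of <- stats::setNames(asv_ids, asv_ids)   # default: self
  genus_of <- stats::setNames(rep(NA_character_, length(asv_ids)), asv_ids)
  for (nw in networks) {
    genus_of[nw$nodes] <- nw$genus
    genus_of[nw$excluded] <- nw$genus
    if (nrow(nw$edges) == 0) next
    verts <- sort(unique(c(nw$edges$asv_a, nw$edges$asv_b)))
    g <- igraph::graph_from_data_frame(nw$edges[, c("asv_a", "asv_b")],
                                       directed = FALSE, vertices = verts)
    memb <- igraph::membership(igraph::cluster_fast_greedy(g))
    # modularity clustering ties on an isolated two-node component and can
    # leave the pair split; a connected pair is a community by definition
    # (the significant positive edge is the merge criterion)
    comp <- igraph::components(g)
    for (ci in which(comp$csize == 2)) {
      vs <- names(comp$membership)[comp$membership == ci]
      memb[vs] <- max(memb) + 1L
    }
    k <- 0L
    for (cid in sort(unique(memb))) {
      members <- names(memb)[memb == cid]
      if (length(members) < 2) next
      k <- k + 1L
      casv_of[members] <- sprintf("cASV_%s_%02d", nw$genus, k)
    }
  }
  groups <- split(asv_ids, casv_of[asv_ids])
  # keep column order stable: order cASVs by their first member's position
  groups <- groups[order(vapply(groups, function(m)
    min(match(m, asv_ids)), numeric(1)))]
  casv_ids <- names(groups)
  casv_table <- matrix(0, nrow(table), length(groups),
                       dimnames = list(rownames(table), casv_ids))
  for (j in seq_along(groups))
    casv_table[, j] <- rowSums(table[, groups[[j]], drop = FALSE])
  mapping <- data.frame(
    casv_id = rep(casv_ids, lengths(groups)),
    asv_id = unlist(groups, use.names = FALSE),
    stringsAsFactors = FALSE)
  mapping$genus <- genus_of[mapping$asv_id]
  sizes <- stats::setNames(lengths(groups), casv_ids)
  mapping$singleton <- sizes[mapping$casv_id] == 1
  rownames(mapping) <- NULL
  list(casv_table = casv_table, mapping = mapping)
}

#' Merge a collated ASV table into cASVs across all genera
#'
#' Builds a within-genus co-abundance network for every genus with at least
#' two annotated ASVs and merges each fast-greedy community into a cASV.
#' BH correction is applied over each genus's pair set by default;
#' `bh_scope = "global"` pools all within-genus pairs into one family.
#' ASVs without a genus annotation are left unmerged by default; with
#' `merge_unannotated = TRUE` they are grouped by their lowest available
#' taxonomic rank label instead.
#'
#' @param collated result of [collate()]/[preprocess_amplicons()], or a
#'   samples x ASVs matrix.
#' @param taxonomy per-ASV taxonomy with `asv_id` and `genus` (higher ranks
#'   used only for unannotated grouping).
#' @param alpha adjusted-p cutoff for edges (default 0.01).
#' @param bh_scope `"genus"` (default) or `"global"` BH family.
#' @param merge_unannotated group genus-less ASVs by lowest shared rank.
#' @return as [cluster_and_merge()], plus `networks` (per-genus edge sets).
#' @export
merge_casvs <- function(collated, taxonomy, alpha = 0.01,
                        bh_scope = c("genus", "global"),
                        merge_unannotated = FALSE) {
  bh_scope <- match.arg(bh_scope)
  table <- if (is.list(collated) && !is.null(collated$rel_abundance))
    collated$rel_abundance else collated
  tax <- taxonomy
  tax$.genus <- tax$genus
  if (merge_unannotated) {
    ranks <- intersect(c("family", "order", "class", "phylum", "kingdom",
                         "domain"), colnames(tax))
    for (i in which(is.na(tax$.genus))) {
      for (r in ranks) {
        if (!is.na(tax[[r]][i])) {
          tax$.genus[i] <- paste0(r, ":", tax[[r]][i])
          break
        }
      }
    }
  }
  tax <- tax[tax$asv_id %in% colnames(table) & !is.na(tax$.genus), ]
  genera <- names(which(table(tax$.genus) >= 2))
  tx <- data.frame(asv_id = tax$asv_id, genus = tax$.genus,
                   stringsAsFactors = FALSE)
  if (bh_scope == "genus") {
    networks <- lapply(genera, function(g)
      genus_correlation_network(table, g, tx, alpha = alpha))
  } else {
    # pool all within-genus pairs into a single BH family
    per_genus <- lapply(genera, function(g) {
      asvs <- intersect(tx$asv_id[tx$genus == g], colnames(table))
      pw <- pairwise_pearson(table[, asvs, drop = FALSE])
      pw$genus <- g
      pw$nodes <- setdiff(asvs, pw$excluded)
      pw
    })
    all_p <- unlist(lapply(per_genus, function(x) x$stats$p))
    adj <- bh_adjust(all_p)
    off <- 0L
    networks <- lapply(per_genus, function(x) {
      n_i <- nrow(x$stats)
      ed <- x$stats
      ed$p_adj <- adj[off + seq_len(n_i)]
      off <<- off + n_i
      ed <- ed[ed$pearson_r > 0 & ed$p_adj < alpha, , drop = FALSE]
      rownames(ed) <- NULL
      structure(list(genus = x$genus, nodes = x$nodes, excluded = x$excluded,
                     edges = ed), class = "coabundance_network")
    })
  }
  out <- cluster_and_merge(networks, table)
  out$networks <- networks
  out
}
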