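# Quality filtering, total-sum scaling and collation of per-amplicon ASV
# count tables. Filtering and normalisation are applied to each amplicon
# separately; the filtered relative-abundance blocks are then collated into
# one table over the union of samples.

#' Filter rare ASVs and shallow samples
#'
#' Removes ASVs with nonzero counts in fewer than `min_sample_prevalence`
#' samples and samples with fewer than `min_reads` total reads, per
#' amplicon table. The two filters interact (dropping a shallow sample can
#' push an ASV below the prevalence cutoff), so they are iterated to a
#' fixed point; this makes the operation idempotent and in practice
#' converges in one or two passes.
#'
#' @param tables list of samples x ASVs integer count matrices (one per
#'   amplicon, `amplicon_id` attribute preserved).
#' @param min_sample_prevalence minimum number of samples an ASV must occur
#'   in (default 2: ASVs present in only one sample are removed).
#' @param min_reads minimum per-sample read total (default 100; a sample
#'   with exactly 100 reads is kept, "less than 100" are removed).
#' @return list of filtered matrices with a `removal_log` attribute
#'   (data.frame: amplicon, type asv/sample, id, reason).
#' @export
filter_asvs_and_samples <- function(tables, min_sample_prevalence = 2,
                                    min_reads = 100) {
  if (is.matrix(tables)) tables <- list(tables)
  log_rows <- list()
  out <- lapply(tables, function(m) {
    check_that(all(m >= 0), "counts must be non-negative")
    amp <- attr(m, "amplicon_id")
    if (is.null(amp)) amp <- NA_character_
    repeat {
      prev <- colSums(m > 0)
      drop_asv <- prev < min_sample_prevalence
      if (any(drop_asv)) {
        log_rows[[length(log_rows) + 1]] <<- data.frame(
          amplicon = amp, type = "asv", id = colnames(m)[drop_asv],
          reason = sprintf("prevalence < %d", min_sample_prevalence),
          stringsAsFactors = FALSE)
        m <- m[, !drop_asv, drop = FALSE]
      }
      if (ncol(m) == 0)
        stop(sprintf("amplicon %s: ASV prevalence filter removed every ASV",
                     amp), call. = FALSE)
      tot <- rowSums(m)
      drop_s <- tot < min_reads
      if (any(drop_s)) {
        log_rows[[length(log_rows) + 1]] <<- data.frame(
          amplicon = amp, type = "sample", id = rownames(m)[drop_s],
          reason = sprintf("reads < %d", min_reads), stringsAsFactors = FALSE)
        m <- m[!drop_s, , drop = FALSE]
      }
      if (nrow(m) == 0)
        stop(sprintf("amplicon %s: sample read-total filter removed every sample",
                     amp), call. = FALSE)
      if (!any(drop_asv) && !any(drop_s)) break
    }
    m
  })
  attr(out, "removal_log") <- if (length(log_rows))
    do.call(rbind, log_rows)
  else
    data.frame(amplicon = character(), type = character(), id = character(),
               reason = character(), stringsAsFactors = FALSE)
  out
}

#' Total-sum scaling to relative abundances
#'
#' Divides each sample row by its total. All-zero rows stay zero, with a
#' warning.
#'
#' @param table samples x ASVs non-negative matrix.
#' @return matrix of the same shape; nonzero rows sum to 1.
#' @export
tss_normalize <- function(table) {
  check_that(all(table >= 0), "counts must be non-negative")
  tot <- rowSums(table)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero sample(s) left at zero under total-sum scaling",
                    sum(zero)))
    tot[zero] <- 1
  }
  out <- table / tot
  attr(out, "amplicon_id") <- attr(table, "amplicon_id")
  out
}

#' Collate per-amplicon relative-abundance tables
#'
#' Block-concatenates amplicon tables over the union of their samples.
#' A sample missing from an amplicon (e.g. filtered there for low reads)
#' gets zeros in that block, so downstream distance computations see a
#' complete matrix. ASV-to-amplicon provenance is retained.
#'
#' @param tables list of samples x ASVs matrices, each carrying an
#'   `amplicon_id` attribute (or named list).
#' @return list with `rel_abundance` (samples x all-ASVs matrix) and
#'   `asv_map` (data.frame: asv_id, amplicon_id).
#' @export
collate <- function(tables) {
  if (is.matrix(tables)) tables <- list(tables)
  check_that(length(tables) >= 1, "no tables to collate")
  amp_ids <- vapply(seq_along(tables), function(i) {
    a <- attr(tables[[i]], "amplicon_id")
    if (is.null(a)) a <- names(tables)[i]
    if (is.null(a) || is.na(a) || !nzchar(a)) a <- sprintf("amp%02d", i)
    a
  }, character(1))
  pairs <- unlist(lapply(seq_along(tables), function(i)
    paste(amp_ids[i], colnames(tables[[i]]))))
  check_that(!anyDuplicated(pairs), "duplicate (amplicon, asv) pairs")
  samples <- sort(unique(unlist(lapply(tables, rownames))))
  blocks <- lapply(tables, function(m) {
    out <- matrix(0, length(samples), ncol(m),
                  dimnames = list(samples, colnames(m)))
    out[rownames(m), ] <- m
    out
  })
  rel <- do.call(cbind, blocks)
  asv_map <- data.frame(
    asv_id = unlist(lapply(tables, colnames)),
    amplicon_id = rep(amp_ids, vapply(tables, ncol, integer(1))),
    stringsAsFactors = FALSE)
  list(rel_abundance = rel, asv_map = asv_map)
}

#' Filter, normalise and collate in one call
#'
#' Convenience wrapper running [filter_asvs_and_samples()],
#' [tss_normalize()] per amplicon and [collate()].
#'
#' @inheritParams filter_asvs_and_samples
#' @return see [collate()]; the filtering `removal_log` is attached.
#' @export
preprocess_amplicons <- function(tables, min_sample_prevalence = 2,
                                 min_reads = 100) {
  filt <- filter_asvs_and_samples(tables, min_sample_prevalence, min_reads)
  rel <- lapply(filt, tss_normalize)
  out <- collate(rel)
  attr(out, "removal_log") <- attr(filt, "removal_log")
  out
}
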