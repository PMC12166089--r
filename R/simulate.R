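# Synthetic multi-amplicon microbiome generator.
#
# Emulates the statistical structure of a multi-marker gut-microbiome study
# of a wild social carnivore: repeatedly sampled hosts with clan membership,
# social rank and age; faecal immune measures (IgA, mucin) that track age;
# latent taxon abundances driven by host covariates; and several amplicons
# observing the same latent taxa, so that the true ASV-to-taxon map is known
# and downstream clustering can be scored against it.

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Dry season runs June-October; wet November-May.
season_from_date <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  ifelse(m >= 6 & m <= 10, "dry", "wet")
}

#' Simulate a host population with repeated faecal sampling
#'
#' Generates individuals (clan, sex, social rank in \[-1, 1\], optional
#' mother) and one to three faecal samples per individual. Ages at sampling
#' are drawn log-uniformly over 50-5800 days so both juveniles and adults
#' are represented; repeat samples of an individual have distinct, later
#' dates.
#'
#' @param n_individuals number of hosts (>= 2).
#' @param n_clans number of social clans (>= 1).
#' @param repeat_fraction fraction of individuals sampled 2-3 times.
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @param n_batches number of sequencing batches assigned to samples.
#' @return list with `hosts` (one row per individual: individual_id, clan,
#'   mother_id, sex, rank) and `metadata` (one row per sample: sample_id,
#'   individual_id, age_days, date, season, batch; immune columns `f_iga`,
#'   `f_mucin` initialised to NA, see [simulate_immune()]).
#' @export
simulate_hosts <- function(n_individuals, n_clans = 3, repeat_fraction = 0.25,
                           seed = 1, n_batches = 3) {
  check_that(n_individuals >= 2, "n_individuals must be >= 2")
  check_that(n_clans >= 1, "n_clans must be >= 1")
  check_that(repeat_fraction >= 0 && repeat_fraction <= 1,
             "repeat_fraction must lie in [0, 1]")
  with_seed(seed, {
    ind <- sprintf("ind%03d", seq_len(n_individuals))
    clan <- sprintf("clan%d", sample.int(n_clans, n_individuals, replace = TRUE))
    sex <- sample(c("F", "M"), n_individuals, replace = TRUE)
    rank <- runif(n_individuals, -1, 1)
    # mothers: about half the individuals have a known mother from the same clan
    mother <- rep(NA_character_, n_individuals)
    for (i in seq_len(n_individuals)) {
      mates <- setdiff(which(clan == clan[i]), i)
      if (length(mates) > 0 && runif(1) < 0.5)
        mother[i] <- ind[sample(mates, 1)]
    }
    hosts <- data.frame(individual_id = ind, clan = clan, mother_id = mother,
                        sex = sex, rank = rank, stringsAsFactors = FALSE)

    n_rep <- round(repeat_fraction * n_individuals)
    repeated <- if (n_rep > 0) sample(ind, n_rep) else character(0)
    n_samp <- ifelse(ind %in% repeated, sample(2:3, n_individuals, replace = TRUE), 1L)

    rows <- vector("list", n_individuals)
    origin <- as.Date("2004-01-01")
    span <- as.integer(as.Date("2018-12-31") - origin)
    for (i in seq_len(n_individuals)) {
      age0 <- exp(runif(1, log(50), log(5800)))
      date0 <- origin + sample.int(span, 1)
      gaps <- if (n_samp[i] > 1) cumsum(round(runif(n_samp[i] - 1, 30, 365))) else integer(0)
      offs <- c(0L, as.integer(gaps))
      rows[[i]] <- data.frame(
        individual_id = ind[i],
        age_days = as.integer(round(age0)) + offs,
        date = date0 + offs,
        stringsAsFactors = FALSE)
    }
    metadata <- do.call(rbind, rows)
    metadata$sample_id <- sprintf("s%03d", seq_len(nrow(metadata)))
    metadata$season <- season_from_date(metadata$date)
    metadata$batch <- sprintf("b%d", sample.int(n_batches, nrow(metadata), replace = TRUE))
    metadata$f_iga <- NA_real_
    metadata$f_mucin <- NA_real_
    metadata <- metadata[, c("sample_id", "individual_id", "age_days", "date",
                             "season", "batch", "f_iga", "f_mucin")]
    rownames(metadata) <- metadata$sample_id
    list(hosts = hosts, metadata = metadata)
  })
}

#' Fill in age-modulated faecal immune measures
#'
#' Faecal IgA and mucin are generated as linear functions of log age plus
#' Gaussian noise, truncated at zero. Any monotone link satisfies the
#' downstream contracts; the log link keeps juvenile-adult contrasts on a
#' plausible scale.
#'
#' @param metadata sample metadata from [simulate_hosts()].
#' @param age_slope slope on log(age in days); length 1 (shared) or 2
#'   (IgA, mucin).
#' @param noise_sd Gaussian noise standard deviation (>= 0), length 1 or 2.
#' @param seed integer RNG seed.
#' @param baseline intercepts for (IgA, mucin), in relative units and
#'   umol equivalents respectively.
#' @return `metadata` with `f_iga` and `f_mucin` filled.
#' @export
simulate_immune <- function(metadata, age_slope = 0.4, noise_sd = 0.2,
                            seed = 1, baseline = c(1, 2)) {
  check_that(all(noise_sd >= 0), "noise_sd must be non-negative")
  check_that(all(metadata$age_days >= 0), "metadata must carry non-negative ages")
  slope <- rep_len(age_slope, 2)
  nsd <- rep_len(noise_sd, 2)
  base <- rep_len(baseline, 2)
  n <- nrow(metadata)
  la <- log(pmax(metadata$age_days, 1))
  with_seed(seed, {
    metadata$f_iga <- pmax(0, base[1] + slope[1] * la + rnorm(n, 0, nsd[1]))
    metadata$f_mucin <- pmax(0, base[2] + slope[2] * la + rnorm(n, 0, nsd[2]))
  })
  metadata
}

#' Default per-taxon effect configuration for the latent community
#'
#' One row per latent taxon: taxonomic labels (component, genus) and the
#' generative coefficients of its log-abundance model. Defaults give a
#' covariate-free community with individual signatures (`sd_indiv`) and
#' sample noise (`sd_resid`); effect sizes for taxon-immune links are
#' deliberately config-exposed rather than asserted as biology.
#'
#' @param n_taxa number of latent taxa (>= 1).
#' @param taxa_per_genus average number of taxa sharing a genus (>= 1);
#'   values above 1 make within-genus cASV merging non-trivial.
#' @param prop_components named proportions for bacteria/fungi/parasite.
#' @param beta_age,beta_iga,beta_mucin per-taxon coefficients (recycled).
#' @param sd_clan,sd_season,sd_indiv,sd_resid random-effect and residual
#'   standard deviations on the log scale (recycled).
#' @param intercept_sd spread of taxon base log-abundances.
#' @param seed integer RNG seed (for intercepts and genus assignment).
#' @return data.frame with one row per taxon.
#' @export
default_effect_config <- function(n_taxa, taxa_per_genus = 2,
                                  prop_components = c(bacteria = 0.6, fungi = 0.25,
                                                      parasite = 0.15),
                                  beta_age = 0, beta_iga = 0, beta_mucin = 0,
                                  sd_clan = 0.25, sd_season = 0.25,
                                  sd_indiv = 0.5, sd_resid = 1,
                                  intercept_sd = 1.5, seed = 1) {
  check_that(n_taxa >= 1, "n_taxa must be >= 1")
  check_that(taxa_per_genus >= 1, "taxa_per_genus must be >= 1")
  pools <- list(
    bacteria = c("Lactobacillus", "Bacteroides", "Prevotella", "Clostridium",
                 "Fusobacterium", "Streptococcus", "Campylobacter", "Blautia",
                 "Roseburia", "Escherichia", "Faecalibacterium", "Treponema"),
    fungi = c("Aspergillus", "Candida", "Penicillium", "Saccharomyces",
              "Mucor", "Neocallimastix", "Malassezia", "Trichosporon"),
    parasite = c("Ancylostoma", "Sarcocystis", "Spirurida", "Cystoisospora",
                 "Cryptosporidium", "Ascaridida", "Diphyllobothriidea",
                 "Cyclophyllidea"))
  with_seed(seed, {
    n_each <- round(prop_components / sum(prop_components) * n_taxa)
    names(n_each) <- names(prop_components)
    while (sum(n_each) < n_taxa) n_each[1] <- n_each[1] + 1
    while (sum(n_each) > n_taxa) n_each[which.max(n_each)] <- max(n_each) - 1
    component <- rep(names(n_each), n_each)
    genus <- character(n_taxa)
    for (cmp in unique(component)) {
      idx <- which(component == cmp)
      n_gen <- max(1, round(length(idx) / taxa_per_genus))
      base <- rep_len(pools[[cmp]], n_gen)
      gnames <- ifelse(duplicated(base) | duplicated(base, fromLast = TRUE),
                       paste0(base, "_", stats::ave(seq_len(n_gen), base,
                                                    FUN = seq_along)),
                       base)
      genus[idx] <- sample(rep_len(gnames, length(idx)))
    }
    data.frame(
      taxon_id = sprintf("taxon%03d", seq_len(n_taxa)),
      genus = genus,
      component = component,
      intercept = rnorm(n_taxa, 0, intercept_sd),
      beta_age = rep_len(beta_age, n_taxa),
      beta_iga = rep_len(beta_iga, n_taxa),
      beta_mucin = rep_len(beta_mucin, n_taxa),
      sd_clan = rep_len(sd_clan, n_taxa),
      sd_season = rep_len(sd_season, n_taxa),
      sd_indiv = rep_len(sd_indiv, n_taxa),
      sd_resid = rep_len(sd_resid, n_taxa),
      stringsAsFactors = FALSE)
  })
}

#' Simulate latent taxon abundances from host covariates
#'
#' Per-taxon log-abundance is an additive model in log age, f-IgA, f-mucin,
#' clan and season effects, an individual signature and residual noise,
#' exponentiated to a non-negative abundance. With all coefficients and
#' standard deviations zero the abundance matrix has identical rows.
#'
#' @param metadata sample metadata (immune columns required when any
#'   `beta_iga`/`beta_mucin` is nonzero).
#' @param hosts host table from [simulate_hosts()].
#' @param n_taxa number of latent taxa; ignored when `effect_config` given.
#' @param effect_config per-taxon configuration, see
#'   [default_effect_config()].
#' @param seed integer RNG seed.
#' @return object of class `latent_community`: list with `taxa`
#'   (taxon_id, genus, component), `abundance` (samples x taxa matrix) and
#'   the `effect_config` used.
#' @export
simulate_latent <- function(metadata, hosts, n_taxa = 40,
                            effect_config = default_effect_config(n_taxa),
                            seed = 1) {
  check_that(nrow(effect_config) >= 1, "at least one taxon required")
  cfg <- effect_config
  num <- cfg[, c("intercept", "beta_age", "beta_iga", "beta_mucin",
                 "sd_clan", "sd_season", "sd_indiv", "sd_resid")]
  check_that(all(is.finite(as.matrix(num))), "effect_config must be finite")
  needs_imm <- any(cfg$beta_iga != 0) || any(cfg$beta_mucin != 0)
  if (needs_imm)
    check_that(!anyNA(metadata$f_iga) && !anyNA(metadata$f_mucin),
               "immune measures must be simulated before using immune effects")
  iga <- ifelse(is.na(metadata$f_iga), 0, metadata$f_iga)
  muc <- ifelse(is.na(metadata$f_mucin), 0, metadata$f_mucin)
  la <- log(pmax(metadata$age_days, 1))
  clan <- hosts$clan[match(metadata$individual_id, hosts$individual_id)]
  n_s <- nrow(metadata)
  n_t <- nrow(cfg)
  with_seed(seed, {
    ab <- matrix(0, n_s, n_t, dimnames = list(metadata$sample_id, cfg$taxon_id))
    clans <- unique(clan)
    inds <- unique(metadata$individual_id)
    seasons <- c("dry", "wet")
    for (t in seq_len(n_t)) {
      ce <- stats::setNames(rnorm(length(clans), 0, cfg$sd_clan[t]), clans)
      se <- stats::setNames(rnorm(2, 0, cfg$sd_season[t]), seasons)
      ue <- stats::setNames(rnorm(length(inds), 0, cfg$sd_indiv[t]), inds)
      eps <- rnorm(n_s, 0, cfg$sd_resid[t])
      ab[, t] <- exp(cfg$intercept[t] + cfg$beta_age[t] * la +
                       cfg$beta_iga[t] * iga + cfg$beta_mucin[t] * muc +
                       ce[clan] + se[metadata$season] +
                       ue[metadata$individual_id] + eps)
    }
    structure(list(taxa = cfg[, c("taxon_id", "genus", "component")],
                   abundance = ab, effect_config = cfg),
              class = "latent_community")
  })
}

#' Define a multi-amplicon observation design
#'
#' Each amplicon observes each latent taxon with a fixed detection outcome
#' (drawn once from `detection_prob`), a lognormal efficiency multiplier,
#' and one or more ASVs whose split proportions are fixed, positive and sum
#' to one. Per-sample sequencing depth is negative-binomial around
#' `depth_mean`.
#'
#' @param taxa taxon table (`taxa` element of a `latent_community`).
#' @param n_amplicons number of amplicons.
#' @param n_asvs_per_taxon ASVs each amplicon yields per detected taxon;
#'   scalar, or a function(n_taxa) returning an integer vector.
#' @param detection_prob probability an amplicon detects a taxon at all;
#'   scalar or per-taxon vector.
#' @param efficiency_sd lognormal sd of per-taxon amplification efficiency.
#' @param depth_mean,depth_dispersion negative-binomial depth parameters
#'   (mean reads per amplicon per sample; size/dispersion parameter).
#' @param seed integer RNG seed (detection, efficiencies, proportions).
#' @return object of class `amplicon_design`.
#' @export
amplicon_design <- function(taxa, n_amplicons = 3, n_asvs_per_taxon = 1,
                            detection_prob = 1, efficiency_sd = 0.3,
                            depth_mean = 1e4, depth_dispersion = 5, seed = 1) {
  check_that(n_amplicons >= 1, "need at least one amplicon")
  n_t <- nrow(taxa)
  dp <- rep_len(detection_prob, n_t)
  with_seed(seed, {
    amps <- vector("list", n_amplicons)
    for (a in seq_len(n_amplicons)) {
      detected <- runif(n_t) < dp
      eff <- exp(rnorm(n_t, 0, efficiency_sd))
      nasv <- if (is.function(n_asvs_per_taxon)) n_asvs_per_taxon(n_t)
              else rep_len(n_asvs_per_taxon, n_t)
      nasv[!detected] <- 0L
      asv <- NULL
      cnt <- 0L
      for (t in seq_len(n_t)) {
        if (nasv[t] < 1) next
        w <- rgamma(nasv[t], shape = 5)
        prop <- w / sum(w)
        ids <- sprintf("A%02d_ASV%04d", a, cnt + seq_len(nasv[t]))
        cnt <- cnt + nasv[t]
        asv <- rbind(asv, data.frame(asv_id = ids, taxon_id = taxa$taxon_id[t],
                                     proportion = prop, stringsAsFactors = FALSE))
      }
      amps[[a]] <- list(amplicon_id = sprintf("amp%02d", a), detected = detected,
                        efficiency = eff, asv = asv)
    }
    structure(list(amplicons = amps, depth_mean = depth_mean,
                   depth_dispersion = depth_dispersion, taxa = taxa),
              class = "amplicon_design")
  })
}

#' Render multi-amplicon ASV count tables from a latent community
#'
#' For every amplicon and sample, reads are drawn multinomially with
#' probabilities proportional to latent abundance times amplification
#' efficiency, split across a taxon's ASVs by the design's fixed
#' proportions. The ground-truth ASV-to-taxon map is always returned so
#' cASV recovery can be scored.
#'
#' @param latent a `latent_community`.
#' @param design an `amplicon_design` built on the same taxa.
#' @param seed integer RNG seed (depths and multinomial draws).
#' @return list with `tables` (one samples x ASVs integer matrix per
#'   amplicon, named by amplicon id), `truth` (asv_id, amplicon_id,
#'   taxon_id, genus, component) and `taxonomy` (per-ASV ranks
#'   domain..genus).
#' @export
render_amplicons <- function(latent, design, seed = 1) {
  check_that(inherits(latent, "latent_community"), "latent must be a latent_community")
  check_that(inherits(design, "amplicon_design"), "design must be an amplicon_design")
  check_that(identical(design$taxa$taxon_id, latent$taxa$taxon_id),
             "design and latent community must share the same taxa")
  ab <- latent$abundance
  n_s <- nrow(ab)
  with_seed(seed, {
    tables <- list()
    truth <- NULL
    for (amp in design$amplicons) {
      if (is.null(amp$asv)) next
      t_idx <- match(amp$asv$taxon_id, colnames(ab))
      # per-ASV unnormalised read probability: abundance x efficiency x split
      p <- sweep(ab[, t_idx, drop = FALSE], 2,
                 amp$efficiency[t_idx] * amp$asv$proportion, `*`)
      depth <- rnbinom(n_s, mu = design$depth_mean, size = design$depth_dispersion)
      cts <- matrix(0L, n_s, nrow(amp$asv),
                    dimnames = list(rownames(ab), amp$asv$asv_id))
      for (s in seq_len(n_s)) {
        tot <- sum(p[s, ])
        if (tot <= 0) {
          warning(sprintf("sample %s has zero total abundance in %s; all-zero row",
                          rownames(ab)[s], amp$amplicon_id))
          next
        }
        if (depth[s] > 0)
          cts[s, ] <- as.integer(rmultinom(1, depth[s], p[s, ] / tot))
      }
      attr(cts, "amplicon_id") <- amp$amplicon_id
      tables[[amp$amplicon_id]] <- cts
      truth <- rbind(truth, data.frame(
        asv_id = amp$asv$asv_id, amplicon_id = amp$amplicon_id,
        taxon_id = amp$asv$taxon_id,
        genus = latent$taxa$genus[match(amp$asv$taxon_id, latent$taxa$taxon_id)],
        component = latent$taxa$component[match(amp$asv$taxon_id, latent$taxa$taxon_id)],
        stringsAsFactors = FALSE))
    }
    list(tables = tables, truth = truth, taxonomy = truth_to_taxonomy(truth))
  })
}

# Expand a truth map into per-ASV taxonomy ranks domain..genus.
truth_to_taxonomy <- function(truth) {
  domain <- c(bacteria = "Bacteria", fungi = "Eukarya", parasite = "Eukarya")
  kingdom <- c(bacteria = NA_character_, fungi = "Fungi", parasite = "Metazoa")
  data.frame(
    asv_id = truth$asv_id,
    domain = unname(domain[truth$component]),
    kingdom = unname(kingdom[truth$component]),
    phylum = paste0("phylum_", truth$component),
    class = paste0("class_", truth$component),
    order = paste0("order_", truth$component),
    family = paste0("family_", truth$genus),
    genus = truth$genus,
    stringsAsFactors = FALSE)
}
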