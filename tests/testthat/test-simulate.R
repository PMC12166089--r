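test_that("host simulation honours sizes, repeats and determinism", {
  a <- simulate_hosts(10, n_clans = 2, repeat_fraction = 0, seed = 1)
  expect_equal(nrow(a$metadata), 10)
  expect_equal(length(unique(a$metadata$individual_id)), 10)

  b <- simulate_hosts(10, n_clans = 2, repeat_fraction = 1, seed = 1)
  expect_true(all(table(b$metadata$individual_id) >= 2))
  # repeated samples of one individual have distinct dates
  dup <- split(b$metadata$date, b$metadata$individual_id)
  expect_true(all(vapply(dup, function(d) !anyDuplicated(d), logical(1))))

  c1 <- simulate_hosts(15, n_clans = 3, repeat_fraction = 0.5, seed = 7)
  c2 <- simulate_hosts(15, n_clans = 3, repeat_fraction = 0.5, seed = 7)
  expect_identical(c1, c2)

  expect_error(simulate_hosts(1), "n_individuals")
  expect_error(simulate_hosts(10, repeat_fraction = 1.5), "repeat_fraction")
})

test_that("host ages span juveniles and adults; ranks bounded; season rule holds", {
  s <- simulate_hosts(200, seed = 3)
  expect_true(all(s$hosts$rank >= -1 & s$hosts$rank <= 1))
  expect_true(min(s$metadata$age_days) < 730)     # juveniles present
  expect_true(max(s$metadata$age_days) > 2000)    # adults present
  m <- as.integer(format(s$metadata$date, "%m"))
  expect_identical(s$metadata$season == "dry", m >= 6 & m <= 10)
  # every mother id refers to a real individual
  mo <- s$hosts$mother_id[!is.na(s$hosts$mother_id)]
  expect_true(all(mo %in% s$hosts$individual_id))
})

test_that("immune measures are monotone in age and reproducible", {
  md <- simulate_hosts(30, seed = 2)$metadata

  flat <- simulate_immune(md, age_slope = 0, noise_sd = 0, seed = 1)
  expect_equal(var(flat$f_iga), 0)
  expect_equal(var(flat$f_mucin), 0)

  up <- simulate_immune(md, age_slope = 0.5, noise_sd = 0, seed = 1)
  expect_equal(cor(up$age_days, up$f_iga, method = "spearman"), 1)
  expect_equal(cor(up$age_days, up$f_mucin, method = "spearman"), 1)

  r1 <- simulate_immune(md, seed = 9)
  r2 <- simulate_immune(md, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$f_iga >= 0 & r1$f_mucin >= 0))

  expect_error(simulate_immune(md, noise_sd = -1), "noise_sd")
})

test_that("latent community collapses to exchangeable rows under the null", {
  sim <- simulate_hosts(20, seed = 4)
  md <- simulate_immune(sim$metadata, seed = 5)
  cfg <- default_effect_config(8, sd_clan = 0, sd_season = 0, sd_indiv = 0,
                               sd_resid = 0, seed = 6)
  lat <- simulate_latent(md, sim$hosts, effect_config = cfg, seed = 7)
  expect_true(all(abs(sweep(lat$abundance, 2, lat$abundance[1, ])) < 1e-12))
})

test_that("a positive age coefficient gives strictly increasing abundance", {
  sim <- simulate_hosts(25, seed = 8)
  md <- simulate_immune(sim$metadata, seed = 9)
  cfg <- default_effect_config(5, sd_clan = 0, sd_season = 0, sd_indiv = 0,
                               sd_resid = 0, seed = 10)
  cfg$beta_age <- c(0.8, 0, 0, 0, 0)
  lat <- simulate_latent(md, sim$hosts, effect_config = cfg, seed = 11)
  o <- order(md$age_days)
  expect_true(all(diff(lat$abundance[o, 1]) > 0))
  expect_equal(var(lat$abundance[, 2]), 0)
})

test_that("immune-linked taxa make community dissimilarity track immune distance", {
  sim <- simulate_hosts(60, seed = 12)
  md <- simulate_immune(sim$metadata, age_slope = 0, noise_sd = 1, seed = 13)
  cfg <- default_effect_config(20, beta_iga = rep(c(1.5, -1.5), 10),
                               sd_clan = 0, sd_season = 0, sd_indiv = 0,
                               sd_resid = 0.3, seed = 14)
  lat <- simulate_latent(md, sim$hosts, effect_config = cfg, seed = 15)
  bc <- beta_diversity(lat$abundance, "bray")
  ut <- upper.tri(bc)
  d_iga <- abs(outer(md$f_iga, md$f_iga, `-`))
  expect_gt(cor(bc[ut], d_iga[ut], method = "spearman"), 0.3)
})

test_that("rendered counts mirror latent abundance ranks at high depth", {
  sim <- simulate_hosts(10, seed = 16)
  md <- simulate_immune(sim$metadata, seed = 17)
  cfg <- default_effect_config(12, seed = 18)
  lat <- simulate_latent(md, sim$hosts, effect_config = cfg, seed = 19)
  des <- amplicon_design(lat$taxa, n_amplicons = 1, n_asvs_per_taxon = 1,
                         efficiency_sd = 0, depth_mean = 1e6,
                         depth_dispersion = 1e6, seed = 20)
  obs <- render_amplicons(lat, des, seed = 21)
  cts <- obs$tables[[1]]
  taxon_of <- obs$truth$taxon_id[match(colnames(cts), obs$truth$asv_id)]
  ab <- lat$abundance[, taxon_of]
  rho <- vapply(seq_len(nrow(cts)), function(s)
    cor(cts[s, ], ab[s, ], method = "spearman"), numeric(1))
  expect_true(all(rho > 0.95))
})

test_that("amplicon design controls detection and ASV split proportions", {
  sim <- simulate_hosts(8, seed = 22)
  md <- simulate_immune(sim$metadata, seed = 23)
  cfg <- default_effect_config(4, seed = 24)
  lat <- simulate_latent(md, sim$hosts, effect_config = cfg, seed = 25)

  des0 <- amplicon_design(lat$taxa, n_amplicons = 1, detection_prob = 0,
                          seed = 26)
  expect_null(des0$amplicons[[1]]$asv)

  des2 <- amplicon_design(lat$taxa, n_amplicons = 1, n_asvs_per_taxon = 2,
                          seed = 27)
  prop <- des2$amplicons[[1]]$asv$proportion
  expect_equal(as.vector(tapply(prop, des2$amplicons[[1]]$asv$taxon_id, sum)),
               rep(1, 4))
  expect_true(all(prop > 0))

  # multinomial expectation: a 0.7/0.3 split shows up in the counts
  des2$amplicons[[1]]$asv$proportion <- rep(c(0.7, 0.3), 4)
  obs <- render_amplicons(lat, des2, seed = 28)
  cts <- obs$tables[[1]]
  ratio <- sum(cts[, 1]) / sum(cts[, 1] + cts[, 2])
  expect_lt(abs(ratio - 0.7), 0.05)

  # determinism and ground-truth map always present
  o1 <- render_amplicons(lat, des2, seed = 5)
  o2 <- render_amplicons(lat, des2, seed = 5)
  expect_identical(o1, o2)
  expect_true(all(c("asv_id", "amplicon_id", "taxon_id") %in%
                    colnames(o1$truth)))
  expect_setequal(o1$truth$asv_id, unlist(lapply(o1$tables, colnames)))
})
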