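test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_genes = 50, n_age_de = 40, n_behavior_genes = 20),
               "n_age_de")
  expect_error(sim_config(frac_age_up = 1.2), "frac_age_up")
  expect_error(sim_config(frac_aged_impaired = -0.1), "frac_aged_impaired")
  expect_error(sim_config(ttc_sd = 0), "ttc_sd")
  expect_error(sim_config(behavior_r = 1), "behavior_r")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
})

test_that("equal seeds reproduce identical output; different seeds differ", {
  a <- generate_counts(small_config(seed = 7))
  b <- generate_counts(small_config(seed = 7))
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  c <- generate_counts(small_config(seed = 8))
  expect_false(identical(a$counts, c$counts))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(42)
  before <- .Random.seed
  invisible(generate_counts(small_config()))
  invisible(generate_behavior(small_config()))
  invisible(generate_spikein(seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("counts are nonnegative integers with NB overdispersion", {
  sim <- generate_counts(small_config())
  expect_type(sim$counts, "integer")
  expect_true(all(sim$counts >= 0))
  # overdispersion: pooled variance/mean ratio across high-count null rows
  null_rows <- setdiff(rownames(sim$counts),
                       c(sim$truth$age_de$gene_id, sim$truth$behavior$gene_id))
  m <- sim$counts[null_rows, ]
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  hi <- mu > 50
  expect_gt(mean(v[hi] / mu[hi]), 1.5)
})

test_that("planted age genes shift by the configured log2 fold change", {
  cfg <- sim_config(n_genes = 400, n_age_de = 100, n_behavior_genes = 0,
                    age_lfc = 2, frac_age_up = 0.5, libsize_spread = 0,
                    nb_dispersion = 0.05, mean_log_expr = 8, seed = 11)
  sim <- generate_counts(cfg)
  aged <- sim$samples$age_group == "aged"
  lfc <- log2(rowMeans(sim$counts[, aged]) + 1) -
    log2(rowMeans(sim$counts[, !aged]) + 1)
  planted <- sim$truth$age_de
  up <- planted$gene_id[planted$sign == 1]
  dn <- planted$gene_id[planted$sign == -1]
  expect_equal(mean(lfc[up]), 2, tolerance = 0.15)
  expect_equal(mean(lfc[dn]), -2, tolerance = 0.15)
  expect_equal(mean(lfc[setdiff(rownames(sim$counts), planted$gene_id)]),
               0, tolerance = 0.1)
})

test_that("planted behavior genes reach the target correlation on average", {
  cfg <- sim_config(n_genes = 500, n_age_de = 0, n_behavior_genes = 200,
                    behavior_r = 0.7, libsize_spread = 0, seed = 5)
  sim <- generate_counts(cfg)
  aged <- sim$samples$age_group == "aged"
  ttc <- sim$samples$set_shift_ttc[aged]
  lg <- log2(sim$counts[sim$truth$behavior$gene_id, aged] + 1)
  r <- apply(lg, 1, cor, y = ttc) * sim$truth$behavior$sign
  expect_equal(mean(r), 0.7, tolerance = 0.05)
})

test_that("with no planted effects the screens are null-calibrated", {
  sim <- generate_counts(null_config(seed = 3, n_genes = 2000))
  nm <- normalize_counts(filter_low_counts(sim$counts), log2 = TRUE)
  scr <- age_screen(nm, age_factor(sim$samples), alpha = 0.025)
  # binomial tolerance: 3 SE around 2.5%
  se <- sqrt(0.025 * 0.975 / nrow(scr))
  expect_lt(abs(mean(scr$significant) - 0.025), 4 * se)
  # zero effect size: planted set indistinguishable from null
  cfg0 <- sim_config(n_genes = 1000, n_age_de = 100, age_lfc = 0,
                     n_behavior_genes = 0, seed = 4)
  sim0 <- generate_counts(cfg0)
  nm0 <- normalize_counts(sim0$counts, log2 = TRUE)
  scr0 <- age_screen(nm0, age_factor(sim0$samples), alpha = 0.025)
  hit <- mean(scr0$significant[scr0$gene_id %in% sim0$truth$age_de$gene_id])
  expect_lt(hit, 0.1)
})

test_that("behavior table structure and mixture control behave as configured", {
  cfg <- small_config()
  beh <- generate_behavior(cfg)
  expect_equal(nrow(beh), cfg$n_young + cfg$n_aged)
  expect_true(all(beh$set_shift_ttc >= 8))
  expect_true(all(abs(beh$discrimination_index) <= 1))
  expect_true(all(is.na(beh$ttc_class[beh$age_group == "young"])))
  expect_true(all(beh$ttc_class[beh$age_group == "aged"] %in% c("AI", "AU")))

  # frac_aged_impaired = 0: aged and young TTC share a mean in expectation
  cfg0 <- sim_config(n_young = 200, n_aged = 200, n_genes = 10, n_age_de = 0, n_behavior_genes = 0,
                     ttc_young_mean = 30, ttc_au_mean = 30,
                     frac_aged_impaired = 0, seed = 2)
  b0 <- generate_behavior(cfg0)
  expect_equal(mean(b0$set_shift_ttc[b0$age_group == "aged"]),
               mean(b0$set_shift_ttc[b0$age_group == "young"]),
               tolerance = 0.1)

  # frac_aged_impaired = 1 with a large AI mean: group gap ~ mean gap
  cfg1 <- sim_config(n_young = 300, n_aged = 300, n_genes = 10, n_age_de = 0, n_behavior_genes = 0,
                     ttc_young_mean = 30, ttc_ai_mean = 90, ttc_sd = 5,
                     frac_aged_impaired = 1, seed = 2)
  b1 <- generate_behavior(cfg1)
  gap <- mean(b1$set_shift_ttc[b1$age_group == "aged"]) -
    mean(b1$set_shift_ttc[b1$age_group == "young"])
  expect_equal(gap, 60, tolerance = 2)
})

test_that("mean-split recovery approaches the analytic Bayes accuracy", {
  # oracle: optimal threshold for N(35,10) vs N(75,10) at equal weights is
  # the midpoint 55; Bayes accuracy = pnorm((75-55)/10) = pnorm(2)
  bayes <- pnorm(2)
  cfg <- sim_config(n_young = 2, n_aged = 400, n_genes = 10, n_age_de = 0, n_behavior_genes = 0,
                    ttc_au_mean = 35, ttc_ai_mean = 75, ttc_sd = 10,
                    frac_aged_impaired = 0.5, seed = 9)
  beh <- generate_behavior(cfg)
  aged <- beh[beh$age_group == "aged", ]
  lab <- mean_split(aged$set_shift_ttc, aged$animal_id)
  acc <- mean(lab$label == aged$ttc_class)
  expect_gt(acc, 0.5)            # above chance
  expect_gt(acc, bayes - 0.05)   # near the Bayes bound for this mixture
})

test_that("spike-in tables are log-linear with noise-controlled fit", {
  clean <- generate_spikein(n_transcripts = 92, noise_sd = 0, seed = 1)
  expect_equal(nrow(clean), 92)
  expect_gt(diff(range(log10(clean$expected_concentration))), 4)
  expect_equal(spikein_qc(clean)$r_squared, 1.0, tolerance = 1e-12)

  # R^2 decreases monotonically with noise, averaged over seeds
  mean_r2 <- function(noise) {
    mean(vapply(1:8, function(s) {
      spikein_qc(generate_spikein(92, noise, seed = s))$r_squared
    }, numeric(1)))
  }
  r2 <- vapply(c(0.05, 0.3, 1), mean_r2, numeric(1))
  expect_true(all(diff(r2) < 0))
})

test_that("qPCR generator plants recoverable fold changes", {
  # exact recovery with no noise: fold 2 puts the target exactly one
  # cycle lower in the treated group
  ct0 <- generate_qpcr(c(Targ = 2), n_per_group = 4, ct_sd = 0, seed = 1)
  trt <- ct0$ct[ct0$gene == "Targ" & ct0$group == "treated"]
  ctl <- ct0$ct[ct0$gene == "Targ" & ct0$group == "control"]
  expect_equal(unique(ctl) - unique(trt), 1)

  # all folds 1: relative expression ~ 1 everywhere
  ct1 <- generate_qpcr(c(A = 1, B = 1), n_per_group = 6, ct_sd = 0.05, seed = 2)
  rel <- delta_delta_ct(ct1, "Gapdh", "control")
  expect_equal(mean(rel$fold), 1, tolerance = 0.05)

  # the published AI-vs-AU fold for Arc (1.89) is recovered within 5%
  # averaged over 100 seeds
  est <- vapply(1:100, function(s) {
    ct <- generate_qpcr(c(Arc = 1.89), n_per_group = 6, ct_sd = 0.1, seed = s)
    rel <- delta_delta_ct(ct, "Gapdh", "control")
    mean(rel$fold[rel$group == "treated"])
  }, numeric(1))
  expect_equal(mean(est), 1.89, tolerance = 1.89 * 0.05)

  expect_error(generate_qpcr(c(A = -2)), "fold")
})
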