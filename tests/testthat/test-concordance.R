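test_that("gene matching is case-insensitive and restricted to the detected universe", {
  prior <- direction_set(c("SST", "GFAP", "Missing", "Arc"),
                         c("down", "up", "up", "up"), name = "prior-study")
  detected <- c("Sst", "gfap", "Arc", "Other")
  matched <- match_genes(prior, detected)
  expect_equal(nrow(matched), 3)
  expect_setequal(matched$gene_id, c("Sst", "gfap", "Arc"))
  expect_equal(matched$direction[matched$key == "sst"], -1)
  expect_warning(match_genes(direction_set("Nope", "up"), detected),
                 "no prior genes matched")
})

test_that("direction agreement counts signs against the prior and ties disagree", {
  prior <- direction_set(c("g001", "g002", "g003", "g004"),
                         c("up", "up", "down", "down"))
  m <- exact_mean_matrix(young_mean = c(10, 10, 10, 10),
                         aged_mean = c(20, 5, 5, 10))  # up, down, down, tie
  grp <- factor(rep(c("young", "aged"), each = 3), levels = c("young", "aged"))
  matched <- match_genes(prior, m)
  agr <- direction_agreement(matched, m, grp)
  expect_equal(agr$T, 4)
  expect_equal(agr$n_same, 2)  # g001 agrees up, g003 agrees down; tie disagrees
  expect_equal(agr$percent_same, 50)
})

test_that("chi-square against chance matches the closed form", {
  # closed form oracle: 2 * (n_same - T/2)^2 / (T/2)
  expect_equal(chi_square_direction(159, 318)$chi2, 0)
  expect_equal(chi_square_direction(159, 318)$p, 1)
  expect_equal(chi_square_direction(203, 318)$chi2, 24.35, tolerance = 0.005)
  expect_equal(chi_square_direction(318, 318)$chi2, 318)
  set.seed(77)
  for (i in 1:200) {
    T <- sample(2:500, 1)
    n_same <- sample(0:T, 1)
    out <- chi_square_direction(n_same, T)
    expect_equal(out$chi2, 2 * (n_same - T / 2)^2 / (T / 2),
                 tolerance = 1e-10)
    expect_equal(out$p, pchisq(out$chi2, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(chi_square_direction(1, 0), "T")
})

test_that("chi-square evidence direction agrees with the exact binomial on small T", {
  # brute-force oracle on all instances with T <= 30: the chi-square is
  # small (p high) exactly when the binomial split is near 50:50
  for (T in c(5, 12, 30)) {
    chi_p <- vapply(0:T, function(k) chi_square_direction(k, T)$p, numeric(1))
    bin_p <- vapply(0:T, function(k) binom.test(k, T, 0.5)$p.value, numeric(1))
    devs <- abs(0:T - T / 2)
    # both p-values decrease as the split departs from 50:50
    expect_true(all(diff(chi_p[order(devs)]) <= 1e-12))
    expect_true(all(diff(bin_p[order(devs)]) <= 1e-12))
    # and therefore rank the instances identically
    expect_equal(order(chi_p, devs), order(bin_p, devs))
  }
})

test_that("expected-direction FDR arithmetic and its monotonicity", {
  # reported at printed precision with conventional half-up rounding
  expect_equal(round_half_up(expected_direction_fdr(318, 0.05, 60), 2), 0.27)
  expect_equal(round_half_up(expected_direction_fdr(26, 0.05, 16), 2), 0.08)
  expect_true(is.na(expected_direction_fdr(318, 0.05, 0)))
  # fdr = 1 exactly at n_sig = T * alpha, strictly decreasing in n_sig
  expect_equal(expected_direction_fdr(200, 0.05, 10), 1)
  fdrs <- vapply(1:50, function(k) expected_direction_fdr(200, 0.05, k),
                 numeric(1))
  expect_true(all(diff(fdrs) < 0))
})

test_that("directed tests assemble the full report with one-tailed pooled t-tests", {
  cfg <- sim_config(n_genes = 300, n_age_de = 60, n_behavior_genes = 0,
                    age_lfc = 1.5, frac_age_up = 0.5, seed = 31)
  sim <- generate_counts(cfg)
  nm <- normalize_counts(filter_low_counts(sim$counts), log2 = TRUE)
  grp <- age_factor(sim$samples)
  # prior predicting the planted directions
  planted <- sim$truth$age_de[sim$truth$age_de$gene_id %in% rownames(nm$values), ]
  prior <- direction_set(planted$gene_id,
                         ifelse(planted$sign == 1, "up", "down"),
                         name = "planted")
  matched <- match_genes(prior, nm)
  rep <- directed_tests(matched, nm, grp, alpha = 0.05)
  expect_s3_class(rep, "concordance_report")
  expect_equal(rep$T, nrow(matched))
  expect_gt(rep$percent_same, 90)
  expect_equal(rep$n_sig, rep$n_sig_up + rep$n_sig_down)
  expect_gt(rep$n_sig / rep$T, 0.8)
  expect_equal(rep$fdr, rep$T * 0.05 / rep$n_sig)
  expect_lt(rep$fdr, 0.1)

  # one-tailed p against cor oracle for one gene
  g <- matched$gene_id[1]
  tt <- t.test(nm$values[g, grp == "aged"], nm$values[g, grp == "young"],
               var.equal = TRUE, alternative =
                 if (matched$direction[1] == 1) "greater" else "less")
  expect_equal(rep$genes$p_one_tailed[1], tt$p.value, tolerance = 1e-12)

  # predicted-direction p plus opposite-direction p sum to one
  flipped <- matched
  flipped$direction <- -flipped$direction
  rep2 <- directed_tests(flipped, nm, grp, alpha = 0.05)
  expect_equal(rep$genes$p_one_tailed + rep2$genes$p_one_tailed,
               rep(1, rep$T), tolerance = 1e-12)
})

test_that("null priors give chance-level agreement and T*alpha significant hits", {
  hits <- 0; total <- 0; same <- 0
  for (s in 1:5) {
    sim <- generate_counts(null_config(seed = 40 + s, n_genes = 800))
    nm <- normalize_counts(filter_low_counts(sim$counts), log2 = TRUE)
    ids <- rownames(nm$values)
    set.seed(1000 + s)
    prior <- direction_set(ids, sample(c("up", "down"), length(ids),
                                       replace = TRUE))
    rep <- directed_tests(match_genes(prior, nm), nm,
                          age_factor(sim$samples), alpha = 0.05)
    hits <- hits + rep$n_sig; total <- total + rep$T
    same <- same + rep$n_same
  }
  expect_lt(abs(hits / total - 0.05), 0.015)
  expect_lt(abs(same / total - 0.5), 0.03)
})

test_that("untestable genes stay in T but cannot be significant", {
  m <- exact_mean_matrix(c(10, 10), c(14, 10), jitter = 0.2)
  m[2, ] <- 7  # zero variance in both groups
  grp <- factor(rep(c("y", "a"), each = 3), levels = c("y", "a"))
  prior <- direction_set(c("g001", "g002"), c("up", "up"))
  rep <- directed_tests(match_genes(prior, m), m, grp)
  expect_equal(rep$T, 2)
  expect_equal(rep$n_untestable, 1)
  expect_false(rep$genes$significant[rep$genes$gene_id == "g002"])
  expect_equal(rep$fdr, 2 * 0.05 / rep$n_sig)
})
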