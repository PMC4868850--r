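#' Simulation configuration for synthetic study data
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the design of the motivating study: 11 young and 20 aged rats,
#' a GO-annotated gene universe of roughly 15,000 genes per region, several
#' hundred genes shifted with age (immune-type genes up, synaptic-type genes
#' down), several hundred genes linearly correlated with the aged animals'
#' set-shift trials-to-criterion (TTC) score, and aged TTC drawn from an
#' impaired/unimpaired two-component mixture whose overall mean sits near
#' the published aged mean split of 51.7 trials.
#'
#' @param n_young,n_aged Number of young and aged animals.
#' @param n_genes Number of genes in the simulated universe.
#' @param n_age_de Number of genes planted with an age effect.
#' @param age_lfc Magnitude of the planted age effect, log2 fold change.
#' @param frac_age_up Fraction of planted age genes shifted upward in aged
#'   animals (the remainder shift down).
#' @param n_behavior_genes Number of genes planted to correlate with the
#'   aged animals' set-shift TTC score.
#' @param behavior_r Target Pearson correlation magnitude between a planted
#'   behavior gene's log2 expression and TTC, in (-1, 1).
#' @param frac_behavior_up Fraction of behavior genes with positive planted
#'   correlation (expression increasing with impairment).
#' @param nb_dispersion Negative-binomial dispersion phi, so that
#'   Var = mu + phi * mu^2. Zero gives Poisson counts.
#' @param mean_log_expr,sd_log_expr Mean and sd of the baseline per-gene
#'   log2 expression level (log-normal baseline means).
#' @param libsize_spread Standard deviation (log2 scale) of multiplicative
#'   per-sample library-size factors; 0 gives equal library sizes.
#' @param ttc_young_mean Mean set-shift TTC for young animals.
#' @param ttc_au_mean,ttc_ai_mean Mean TTC of the aged-unimpaired and
#'   aged-impaired subpopulations.
#' @param ttc_sd Within-component TTC standard deviation.
#' @param frac_aged_impaired Mixing weight of the impaired component.
#' @param integerize_ttc If TRUE, TTC values are rounded to whole trials
#'   (still floored at 8, the eight-consecutive-correct criterion).
#' @param seed Integer seed; identical configurations with identical seeds
#'   reproduce byte-identical output.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @seealso [generate_counts()], [generate_behavior()]
#' @export
sim_config <- function(n_young = 11, n_aged = 20, n_genes = 15000,
                       n_age_de = 700, age_lfc = 1, frac_age_up = 0.47,
                       n_behavior_genes = 400, behavior_r = 0.7,
                       frac_behavior_up = 0.73, nb_dispersion = 0.1,
                       mean_log_expr = 5, sd_log_expr = 2,
                       libsize_spread = 0.2,
                       ttc_young_mean = 30, ttc_au_mean = 35,
                       ttc_ai_mean = 75, ttc_sd = 10,
                       frac_aged_impaired = 0.5,
                       integerize_ttc = FALSE, seed = 1L) {
  cfg <- list(n_young = as.integer(n_young), n_aged = as.integer(n_aged),
              n_genes = as.integer(n_genes), n_age_de = as.integer(n_age_de),
              age_lfc = age_lfc, frac_age_up = frac_age_up,
              n_behavior_genes = as.integer(n_behavior_genes),
              behavior_r = behavior_r, frac_behavior_up = frac_behavior_up,
              nb_dispersion = nb_dispersion, mean_log_expr = mean_log_expr,
              sd_log_expr = sd_log_expr, libsize_spread = libsize_spread,
              ttc_young_mean = ttc_young_mean, ttc_au_mean = ttc_au_mean,
              ttc_ai_mean = ttc_ai_mean, ttc_sd = ttc_sd,
              frac_aged_impaired = frac_aged_impaired,
              integerize_ttc = isTRUE(integerize_ttc),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < min) {
      stop_param(field, sprintf("must be a single integer >= %d", min))
    }
  }
  chk_count("n_young", 1L); chk_count("n_aged", 2L)
  chk_count("n_genes", 1L); chk_count("n_age_de", 0L)
  chk_count("n_behavior_genes", 0L)
  if (cfg$n_age_de + cfg$n_behavior_genes > cfg$n_genes) {
    stop_param("n_age_de", "planted gene sets must fit inside n_genes")
  }
  chk_unit <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_param(field, "must lie in [0, 1]")
    }
  }
  chk_unit("frac_age_up"); chk_unit("frac_aged_impaired")
  chk_unit("frac_behavior_up")
  if (abs(cfg$behavior_r) >= 1) stop_param("behavior_r", "must lie in (-1, 1)")
  if (cfg$nb_dispersion < 0) stop_param("nb_dispersion", "must be >= 0")
  if (cfg$sd_log_expr <= 0) stop_param("sd_log_expr", "must be > 0")
  if (cfg$libsize_spread < 0) stop_param("libsize_spread", "must be >= 0")
  if (cfg$ttc_sd <= 0) stop_param("ttc_sd", "must be > 0")
  if (cfg$age_lfc < 0) stop_param("age_lfc", "must be >= 0")
  invisible(cfg)
}

#' Simulate per-animal behavioral scores
#'
#' Draws set-shift and visual-discrimination trials-to-criterion (TTC),
#' water-maze block-5 path lengths, platform crossings, and the probe-trial
#' discrimination index for every animal. Young TTC is normal, truncated
#' below at 8 trials (the task criterion is eight consecutive correct
#' responses); aged TTC comes from an impaired/unimpaired (AI/AU) Gaussian
#' mixture. The latent AI/AU label is returned in \code{ttc_class} so that
#' classification procedures can be scored against ground truth. The
#' spatial block-5 path length is generated with a negative dependence on
#' the discrimination index, mirroring the observed coupling between poor
#' probe performance and long spatial-search paths.
#'
#' @param config A [sim_config()] object.
#' @param region Region label recorded for every sample.
#' @return A data frame (one row per animal) with columns \code{sample_id},
#'   \code{animal_id}, \code{region}, \code{age_group}, \code{set_shift_ttc},
#'   \code{visual_ttc}, \code{cue_block5}, \code{spatial_block5},
#'   \code{crossings}, \code{discrimination_index} and the latent
#'   \code{ttc_class} (\code{NA} for young animals).
#' @export
generate_behavior <- function(config, region = "mPFC") {
  validate_sim_config(config)
  n_y <- config$n_young
  n_a <- config$n_aged
  with_seed(config$seed, {
    ttc_young <- rtnorm(n_y, config$ttc_young_mean, config$ttc_sd, lower = 8)
    impaired <- stats::runif(n_a) < config$frac_aged_impaired
    ttc_aged <- numeric(n_a)
    ttc_aged[impaired] <- rtnorm(sum(impaired), config$ttc_ai_mean,
                                 config$ttc_sd, lower = 8)
    ttc_aged[!impaired] <- rtnorm(sum(!impaired), config$ttc_au_mean,
                                  config$ttc_sd, lower = 8)
    n <- n_y + n_a
    visual <- rtnorm(n, 30, 10, lower = 8)
    di <- rtnorm(n, 0.3, 0.2, lower = -1, upper = 1)
    cue <- rtnorm(n, 300, 80, lower = 0)
    spatial <- pmax(0, 400 - 150 * di + stats::rnorm(n, 0, 55))
    crossings <- rtnorm(n, 3, 1.5, lower = 0)
    ttc <- c(ttc_young, ttc_aged)
    if (config$integerize_ttc) ttc <- pmax(8, round(ttc))
    ids <- c(sprintf("Y%02d", seq_len(n_y)), sprintf("A%02d", seq_len(n_a)))
    data.frame(
      sample_id = ids,
      animal_id = ids,
      region = region,
      age_group = rep(c("young", "aged"), c(n_y, n_a)),
      set_shift_ttc = ttc,
      visual_ttc = if (config$integerize_ttc) pmax(8, round(visual)) else visual,
      cue_block5 = cue,
      spatial_block5 = spatial,
      crossings = crossings,
      discrimination_index = di,
      ttc_class = c(rep(NA_character_, n_y),
                    ifelse(impaired, "AI", "AU")),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a count matrix with planted age and behavior effects
#'
#' Generates negative-binomial gene-level counts for young and aged
#' animals. Baseline per-gene log2 means are normal with location
#' \code{mean_log_expr}; per-sample library-size factors are log-normal
#' with spread \code{libsize_spread}. The first \code{n_age_de} genes are
#' shifted by \code{age_lfc} log2 units in aged animals (a configurable
#' fraction upward); the next \code{n_behavior_genes} genes receive, in
#' aged animals only, an additive log2 term proportional to the
#' standardized set-shift TTC score. The proportionality constant is
#' solved per gene from the target correlation \code{behavior_r} and the
#' delta-method variance of log2 negative-binomial noise, so the expected
#' observed correlation (after count noise) is approximately
#' \code{behavior_r}.
#'
#' @param config A [sim_config()] object.
#' @param region Region label passed through to the sample table.
#' @return A list with components \code{counts} (integer matrix, genes x
#'   samples), \code{samples} (the [generate_behavior()] table) and
#'   \code{truth} (a \code{ground_truth} list: \code{age_de} and
#'   \code{behavior} data frames of planted gene ids and signs,
#'   \code{true_size_factors}, \code{ttc_class}).
#' @export
generate_counts <- function(config, region = "mPFC") {
  validate_sim_config(config)
  samples <- generate_behavior(config, region = region)
  n <- nrow(samples)
  aged <- samples$age_group == "aged"
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))

  with_seed(config$seed + 1L, {
    mu0 <- stats::rnorm(config$n_genes, config$mean_log_expr,
                        config$sd_log_expr)
    log2mu <- matrix(mu0, nrow = config$n_genes, ncol = n)

    # planted age effects: first block of genes, sign split by frac_age_up
    age_idx <- seq_len(config$n_age_de)
    n_up <- round(config$frac_age_up * config$n_age_de)
    age_sign <- rep(c(1, -1), c(n_up, config$n_age_de - n_up))
    if (config$n_age_de > 0L) {
      log2mu[age_idx, aged] <- log2mu[age_idx, aged] +
        age_sign * config$age_lfc
    }

    # planted behavior correlation: next block, coupled to standardized TTC
    beh_idx <- seq_len(config$n_behavior_genes) + config$n_age_de
    n_bup <- round(config$frac_behavior_up * config$n_behavior_genes)
    beh_sign <- rep(c(1, -1), c(n_bup, config$n_behavior_genes - n_bup))
    if (config$n_behavior_genes > 0L) {
      z_ttc <- as.numeric(scale(samples$set_shift_ttc[aged]))
      # delta-method variance of log2(NB) noise at the gene's baseline mean
      v_noise <- (1 / 2^mu0[beh_idx] + config$nb_dispersion) / log(2)^2
      beta <- sqrt(config$behavior_r^2 * v_noise / (1 - config$behavior_r^2))
      log2mu[beh_idx, aged] <- log2mu[beh_idx, aged] +
        (beta * beh_sign) %o% z_ttc
    }

    sf <- 2^stats::rnorm(n, 0, config$libsize_spread)
    if (config$libsize_spread > 0) sf <- sf / exp(mean(log(sf)))
    mu_lin <- sweep(2^log2mu, 2, sf, `*`)

    counts <- if (config$nb_dispersion > 0) {
      stats::rnbinom(length(mu_lin), mu = mu_lin,
                     size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(length(mu_lin), mu_lin)
    }
    counts <- matrix(pmin(counts, .Machine$integer.max), nrow = config$n_genes,
                     dimnames = list(gene_ids, samples$sample_id))
    storage.mode(counts) <- "integer"

    truth <- structure(list(
      age_de = data.frame(gene_id = gene_ids[age_idx],
                          sign = age_sign,
                          stringsAsFactors = FALSE),
      behavior = data.frame(gene_id = gene_ids[beh_idx],
                            sign = beh_sign,
                            stringsAsFactors = FALSE),
      true_size_factors = stats::setNames(sf, samples$sample_id),
      ttc_class = stats::setNames(samples$ttc_class[aged],
                                  samples$sample_id[aged])
    ), class = "ground_truth")

    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Simulate a spike-in control table
#'
#' Expected concentrations span several orders of magnitude on a log10
#' grid (92 transcripts mirrors the standard external-control mix);
#' observed counts are linear in log10 concentration with Gaussian noise
#' of sd \code{noise_sd} on the log10 scale.
#'
#' @param n_transcripts Number of spike-in transcripts (>= 1).
#' @param noise_sd Log10-scale noise standard deviation.
#' @param seed Integer seed.
#' @return A data frame with columns \code{transcript_id},
#'   \code{expected_concentration}, \code{observed_count}.
#' @export
generate_spikein <- function(n_transcripts = 92, noise_sd = 0.1, seed = 1L) {
  if (n_transcripts < 1L) stop_param("n_transcripts", "must be >= 1")
  if (noise_sd < 0) stop_param("noise_sd", "must be >= 0")
  with_seed(seed, {
    expected <- 10^seq(-2, 4, length.out = n_transcripts)
    observed <- 10^(1 + log10(expected) +
                      stats::rnorm(n_transcripts, 0, noise_sd))
    data.frame(
      transcript_id = sprintf("ERCC-%05d", seq_len(n_transcripts)),
      expected_concentration = expected,
      observed_count = observed,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a qPCR CT table with known fold changes
#'
#' CT values follow CT = baseline - log2(expression) + noise, so a gene
#' with fold change f in the treated group sits log2(f) cycles lower
#' there. The reference gene (fold 1) is group-invariant in expectation,
#' emulating a stable housekeeping control.
#'
#' @param fold_changes Named positive numeric vector of treated/control
#'   fold changes, one per target gene. The reference gene is appended
#'   with fold 1 if absent.
#' @param n_per_group Samples per group.
#' @param ct_sd Per-well CT noise sd (cycles).
#' @param seed Integer seed.
#' @param reference_gene Name of the reference (housekeeping) gene.
#' @param group_labels Labels for the control and treated groups, in that
#'   order.
#' @return A long data frame with columns \code{sample_id}, \code{group},
#'   \code{gene}, \code{ct}.
#' @export
generate_qpcr <- function(fold_changes, n_per_group = 6, ct_sd = 0.2,
                          seed = 1L, reference_gene = "Gapdh",
                          group_labels = c("control", "treated")) {
  if (length(fold_changes) == 0L || is.null(names(fold_changes))) {
    stop_param("fold_changes", "must be a named numeric vector")
  }
  if (any(fold_changes <= 0)) {
    bad <- names(fold_changes)[which(fold_changes <= 0)[1L]]
    stop_param("fold_changes", sprintf("fold for '%s' must be > 0", bad))
  }
  if (!reference_gene %in% names(fold_changes)) {
    fold_changes <- c(fold_changes, stats::setNames(1, reference_gene))
  } else if (fold_changes[[reference_gene]] != 1) {
    stop_param("fold_changes", "reference gene must have fold change 1")
  }
  genes <- names(fold_changes)
  with_seed(seed, {
    baseline <- stats::setNames(stats::runif(length(genes), 18, 26), genes)
    grid <- expand.grid(rep_within = seq_len(n_per_group),
                        group = group_labels, gene = genes,
                        stringsAsFactors = FALSE)
    shift <- ifelse(grid$group == group_labels[2L],
                    log2(fold_changes[grid$gene]), 0)
    data.frame(
      sample_id = sprintf("%s_%02d", grid$group, grid$rep_within),
      group = grid$group,
      gene = grid$gene,
      ct = baseline[grid$gene] - shift +
        stats::rnorm(nrow(grid), 0, ct_sd),
      stringsAsFactors = FALSE
    )
  })
}
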