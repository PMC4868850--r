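# Shared fixture builders. Everything is generated in code; no files.

# A small but fully featured simulation: planted age and behavior genes,
# library-size spread, NB dispersion.
small_config <- function(seed = 1L, ...) {
  sim_config(n_genes = 600, n_age_de = 40, n_behavior_genes = 40,
             seed = seed, ...)
}

# Null configuration: no planted effects.
null_config <- function(seed = 1L, n_genes = 1000, ...) {
  sim_config(n_genes = n_genes, n_age_de = 0, n_behavior_genes = 0,
             seed = seed, ...)
}

# Tiny deterministic count matrix.
toy_counts <- function() {
  m <- matrix(c(10L, 20L, 30L,
                5L, 10L, 15L,
                0L, 0L, 0L,
                100L, 200L, 300L),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  m
}

age_factor <- function(samples) {
  factor(samples$age_group, levels = c("young", "aged"))
}

aged_scores <- function(samples, measure = "set_shift_ttc") {
  ifelse(samples$age_group == "aged", samples[[measure]], NA_real_)
}

# Expression matrix with exact group means and no noise: gene i has mean
# young_mean[i] in young columns, aged_mean[i] in aged columns, with a
# fixed within-group perturbation so variances are nonzero.
exact_mean_matrix <- function(young_mean, aged_mean, n_young = 3, n_aged = 3,
                              jitter = 0.1) {
  stopifnot(length(young_mean) == length(aged_mean))
  g <- length(young_mean)
  pat_y <- seq(-jitter, jitter, length.out = n_young)
  pat_a <- seq(-jitter, jitter, length.out = n_aged)
  m <- cbind(outer(young_mean, rep(1, n_young)) + rep(pat_y, each = g),
             outer(aged_mean, rep(1, n_aged)) + rep(pat_a, each = g))
  dimnames(m) <- list(sprintf("g%03d", seq_len(g)),
                      c(paste0("Y", seq_len(n_young)),
                        paste0("A", seq_len(n_aged))))
  m
}
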