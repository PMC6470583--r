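# Shared fixtures. The large synthetic bundle is expensive, so it is built
# once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# 2000-family bundle at the generator's default rates, used by the
# parameter-recovery and calibration tests
shared_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    cfg <- generator_config(seed = 11, n_genes = 4200, n_families = 2000,
                            rho_epigenome = 0.4)
    .fixture_cache$bundle <- simulate_te_dataset(cfg)
  }
  .fixture_cache$bundle
}

shared_env <- function() {
  if (is.null(.fixture_cache$env)) {
    b <- shared_bundle()
    env <- te_environment(b$genes, b$tes, chrom_sizes = b$chrom_sizes)
    env <- assign_categories(env, fit_category_model(env))
    .fixture_cache$env <- env
  }
  .fixture_cache$env
}

# printed category marginals of the duplicated genes and the 15-cell
# pair-context counts of the published analysis (canonical lower-triangle,
# row-wise cell order)
published_marginals <- function() c(109, 713, 915, 729, 374)

published_pair_counts <- function() {
  c(20,
    36, 121,
    18, 220, 169,
    13, 143, 229, 110,
    2, 72, 110, 124, 33)
}

random_intervals <- function(n, chrom = "chr1", max_pos = 10000,
                             max_len = 500) {
  s <- sample.int(max_pos, n, replace = TRUE)
  genomic_intervals(chrom, s, s + sample.int(max_len, n, replace = TRUE))
}
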