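# Shared setup for the numbered analysis scripts: one desk-scale synthetic
# NCII study used consistently across all stages. Every script can be run
# from the repository root with Rscript; outputs land under results/.

library(nciiqtl)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

# Desk-scale mirror of the study design: biparental RILs crossed to two
# near-identical testers (95% shared alleles), 4 environments x 2 replicates.
study_config <- function(seed = 2026L) {
  sim_config(n_ril = 120, n_chromosomes = 5, markers_per_chrom = 60,
             map_length_cM = 150, tester_similarity = 0.95,
             n_env = 4, n_rep = 2, residual_het_rate = 0.005, seed = seed)
}

# Two synthetic traits: "PH" is tall-structured (strong additive, some
# dominance, high heritability); "GY" is heterosis-prone (dominance and
# dominance-by-dominance heavy), echoing the contrast the pipeline is
# designed to expose.
build_study <- function(cfg = study_config()) {
  st <- simulate_ncii_study(cfg)
  mks <- colnames(st$pooled$Z)
  set.seed(cfg$seed + 7)
  m <- length(mks)
  dd_pairs <- data.frame(marker1 = sample(mks, 4), marker2 = sample(mks, 4),
                         type = "dd", effect = c(5, 0.7, -0.7, 0.6),
                         stringsAsFactors = FALSE)
  # each trait mixes a polygenic background with a few major loci so that
  # the scan stage has mappable QTL on top of the kernels' signal
  spike <- function(base, at, size) { base[at] <- base[at] + size; base }
  a_ph <- spike(rnorm(m), c(40, 160, 250), c(20, -18, 16))
  a_gy <- rnorm(m)
  d_gy <- spike(rnorm(m), c(80, 220), c(22, 20))
  truths <- list(
    PH = true_genetics(mks,
                       additive = setNames(a_ph, mks),
                       dominance = setNames(rnorm(m), mks),
                       variance_targets = c(sigma2_a = 8, sigma2_d = 2,
                                            sigma2_E = 4, sigma2_GxE = 1.5,
                                            sigma2_rep = 0.5, sigma2_eps = 4)),
    GY = true_genetics(mks,
                       additive = setNames(a_gy, mks),
                       dominance = setNames(d_gy, mks),
                       epistatic_pairs = dd_pairs,
                       variance_targets = c(sigma2_a = 2, sigma2_d = 6,
                                            sigma2_dd = 3, sigma2_E = 4,
                                            sigma2_GxE = 2, sigma2_rep = 0.5,
                                            sigma2_eps = 8)))
  phen <- lapply(names(truths), function(tr)
    simulate_phenotypes(st$pooled, truths[[tr]], cfg, mu = if (tr == "PH") 180 else 120,
                        trait = tr))
  names(phen) <- names(truths)
  list(cfg = cfg, study = st, truths = truths, phen = phen)
}

# Entry means (per-genotype BLUEs across environments) for a trait.
trait_blues <- function(phen_one, ids) {
  fit <- fit_trial_model(phen_one$records)
  fit$blues[ids]
}
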