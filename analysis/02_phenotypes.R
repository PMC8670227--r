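#!/usr/bin/env Rscript
# Stage 2 — trial-level phenotype analysis: outlier razor, across-environment
# variance components and broad-sense heritability, trait summaries,
# midparent heterosis (MPH) with its own heritability, GCA/SCA decomposition
# and a path analysis of the second trait toward the first... i.e. the whole
# Table-1-style summary for the synthetic study.

source("analysis/_common.R")

dat <- build_study()
st <- dat$study
ids <- rownames(st$pooled$Z)
out <- file.path(RESULTS_DIR, "phenotypes")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

summary_rows <- list(); mph_rows <- list(); blues_by_trait <- list()
for (tr in names(dat$phen)) {
  razor <- remove_outliers(dat$phen[[tr]]$records)
  cat(sprintf("[%s] outlier razor removed %d of %d records\n", tr,
              nrow(razor$removed), nrow(dat$phen[[tr]]$records)))
  fit <- fit_trial_model(razor$records)
  s <- summarize_trait(fit$blues)
  summary_rows[[tr]] <- data.frame(
    trait = tr, min = s["min"], max = s["max"], mean = s["mean"],
    sd = s["sd"], cv = s["cv"], sigma2_G = fit$sigma2_G,
    sigma2_GxE = fit$sigma2_GxE, sigma2_eps = fit$sigma2_eps,
    n_env = fit$n_env, H2 = fit$H2, p_G = fit$p_G, p_GxE = fit$p_GxE,
    row.names = NULL)
  blues_by_trait[[tr]] <- fit$blues[ids]

  # midparent heterosis: per-environment BLUEs of hybrids and of the
  # parents, the latter simulated under the identical (rescaled) genetic
  # model — inbred parents express additive effects only
  recs <- razor$records
  env_blues <- do.call(rbind, lapply(split(recs, recs$environment), function(d) {
    b <- within_env_blue(d)
    data.frame(hybrid = names(b), environment = d$environment[1], value = b,
               row.names = NULL)
  }))
  parents <- rbind(st$ril$genotypes,
                   TC = st$testers$tester1, TM = st$testers$tester2)
  psim <- simulate_phenotypes(ril_coding(parents),
                              dat$phen[[tr]]$applied_effects, dat$cfg,
                              mu = if (tr == "PH") 180 else 120, trait = tr,
                              scale = "none")
  prec <- psim$records
  parent_blues <- do.call(rbind, lapply(split(prec, prec$environment),
    function(d) {
      b <- within_env_blue(d)
      data.frame(genotype = names(b), environment = d$environment[1],
                 value = b, row.names = NULL)
    }))
  links <- st$pooled$parent_links
  mph_tab <- build_mph_table(env_blues, links, parent_blues)
  mfit <- mph_model(data.frame(hybrid = mph_tab$hybrid,
                               environment = mph_tab$environment,
                               mph = mph_tab$mph))
  mph_rows[[tr]] <- data.frame(trait = tr, sigma2_G = mfit$sigma2_G,
                               sigma2_E = mfit$sigma2_E,
                               sigma2_eps = mfit$sigma2_eps,
                               h2_mph = mfit$h2_mph, row.names = NULL)

  # GCA/SCA on per-environment hybrid BLUEs
  gd <- merge(env_blues, links, by = "hybrid")
  gsd <- gca_sca_decompose(data.frame(ril = gd$ril, tester = gd$tester,
                                      environment = gd$environment,
                                      value = gd$value))
  cat(sprintf("[%s] SCA/GCA ratio: %.3f\n", tr, gsd$sca_gca_ratio))
}

write_table_tsv(do.call(rbind, summary_rows),
                file.path(out, "trait_summary.tsv"))
write_table_tsv(do.call(rbind, mph_rows), file.path(out, "mph_summary.tsv"))

# path analysis: which trait drives which (illustrative two-trait case)
tab <- data.frame(GY = blues_by_trait$GY, PH = blues_by_trait$PH)
pa <- correlations_and_path(tab, "GY")
write_table_tsv(data.frame(predictor = names(pa$path), path = pa$path,
                           displayed = !is.na(pa$display)),
                file.path(out, "path_coefficients.tsv"))

cat("Trait summaries written to", out, "\n")
print(do.call(rbind, summary_rows)[, c("trait", "mean", "cv", "H2")])
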