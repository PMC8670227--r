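#' End-to-end pipeline over a synthetic NCII study
#'
#' Runs the full dissection on simulated data: study simulation, phenotype
#' analysis (outlier razor, trial model, heritability, MPH), kinship
#' construction, five-kernel variance dissection, main-effect genome scan,
#' QTL interval calling, and a small genomic-prediction experiment. All
#' stage outputs and a provenance record (config, seed, package version)
#' are written as TSV/JSON under \code{out_dir}.
#'
#' @param config a \code{\link{sim_config}}; its seed drives every stage.
#' @param truth a \code{\link{true_genetics}} or NULL for a default
#'   architecture (a handful of additive and dominance QTL).
#' @param out_dir output directory (created if absent); NULL skips writing.
#' @param scan_dataset which dataset to scan ("pooled" here).
#' @param cv_repeats repeats for the prediction stage.
#' @return invisible list with the stage outputs.
#' @export
run_pipeline <- function(config = sim_config(n_ril = 100, n_chromosomes = 3,
                                             markers_per_chrom = 40),
                         truth = NULL, out_dir = NULL,
                         scan_dataset = "pooled", cv_repeats = 5) {
  study <- simulate_ncii_study(config)
  map <- study$ril$map
  if (is.null(truth)) {
    qtl_mks <- map$marker[round(seq(5, nrow(map) - 5, length.out = 3))]
    truth <- true_genetics(
      markers = map$marker,
      additive = stats::setNames(c(1, -0.8, 0.6), qtl_mks),
      dominance = stats::setNames(c(0.8, 0.5), qtl_mks[1:2]),
      variance_targets = c(sigma2_a = 1, sigma2_d = 0.5, sigma2_E = 0.5,
                           sigma2_GxE = 0.3, sigma2_rep = 0.1,
                           sigma2_eps = 1))
  }
  sim <- simulate_phenotypes(study$pooled, truth, config, mu = 10)
  razor <- remove_outliers(sim$records)
  trial <- fit_trial_model(razor$records)
  kin <- compute_kinship_set(study$pooled)
  y <- trial$blues[rownames(study$pooled$Z)]
  X <- cbind(1, study$pooled$population)
  vc <- estimate_polygenic_varcomps(y, X, kin, backend = "reml")
  K <- compose_background(kin, vc$lambda)
  wh <- whiten(y, X, K)
  scan <- scan_main_effects(wh, study$pooled$Z, study$pooled$W, map,
                            dataset = scan_dataset)
  qtls <- call_qtl_intervals(scan[scan$effect_type == "add", ],
                             lod_threshold = 2.5)
  if (nrow(qtls)) qtls <- group_pleiotropic(qtls)
  parts <- make_cv_partitions(study$pooled$parent_links, "CV2", nfolds = 2,
                              repeats = cv_repeats, seed = config$seed)
  kl <- as_kernel_list(kin)[c("a", "d")]
  cv <- run_cross_validation(y, kl, parts, model = "GS")
  out <- list(study = study, phenotypes = sim, razor = razor, trial = trial,
              kinships = kin, varcomp = vc, scan = scan, qtls = qtls,
              cv = cv, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes_tsv(study$ril$genotypes,
                        file.path(out_dir, "ril_genotypes.tsv"))
    write_table_tsv(map, file.path(out_dir, "marker_map.tsv"))
    write_table_tsv(sim$records, file.path(out_dir, "trial_records.tsv"))
    write_table_tsv(scan, file.path(out_dir, "scan_main.tsv"))
    write_table_tsv(qtls, file.path(out_dir, "qtl_calls.tsv"))
    write_table_tsv(cv$results, file.path(out_dir, "cv_results.tsv"))
    jsonlite::write_json(
      list(seed = config$seed,
           config = unclass(config),
           realized_variances = as.list(sim$realized),
           varcomp = as.list(vc$sigma2),
           heritability = trial$H2,
           package_version = as.character(utils::packageVersion("nciiqtl"))),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
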