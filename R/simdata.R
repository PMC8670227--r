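#' Simulation configuration for a synthetic NCII study
#'
#' Bundles the dimensions and rates of a simulated North Carolina Design II
#' maize study: a biparental RIL population, two elite testers that share most
#' of their parental alleles, and multi-environment replicated trials.
#' Defaults mirror the study design the package emulates: 339 RILs genotyped
#' at roughly 4,100 bin markers on 10 chromosomes (about 2,669 cM in total,
#' i.e. ~0.64 cM/bin), two testers identical at 95% of loci, and 4
#' environments with 2 replicates each.
#'
#' @param n_ril number of recombinant inbred lines.
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chrom bin markers per chromosome.
#' @param map_length_cM per-chromosome genetic map length (recycled).
#' @param tester_similarity fraction of loci at which the two testers carry
#'   the same parental allele, in [0, 1].
#' @param n_env number of environments (year-by-location combinations).
#' @param n_rep replicates nested within environment.
#' @param residual_het_rate fraction of residual heterozygous RIL calls
#'   (flagged and set missing before coding), in [0, 0.05].
#' @param seed integer seed controlling all randomness downstream.
#' @return an object of class \code{sim_config} (a named list).
#' @export
sim_config <- function(n_ril = 339, n_chromosomes = 10, markers_per_chrom = 414,
                       map_length_cM = 267, tester_similarity = 0.95,
                       n_env = 4, n_rep = 2, residual_het_rate = 0.005,
                       seed = 1L) {
  stopifnot(n_ril >= 1, n_chromosomes >= 1, markers_per_chrom >= 1,
            n_env >= 1, n_rep >= 1)
  if (any(map_length_cM < 0)) stop("map_length_cM must be non-negative")
  if (tester_similarity < 0 || tester_similarity > 1)
    stop("tester_similarity must be in [0, 1]")
  if (residual_het_rate < 0 || residual_het_rate > 0.05)
    stop("residual_het_rate must be in [0, 0.05]")
  cfg <- list(n_ril = as.integer(n_ril),
              n_chromosomes = as.integer(n_chromosomes),
              markers_per_chrom = as.integer(markers_per_chrom),
              map_length_cM = rep_len(map_length_cM, n_chromosomes),
              tester_similarity = tester_similarity,
              n_env = as.integer(n_env), n_rep = as.integer(n_rep),
              residual_het_rate = residual_het_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Build a marker map with evenly spaced bins
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame with columns marker, chrom, cM, bp. Physical positions
#'   are laid out at 1 Mb per cM purely for reporting.
#' @export
make_marker_map <- function(config) {
  maps <- lapply(seq_len(config$n_chromosomes), function(ch) {
    m <- config$markers_per_chrom
    len <- config$map_length_cM[ch]
    pos <- if (m == 1) 0 else seq(0, len, length.out = m)
    data.frame(marker = sprintf("c%d_m%d", ch, seq_len(m)),
               chrom = ch, cM = pos, bp = round(pos * 1e6),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

# One gamete-like mosaic per chromosome under a Haldane (Poisson) crossover
# process: crossover count ~ Poisson(length in Morgans), positions uniform,
# phase alternates. RILs are treated as fully inbred doubled-haploid-like
# mosaics so adjacent-marker recombinant fractions equal the Haldane map
# function of the interval directly.
.sim_chromosome_mosaic <- function(pos_cM, len_cM) {
  n_xo <- stats::rpois(1, len_cM / 100)
  start <- if (stats::runif(1) < 0.5) 1L else -1L
  if (n_xo == 0) return(rep(start, length(pos_cM)))
  xo <- sort(stats::runif(n_xo, 0, len_cM))
  phase <- start * (-1L)^(findInterval(pos_cM, xo))
  as.integer(phase)
}

#' Simulate a RIL population
#'
#' Generates \code{n_ril} recombinant inbred genomes as mosaics of the two
#' parental alleles (+1 = first parent, -1 = second parent) under a Haldane
#' crossover process along the marker map. A fraction
#' \code{residual_het_rate} of calls is flagged as residual heterozygous and
#' set missing, reflecting incomplete fixation at F11.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genotypes} (n_ril x m matrix of +1/-1/NA,
#'   dimnames set), \code{map} (marker map data.frame) and \code{n_het}
#'   (count of residual heterozygous calls flagged).
#' @export
simulate_ril_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- make_marker_map(config)
  split_idx <- split(seq_len(nrow(map)), map$chrom)
  geno <- matrix(NA_integer_, config$n_ril, nrow(map),
                 dimnames = list(sprintf("RIL%03d", seq_len(config$n_ril)),
                                 map$marker))
  for (i in seq_len(config$n_ril)) {
    for (ch in seq_along(split_idx)) {
      idx <- split_idx[[ch]]
      geno[i, idx] <- .sim_chromosome_mosaic(map$cM[idx],
                                             config$map_length_cM[ch])
    }
  }
  n_het <- 0L
  if (config$residual_het_rate > 0) {
    het <- which(stats::runif(length(geno)) < config$residual_het_rate)
    geno[het] <- NA_integer_
    n_het <- length(het)
  }
  list(genotypes = geno, map = map, n_het = n_het)
}

#' Simulate the two tester genotypes
#'
#' The testers carry parental alleles (+1/-1 relative to the two RIL
#' parents). At a fraction \code{tester_similarity} of loci the two testers
#' carry the same allele; elsewhere they carry opposite alleles.
#'
#' @param config a \code{\link{sim_config}}.
#' @param map marker map (from \code{\link{simulate_ril_population}}).
#' @return list with integer vectors \code{tester1}, \code{tester2} (named by
#'   marker) and logical \code{shared} marking shared-allele loci.
#' @export
simulate_testers <- function(config, map) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m <- nrow(map)
  t1 <- ifelse(stats::runif(m) < 0.5, 1L, -1L)
  shared <- stats::runif(m) < config$tester_similarity
  t2 <- ifelse(shared, t1, -t1)
  names(t1) <- names(t2) <- map$marker
  list(tester1 = as.integer(t1), tester2 = as.integer(t2), shared = shared)
}

#' Define ground-truth genetic architecture
#'
#' Holds per-marker additive and dominance effects, a list of epistatic
#' pairs, and the intended variance targets. Effects may be given directly,
#' or drawn at random and later rescaled to variance targets by
#' \code{\link{simulate_phenotypes}}.
#'
#' @param markers marker names the effects refer to.
#' @param additive named numeric vector of additive effects a_k (subset of
#'   markers), or NULL.
#' @param dominance named numeric vector of dominance effects d_k, or NULL.
#' @param epistatic_pairs data.frame with columns marker1, marker2, type
#'   (one of "aa", "ad", "dd") and effect, or NULL.
#' @param variance_targets named numeric vector with any of
#'   sigma2_a, sigma2_d, sigma2_aa, sigma2_ad, sigma2_dd, sigma2_GxE,
#'   sigma2_E, sigma2_rep, sigma2_eps. Genetic entries, when positive, cause
#'   the corresponding effects to be rescaled so the realized variance in the
#'   simulated hybrids matches the target exactly.
#' @return object of class \code{true_genetics}.
#' @export
true_genetics <- function(markers, additive = NULL, dominance = NULL,
                          epistatic_pairs = NULL,
                          variance_targets = c(sigma2_eps = 1)) {
  for (eff in list(additive, dominance)) {
    if (!is.null(eff) && !all(names(eff) %in% markers))
      stop("effect refers to a marker absent from the map: ",
           paste(setdiff(names(eff), markers), collapse = ", "))
  }
  if (!is.null(epistatic_pairs)) {
    stopifnot(all(c("marker1", "marker2", "type", "effect") %in%
                    names(epistatic_pairs)))
    if (!all(epistatic_pairs$type %in% c("aa", "ad", "dd")))
      stop("epistatic type must be one of aa, ad, dd")
    bad <- setdiff(c(epistatic_pairs$marker1, epistatic_pairs$marker2), markers)
    if (length(bad)) stop("epistatic pair refers to missing marker: ",
                          paste(unique(bad), collapse = ", "))
  }
  if (any(variance_targets < 0)) stop("variance targets must be non-negative")
  structure(list(markers = markers, additive = additive, dominance = dominance,
                 epistatic_pairs = epistatic_pairs,
                 variance_targets = variance_targets),
            class = "true_genetics")
}

#' Draw a fully polygenic truth calibrated to the kinship scale
#'
#' Draws iid per-marker additive and dominance effects whose variances are
#' calibrated to the (centered) design cross-product scale, so that the
#' model-scale variance components of the normalized kinship kernels equal
#' the targets in expectation: a_k ~ N(0, sigma2_a / c_a) with c_a the mean
#' diagonal of the raw centered kernel. This is the faithful generative
#' counterpart of the five-kernel variance model and the reference
#' architecture for variance-recovery experiments (use
#' \code{scale = "none"} in \code{\link{simulate_phenotypes}}).
#'
#' @param coding a \code{hybrid_coding} defining the design matrices.
#' @param variance_targets named vector with sigma2_a and/or sigma2_d
#'   (genetic), plus any of sigma2_E, sigma2_GxE, sigma2_rep, sigma2_eps
#'   passed through to the phenotype simulator.
#' @param seed integer seed for the effect draw.
#' @return a \code{\link{true_genetics}}.
#' @export
polygenic_truth <- function(coding, variance_targets, seed = 1L) {
  set.seed(seed)
  markers <- colnames(coding$Z)
  m <- length(markers)
  getv <- function(nm) if (nm %in% names(variance_targets))
    variance_targets[[nm]] else 0
  add <- dom <- NULL
  if (getv("sigma2_a") > 0) {
    Zc <- .prep_design(coding$Z)
    c_a <- mean(rowSums(Zc^2))
    add <- stats::setNames(stats::rnorm(m, 0, sqrt(getv("sigma2_a") / c_a)),
                           markers)
  }
  if (getv("sigma2_d") > 0) {
    Wc <- .prep_design(coding$W)
    c_d <- mean(rowSums(Wc^2))
    dom <- stats::setNames(stats::rnorm(m, 0, sqrt(getv("sigma2_d") / c_d)),
                           markers)
  }
  true_genetics(markers, additive = add, dominance = dom,
                variance_targets = variance_targets)
}

# Rescale a genetic-value vector to an exact target variance; returns the
# vector and the applied factor (0-variance vectors are left untouched).
.scale_to_var <- function(g, target) {
  v <- stats::var(g)
  if (is.na(v) || v < .Machine$double.eps) return(list(g = g * 0, f = 0))
  f <- sqrt(target / v)
  list(g = g * f, f = f)
}

# Per-component genetic values from a hybrid coding and effect draws.
.component_values <- function(Z, W, truth) {
  zero <- numeric(nrow(Z))
  g_a <- g_d <- g_aa <- g_ad <- g_dd <- zero
  if (!is.null(truth$additive))
    g_a <- as.numeric(Z[, names(truth$additive), drop = FALSE] %*% truth$additive)
  if (!is.null(truth$dominance))
    g_d <- as.numeric(W[, names(truth$dominance), drop = FALSE] %*% truth$dominance)
  ep <- truth$epistatic_pairs
  if (!is.null(ep)) {
    for (i in seq_len(nrow(ep))) {
      k <- ep$marker1[i]; kp <- ep$marker2[i]
      col <- switch(ep$type[i],
                    aa = Z[, k] * Z[, kp],
                    ad = Z[, k] * W[, kp],
                    dd = W[, k] * W[, kp])
      gi <- col * ep$effect[i]
      if (ep$type[i] == "aa") g_aa <- g_aa + gi
      if (ep$type[i] == "ad") g_ad <- g_ad + gi
      if (ep$type[i] == "dd") g_dd <- g_dd + gi
    }
  }
  list(a = g_a, d = g_d, aa = g_aa, ad = g_ad, dd = g_dd)
}

#' Simulate multi-environment trial phenotypes for hybrids (or RILs)
#'
#' Writes phenotype records from exactly the model the pipeline fits:
#' observation = mu + genetic value (additive + dominance + epistatic) +
#' environment effect + genotype-by-environment draw + replicate-within-
#' environment effect + residual. When a genetic variance target is set, the
#' corresponding component is rescaled so its realized variance across
#' individuals matches the target exactly; realized variances are returned
#' alongside the targets.
#'
#' @param coding a \code{hybrid_coding} (see
#'   \code{\link{derive_hybrid_codes}}) whose Z/W matrices define the
#'   genotypes; missing codes are treated as 0 (mean of the two homozygote
#'   codes) when forming genetic values.
#' @param truth a \code{\link{true_genetics}}.
#' @param config a \code{\link{sim_config}} (n_env, n_rep, seed used).
#' @param mu grand mean.
#' @param trait trait label.
#' @param scale "realized" (default) rescales each genetic component so its
#'   realized variance across individuals equals the target exactly;
#'   "none" uses the supplied effects as-is (the right choice with
#'   \code{\link{polygenic_truth}}, whose effects are already calibrated on
#'   the model scale).
#' @return list with \code{records} (long data.frame: genotype, environment,
#'   replicate, trait, value), \code{realized} (named numeric realized
#'   variance components), \code{targets}, \code{genetic_values}
#'   (per-individual total genetic value) and \code{applied_effects} (a
#'   \code{true_genetics} holding the effects actually applied after any
#'   rescaling, reusable to score other genotypes under the same model).
#' @export
simulate_phenotypes <- function(coding, truth, config, mu = 0, trait = "trait1",
                                scale = c("realized", "none")) {
  stopifnot(inherits(truth, "true_genetics"))
  scale <- match.arg(scale)
  set.seed(config$seed + 2L)
  Z <- coding$Z; W <- coding$W
  Z[is.na(Z)] <- 0; W[is.na(W)] <- 0
  vt <- truth$variance_targets
  tgt <- function(nm) if (nm %in% names(vt)) vt[[nm]] else NA_real_
  g <- .component_values(Z, W, truth)
  realized <- c()
  factors <- c(a = 1, d = 1, aa = 1, ad = 1, dd = 1)
  for (comp in c("a", "d", "aa", "ad", "dd")) {
    t_nm <- paste0("sigma2_", comp)
    if (scale == "realized" && !is.na(tgt(t_nm)) && tgt(t_nm) > 0) {
      sc <- .scale_to_var(g[[comp]], tgt(t_nm))
      g[[comp]] <- sc$g
      factors[comp] <- sc$f
    }
    realized[t_nm] <- stats::var(g[[comp]])
  }
  # the effects actually applied (after any rescaling), reusable to score
  # other genotypes (e.g. parents) under the identical genetic model
  eff_applied <- truth
  if (!is.null(eff_applied$additive))
    eff_applied$additive <- eff_applied$additive * factors["a"]
  if (!is.null(eff_applied$dominance))
    eff_applied$dominance <- eff_applied$dominance * factors["d"]
  if (!is.null(eff_applied$epistatic_pairs)) {
    ep <- eff_applied$epistatic_pairs
    ep$effect <- ep$effect * unname(factors[ep$type])
    eff_applied$epistatic_pairs <- ep
  }
  g_tot <- g$a + g$d + g$aa + g$ad + g$dd
  n <- nrow(Z)
  ids <- rownames(Z)
  s2_E <- if (!is.na(tgt("sigma2_E"))) tgt("sigma2_E") else 0
  s2_GxE <- if (!is.na(tgt("sigma2_GxE"))) tgt("sigma2_GxE") else 0
  s2_rep <- if (!is.na(tgt("sigma2_rep"))) tgt("sigma2_rep") else 0
  s2_eps <- if (!is.na(tgt("sigma2_eps"))) tgt("sigma2_eps") else 0
  env_eff <- stats::rnorm(config$n_env, 0, sqrt(s2_E))
  gxe <- matrix(stats::rnorm(n * config$n_env, 0, sqrt(s2_GxE)), n, config$n_env)
  rep_eff <- matrix(stats::rnorm(config$n_env * config$n_rep, 0, sqrt(s2_rep)),
                    config$n_env, config$n_rep)
  recs <- vector("list", config$n_env * config$n_rep)
  idx <- 1L
  for (e in seq_len(config$n_env)) {
    for (r in seq_len(config$n_rep)) {
      val <- mu + g_tot + env_eff[e] + gxe[, e] + rep_eff[e, r] +
        stats::rnorm(n, 0, sqrt(s2_eps))
      recs[[idx]] <- data.frame(genotype = ids, environment = paste0("E", e),
                                replicate = paste0("R", r), trait = trait,
                                value = val, stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  realized["sigma2_GxE"] <- s2_GxE
  realized["sigma2_eps"] <- s2_eps
  list(records = do.call(rbind, recs), realized = realized,
       targets = vt, genetic_values = g_tot, applied_effects = eff_applied)
}

#' Simulate a complete synthetic NCII study
#'
#' Convenience wrapper: RIL genomes, two testers, the TC and TM hybrid
#' codings and the pooled TC-TM coding.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{ril} (genotypes + map), \code{testers},
#'   \code{coding_tc}, \code{coding_tm}, \code{pooled}.
#' @export
simulate_ncii_study <- function(config = sim_config()) {
  ril <- simulate_ril_population(config)
  testers <- simulate_testers(config, ril$map)
  tc <- derive_hybrid_codes(ril$genotypes, testers$tester1, suffix = "TC")
  tm <- derive_hybrid_codes(ril$genotypes, testers$tester2, suffix = "TM")
  pooled <- pool_populations(tc, tm)
  list(ril = ril, testers = testers, coding_tc = tc, coding_tm = tm,
       pooled = pooled)
}
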