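#' Remove phenotypic outliers with a studentized-residual razor
#'
#' For each trait, fits the fixed-effect trial model
#' value ~ genotype + environment/replicate and drops observations whose
#' absolute externally studentized residual strictly exceeds the threshold.
#' The pass is a single sweep (not iterated); a residual exactly equal to the
#' threshold is retained.
#'
#' @param records long-format trial records (genotype, environment,
#'   replicate, trait, value).
#' @param threshold studentized-residual cutoff (default 2.8).
#' @return list with \code{records} (cleaned) and \code{removed} (the
#'   offending rows, with their studentized residuals).
#' @export
remove_outliers <- function(records, threshold = 2.8) {
  stopifnot(all(c("genotype", "environment", "replicate", "trait", "value")
                %in% names(records)))
  removed <- list()
  keep <- rep(TRUE, nrow(records))
  for (tr in unique(records$trait)) {
    idx <- which(records$trait == tr & !is.na(records$value))
    d <- records[idx, ]
    multi_env <- length(unique(d$environment)) > 1
    fml <- if (multi_env) value ~ genotype + environment + environment:replicate
           else value ~ genotype + replicate
    fit <- stats::lm(fml, data = d)
    rs <- stats::rstudent(fit)
    bad <- which(!is.na(rs) & abs(rs) > threshold)
    if (length(bad)) {
      out <- d[bad, ]
      out$studentized_residual <- rs[bad]
      out$row <- idx[bad]
      removed[[tr]] <- out
      keep[idx[bad]] <- FALSE
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    cbind(records[0, ], studentized_residual = numeric(0),
          row = integer(0))
  cleaned <- records[keep, ]
  gone <- setdiff(unique(records$genotype), unique(cleaned$genotype))
  if (length(gone))
    warning("all observations removed for genotype(s): ",
            paste(gone, collapse = ", "))
  list(records = cleaned, removed = removed)
}

#' Across-environment trial model: BLUEs and variance components
#'
#' Fits the two standard forms of the multi-environment model
#' y = mu + G + E + GxE + R(E) + eps for one trait: genotype fixed (with
#' environment, GxE and replicate-within-environment random) for the BLUEs,
#' and all terms random for REML variance components. Component significance
#' is assessed by a REML likelihood-ratio test against the component-dropped
#' model with a 50:50 chi-square(0)/chi-square(1) mixture null.
#'
#' @param records long-format records for a single trait (or pass
#'   \code{trait} to subset).
#' @param trait optional trait id to subset on.
#' @return object of class \code{varcomp_anova}: list with
#'   \code{sigma2_G}, \code{sigma2_GxE}, \code{sigma2_eps}, \code{sigma2_E},
#'   \code{n_env}, \code{n_rep}, \code{blues} (named vector),
#'   \code{p_G}, \code{p_GxE} (mixture LRT p-values), \code{H2}.
#' @export
fit_trial_model <- function(records, trait = NULL) {
  if (!is.null(trait)) records <- records[records$trait == trait, ]
  records <- records[!is.na(records$value), ]
  records$genotype <- factor(records$genotype)
  records$environment <- factor(records$environment)
  records$replicate <- factor(records$replicate)
  n_env <- nlevels(records$environment)
  n_rep <- nlevels(records$replicate)
  if (n_env < 2)
    stop("at least two environments are needed to separate GxE")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  vfit <- lme4::lmer(value ~ (1 | genotype) + (1 | environment) +
                       (1 | genotype:environment) +
                       (1 | environment:replicate),
                     data = records, REML = TRUE, control = ctrl)
  vc <- as.data.frame(lme4::VarCorr(vfit))
  getv <- function(g) {
    i <- match(g, vc$grp)
    if (is.na(i)) 0 else vc$vcov[i]
  }
  s2_G <- getv("genotype"); s2_GxE <- getv("genotype:environment")
  s2_E <- getv("environment"); s2_eps <- getv("Residual")
  drop_p <- function(form_drop) {
    red <- lme4::lmer(form_drop, data = records, REML = TRUE, control = ctrl)
    lrt <- max(0, 2 * (as.numeric(stats::logLik(vfit)) -
                         as.numeric(stats::logLik(red))))
    0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE) + 0.5 * (lrt <= 0)
  }
  p_G <- drop_p(value ~ (1 | environment) + (1 | genotype:environment) +
                  (1 | environment:replicate))
  p_GxE <- drop_p(value ~ (1 | genotype) + (1 | environment) +
                    (1 | environment:replicate))
  bfit <- lme4::lmer(value ~ 0 + genotype + (1 | environment) +
                       (1 | genotype:environment) +
                       (1 | environment:replicate),
                     data = records, REML = TRUE, control = ctrl)
  blues <- lme4::fixef(bfit)
  names(blues) <- sub("^genotype", "", names(blues))
  structure(list(sigma2_G = s2_G, sigma2_GxE = s2_GxE, sigma2_eps = s2_eps,
                 sigma2_E = s2_E, n_env = n_env, n_rep = n_rep,
                 blues = blues, p_G = p_G, p_GxE = p_GxE,
                 H2 = broad_sense_heritability(s2_G, s2_GxE, s2_eps,
                                               n_env, n_rep)),
            class = "varcomp_anova")
}

#' Broad-sense heritability on an entry-mean basis
#'
#' H2 = sigma2_G / (sigma2_G + sigma2_GxE / n_env +
#' sigma2_eps / (n_env * n_rep)).
#'
#' @param sigma2_G genotypic variance.
#' @param sigma2_GxE genotype-by-environment interaction variance.
#' @param sigma2_eps residual variance.
#' @param n_env number of environments.
#' @param n_rep replicates per environment.
#' @return heritability in [0, 1]; NA (with a warning) if all components are
#'   zero.
#' @export
broad_sense_heritability <- function(sigma2_G, sigma2_GxE, sigma2_eps,
                                     n_env, n_rep) {
  stopifnot(n_env >= 1, n_rep >= 1)
  denom <- sigma2_G + sigma2_GxE / n_env + sigma2_eps / (n_env * n_rep)
  if (denom <= 0) {
    warning("all variance components are zero; heritability undefined")
    return(NA_real_)
  }
  sigma2_G / denom
}

#' Summary statistics for a trait
#'
#' @param values numeric vector (n >= 2).
#' @return named vector min, max, mean, sd, cv (CV in percent,
#'   100 * SD / mean; NA with a warning if the mean is zero).
#' @export
summarize_trait <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 2)
  m <- mean(values); s <- stats::sd(values)
  cv <- if (m == 0) {
    warning("mean is zero; CV undefined"); NA_real_
  } else 100 * s / m
  c(min = min(values), max = max(values), mean = m, sd = s, cv = cv)
}

#' Per-environment BLUEs (genotype fixed, replicate random)
#'
#' Fits y = mu + G + R + eps within one environment with genotype fixed and
#' replicate random; with a single replicate the BLUE is the observation.
#'
#' @param records long records for one environment and one trait.
#' @return named numeric vector of genotype BLUEs.
#' @export
within_env_blue <- function(records) {
  records <- records[!is.na(records$value), ]
  records$genotype <- factor(records$genotype)
  if (length(unique(records$replicate)) < 2) {
    out <- tapply(records$value, records$genotype, mean)
    return(stats::setNames(as.numeric(out), names(out)))
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- tryCatch(
    lme4::lmer(value ~ 0 + genotype + (1 | replicate), data = records,
               REML = TRUE, control = ctrl),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- tapply(records$value, records$genotype, mean)
    return(stats::setNames(as.numeric(out), names(out)))
  }
  b <- lme4::fixef(fit)
  stats::setNames(as.numeric(b), sub("^genotype", "", names(b)))
}

#' Midparent heterosis
#'
#' MPH = H - (P1 + P2) / 2, computed per hybrid and environment from BLUEs
#' of the hybrid (H), the tester parent (P1) and the RIL parent (P2).
#' Vectorized; missing parent values propagate to missing MPH.
#'
#' @param H,P1,P2 numeric vectors of BLUEs on the same environment.
#' @return numeric MPH values.
#' @export
compute_mph <- function(H, P1, P2) H - (P1 + P2) / 2

#' Second-step MPH mixed model
#'
#' Fits MPH_ij = mu + G_i + E_j + eps_ij with genotype and environment
#' random for variance components (genotype fixed for BLUEs), and returns
#' the MPH heritability sigma2_G / (sigma2_G + sigma2_eps / n_env) —
#' replicates are already absorbed by the first-step BLUEs.
#'
#' @param mph data.frame with columns hybrid, environment, mph.
#' @return list with sigma2_G, sigma2_E, sigma2_eps, n_env, h2_mph,
#'   p_G (mixture LRT p-value) and blues (per-hybrid MPH BLUEs).
#' @export
mph_model <- function(mph) {
  stopifnot(all(c("hybrid", "environment", "mph") %in% names(mph)))
  mph <- mph[!is.na(mph$mph), ]
  mph$hybrid <- factor(mph$hybrid)
  mph$environment <- factor(mph$environment)
  n_env <- nlevels(mph$environment)
  if (n_env < 2) stop("at least two environments are needed for the MPH model")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  vfit <- lme4::lmer(mph ~ (1 | hybrid) + (1 | environment), data = mph,
                     REML = TRUE, control = ctrl)
  vc <- as.data.frame(lme4::VarCorr(vfit))
  getv <- function(g) { i <- match(g, vc$grp); if (is.na(i)) 0 else vc$vcov[i] }
  s2_G <- getv("hybrid"); s2_E <- getv("environment"); s2_eps <- getv("Residual")
  red <- lme4::lmer(mph ~ (1 | environment), data = mph, REML = TRUE,
                    control = ctrl)
  lrt <- max(0, 2 * (as.numeric(stats::logLik(vfit)) -
                       as.numeric(stats::logLik(red))))
  p_G <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE) + 0.5 * (lrt <= 0)
  bfit <- lme4::lmer(mph ~ 0 + hybrid + (1 | environment), data = mph,
                     REML = TRUE, control = ctrl)
  blues <- lme4::fixef(bfit)
  names(blues) <- sub("^hybrid", "", names(blues))
  list(sigma2_G = s2_G, sigma2_E = s2_E, sigma2_eps = s2_eps, n_env = n_env,
       h2_mph = s2_G / (s2_G + s2_eps / n_env), p_G = p_G, blues = blues)
}

#' GCA/SCA decomposition of hybrid performance
#'
#' Fits y = mu + E + GCA_RIL + GCA_Tester + SCA + GCA_RIL:E + GCA_Tester:E +
#' SCA:E + eps with all effects random, on per-environment hybrid BLUEs.
#'
#' @param blues data.frame with columns ril, tester, environment, value.
#' @return list of the seven variance components plus
#'   \code{sca_gca_ratio} = sigma2_SCA / (sigma2_GCA_RIL + sigma2_GCA_Tester).
#' @export
gca_sca_decompose <- function(blues) {
  stopifnot(all(c("ril", "tester", "environment", "value") %in% names(blues)))
  if (length(unique(blues$tester)) < 2)
    stop("SCA is not identifiable with a single tester")
  d <- blues
  d$ril <- factor(d$ril); d$tester <- factor(d$tester)
  d$environment <- factor(d$environment)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  # with one BLUE per ril x tester x environment cell the SCA-by-environment
  # term is confounded with the residual and is absorbed there
  cells <- paste(d$ril, d$tester, d$environment)
  sca_e_estimable <- anyDuplicated(cells) > 0
  fml <- if (sca_e_estimable)
    value ~ (1 | environment) + (1 | ril) + (1 | tester) + (1 | ril:tester) +
      (1 | ril:environment) + (1 | tester:environment) +
      (1 | ril:tester:environment)
  else
    value ~ (1 | environment) + (1 | ril) + (1 | tester) + (1 | ril:tester) +
      (1 | ril:environment) + (1 | tester:environment)
  fit <- lme4::lmer(fml, data = d, REML = TRUE, control = ctrl)
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) { i <- match(g, vc$grp); if (is.na(i)) 0 else vc$vcov[i] }
  out <- list(sigma2_E = getv("environment"),
              sigma2_GCA_RIL = getv("ril"),
              sigma2_GCA_Tester = getv("tester"),
              sigma2_SCA = getv("ril:tester"),
              sigma2_GCA_RIL_E = getv("ril:environment"),
              sigma2_GCA_Tester_E = getv("tester:environment"),
              sigma2_SCA_E = if (sca_e_estimable)
                getv("ril:tester:environment") else NA_real_,
              sigma2_eps = getv("Residual"))
  gca_sum <- out$sigma2_GCA_RIL + out$sigma2_GCA_Tester
  out$sca_gca_ratio <- if (gca_sum > 0) out$sigma2_SCA / gca_sum else NA_real_
  out
}

#' Trait correlations and path analysis
#'
#' Computes the pairwise correlation matrix and path coefficients of each
#' predictor trait toward a response trait. Path coefficients follow the
#' standardized partial-regression convention p_i = b_i * s_Xi / s_Y, i.e.
#' the coefficients of an ordinary regression of the standardized response
#' on the standardized predictors. Values below \code{display_threshold}
#' (default 0.14) are suppressed only in the \code{display} copy.
#'
#' @param traits data.frame of per-genotype trait values (columns = traits).
#' @param response name of the response trait (e.g. grain yield).
#' @param display_threshold magnitude below which coefficients are hidden in
#'   the display output.
#' @return list with \code{correlations}, \code{path} (named coefficients),
#'   \code{display} (thresholded copy), \code{unstable} (TRUE if the
#'   predictor matrix is ill-conditioned).
#' @export
correlations_and_path <- function(traits, response, display_threshold = 0.14) {
  stopifnot(response %in% names(traits))
  cc <- traits[stats::complete.cases(traits), , drop = FALSE]
  preds <- setdiff(names(traits), response)
  if (nrow(cc) < length(preds) + 2)
    stop("not enough complete cases for path analysis")
  cors <- stats::cor(cc)
  Xs <- scale(as.matrix(cc[, preds, drop = FALSE]))
  ys <- as.numeric(scale(cc[[response]]))
  R <- stats::cor(Xs)
  unstable <- kappa(R) > 1e8
  b <- as.numeric(stats::coef(stats::lm(ys ~ Xs - 1)))
  names(b) <- preds
  disp <- b
  disp[abs(disp) < display_threshold] <- NA_real_
  list(correlations = cors, path = b, display = disp, unstable = unstable,
       display_threshold = display_threshold)
}

#' Assemble an MPH table from per-environment BLUEs
#'
#' @param hybrid_blues data.frame hybrid, environment, value.
#' @param parent_links data.frame hybrid, ril, tester.
#' @param parent_blues data.frame genotype, environment, value covering the
#'   RILs and the testers.
#' @return data.frame hybrid, environment, mph.
#' @export
build_mph_table <- function(hybrid_blues, parent_links, parent_blues) {
  key <- function(g, e) paste(g, e, sep = "\r")
  pb <- stats::setNames(parent_blues$value,
                        key(parent_blues$genotype, parent_blues$environment))
  links <- parent_links[match(hybrid_blues$hybrid, parent_links$hybrid), ]
  p1 <- pb[key(links$tester, hybrid_blues$environment)]
  p2 <- pb[key(links$ril, hybrid_blues$environment)]
  data.frame(hybrid = hybrid_blues$hybrid,
             environment = hybrid_blues$environment,
             mph = compute_mph(hybrid_blues$value, as.numeric(p1),
                               as.numeric(p2)),
             stringsAsFactors = FALSE)
}
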