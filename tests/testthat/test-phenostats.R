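test_that("outlier razor removes an injected gross outlier and nothing else", {
  rec <- make_trial_records(40, 3, 2, s2_G = 4, s2_GxE = 1, s2_eps = 1,
                            seed = 7)
  clean0 <- remove_outliers(rec)
  base_removed <- nrow(clean0$removed)
  rec2 <- rec
  rec2$value[17] <- rec2$value[17] + 20 * sd(rec$value)
  clean <- remove_outliers(rec2)
  expect_true(17 %in% clean$removed$row)
  # the single sweep may also flag replicate siblings of the contaminated
  # genotype (its fixed effect absorbs part of the shock) but nothing else
  extra <- setdiff(clean$removed$row, c(17, clean0$removed$row))
  expect_true(all(rec2$genotype[extra] == rec2$genotype[17]))
})

test_that("outlier threshold is strict: a residual at the cutoff survives", {
  rec <- make_trial_records(30, 2, 2, s2_G = 2, s2_GxE = 0.5, s2_eps = 1,
                            seed = 13)
  fit <- lm(value ~ genotype + environment + environment:replicate, data = rec)
  t_max <- max(abs(rstudent(fit)))
  res <- remove_outliers(rec, threshold = t_max)
  expect_equal(nrow(res$removed), 0)
  res2 <- remove_outliers(rec, threshold = t_max * 0.999)
  expect_equal(nrow(res2$removed), 1)
})

test_that("balanced noiseless data give marginal-mean BLUEs and zero residual", {
  g_eff <- seq(-3, 3, length.out = 7)
  e_eff <- c(-1, 0, 2)
  rec <- expand.grid(genotype = paste0("g", 1:7), environment = paste0("E", 1:3),
                     replicate = c("R1", "R2"), stringsAsFactors = FALSE)
  rec$trait <- "t1"
  rec$value <- 10 + g_eff[as.integer(sub("g", "", rec$genotype))] +
    e_eff[as.integer(sub("E", "", rec$environment))]
  fit <- fit_trial_model(rec)
  marg <- tapply(rec$value, rec$genotype, mean)
  expect_equal(fit$blues[names(marg)], marg, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_lt(fit$sigma2_eps, 1e-6)
})

test_that("trial-model variance components recover generator truth", {
  errs <- sapply(1:6, function(s) {
    rec <- make_trial_records(300, 4, 2, s2_G = 10, s2_GxE = 4, s2_eps = 8,
                              seed = 100 + s)
    fit <- fit_trial_model(rec)
    c(abs(fit$sigma2_G - 10) / 10, abs(fit$sigma2_GxE - 4) / 4,
      abs(fit$sigma2_eps - 8) / 8)
  })
  expect_lt(mean(errs[1, ]), 0.20)
  expect_lt(mean(errs[2, ]), 0.20)
  expect_lt(mean(errs[3, ]), 0.20)
})

test_that("trial model matches a brute-force REML oracle on a small instance", {
  rec <- make_trial_records(12, 3, 2, s2_G = 5, s2_GxE = 2, s2_eps = 3,
                            seed = 99)
  fit <- fit_trial_model(rec)
  # direct dense REML over the four components, independent of lme4
  gf <- factor(rec$genotype); ef <- factor(rec$environment)
  gef <- factor(paste(rec$genotype, rec$environment))
  erf <- factor(paste(rec$environment, rec$replicate))
  Zl <- list(G = model.matrix(~ 0 + gf), E = model.matrix(~ 0 + ef),
             GxE = model.matrix(~ 0 + gef), ER = model.matrix(~ 0 + erf))
  X <- matrix(1, nrow(rec), 1)
  nll <- function(logs) {
    s <- exp(logs)
    -reml_loglik_oracle(c(G = s[1], E = s[2], GxE = s[3], ER = s[4],
                          residual = s[5]), rec$value, X, Zl)
  }
  opt <- optim(log(c(5, 1, 2, 1, 3)), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  ll_or <- -opt$value
  ll_pkg <- reml_loglik_oracle(
    c(G = fit$sigma2_G, E = fit$sigma2_E, GxE = fit$sigma2_GxE,
      ER = 1e-10, residual = fit$sigma2_eps), rec$value, X, Zl)
  # the lme4 fit includes the replicate term; evaluate it at the fitted point
  vfit_rep <- lme4::lmer(value ~ (1 | genotype) + (1 | environment) +
                           (1 | genotype:environment) +
                           (1 | environment:replicate),
                         data = rec, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(vfit_rep))
  s_rep <- vc$vcov[match("environment:replicate", vc$grp)]
  ll_pkg <- reml_loglik_oracle(
    c(G = fit$sigma2_G, E = fit$sigma2_E, GxE = fit$sigma2_GxE,
      ER = max(s_rep, 1e-10), residual = fit$sigma2_eps),
    rec$value, X, Zl)
  # the package fit attains the oracle's restricted likelihood optimum
  expect_lt(ll_pkg, ll_or + 1e-4)
  expect_gt(ll_pkg, ll_or - 1e-4)
})

test_that("broad-sense heritability matches published maize NCII rows", {
  expect_equal(round(broad_sense_heritability(217.97, 26.64, 45.08, 4, 2), 2),
               0.95)
  expect_equal(round(broad_sense_heritability(40.76, 45.49, 180.99, 5, 2), 2),
               0.60)
  expect_equal(broad_sense_heritability(7, 0, 0, 3, 2), 1)
  expect_warning(h <- broad_sense_heritability(0, 0, 0, 4, 2), "undefined")
  expect_true(is.na(h))
})

test_that("trait summaries reproduce published CV values", {
  set.seed(2)
  x <- rnorm(500)
  x <- (x - mean(x)) / sd(x) * 15.29 + 179.28   # exact moments
  s <- summarize_trait(x)
  expect_equal(round(unname(s["cv"]), 2), 8.53)
  y <- (rnorm(300) - 0) ; y <- (y - mean(y)) / sd(y) * 8.91 + 67.87
  expect_equal(round(unname(summarize_trait(y)["cv"]), 2), 13.13)
  expect_equal(unname(summarize_trait(rep(5, 10))["cv"]), 0)
})

test_that("within-environment BLUEs behave under replicate structure", {
  rec <- data.frame(genotype = rep(paste0("g", 1:6), 2),
                    environment = "E1",
                    replicate = rep(c("R1", "R2"), each = 6),
                    trait = "t1",
                    value = c(1:6, 1:6 + 0.0))
  b <- within_env_blue(rec)
  expect_equal(unname(b[paste0("g", 1:6)]), as.numeric(1:6), tolerance = 1e-8)
  # balanced replicate shift: BLUEs move by the half-shift regardless of
  # shrinkage (the replicate contrast is orthogonal to genotypes)
  rec2 <- rec
  rec2$value[rec2$replicate == "R2"] <- rec2$value[rec2$replicate == "R2"] + 4
  b2 <- within_env_blue(rec2)
  expect_equal(unname(b2 - b), rep(2, 6), tolerance = 1e-4)
  # single replicate: BLUE is the observation
  rec1 <- rec[rec$replicate == "R1", ]
  expect_equal(unname(within_env_blue(rec1)[paste0("g", 1:6)]),
               as.numeric(1:6))
})

test_that("midparent heterosis is exact and shift-invariant", {
  expect_equal(compute_mph(10, 8, 6), 3)
  expect_equal(compute_mph(7, 8, 6), 0)
  c_ <- 13.7
  expect_equal(compute_mph(10 + c_, 8 + c_, 6 + c_), compute_mph(10, 8, 6))
  expect_true(is.na(compute_mph(10, NA, 6)))
})

test_that("MPH model recovers variance components and matches an oracle", {
  sim_mph <- function(n_h, n_env, s2G, s2E, s2e, seed) {
    set.seed(seed)
    G <- rnorm(n_h, 0, sqrt(s2G)); E <- rnorm(n_env, 0, sqrt(s2E))
    d <- expand.grid(hybrid = paste0("h", seq_len(n_h)),
                     environment = paste0("E", seq_len(n_env)),
                     stringsAsFactors = FALSE)
    d$mph <- G[match(d$hybrid, paste0("h", seq_len(n_h)))] +
      E[match(d$environment, paste0("E", seq_len(n_env)))] +
      rnorm(nrow(d), 0, sqrt(s2e))
    d
  }
  errs <- sapply(1:5, function(s) {
    d <- sim_mph(300, 4, 2, 1, 1, 200 + s)
    f <- mph_model(d)
    abs(f$sigma2_G - 2) / 2
  })
  expect_lt(mean(errs), 0.20)
  # brute-force REML oracle on a 10-hybrid instance
  d <- sim_mph(10, 3, 2, 1, 1, 77)
  f <- mph_model(d)
  Zl <- list(G = model.matrix(~ 0 + factor(d$hybrid)),
             E = model.matrix(~ 0 + factor(d$environment)))
  X <- matrix(1, nrow(d), 1)
  nll <- function(logs) {
    s <- exp(logs)
    -reml_loglik_oracle(c(G = s[1], E = s[2], residual = s[3]), d$mph, X, Zl)
  }
  opt <- optim(log(c(2, 1, 1)), nll, control = list(maxit = 5000,
                                                    reltol = 1e-14))
  ll_pkg <- reml_loglik_oracle(c(G = f$sigma2_G, E = f$sigma2_E,
                                 residual = f$sigma2_eps), d$mph, X, Zl)
  expect_equal(ll_pkg, -opt$value, tolerance = 1e-4)
  # MPH heritability stays in [0, 1]
  expect_gte(f$h2_mph, 0); expect_lte(f$h2_mph, 1)
})

test_that("GCA/SCA decomposition separates additive and non-additive signal", {
  set.seed(5)
  n_r <- 60
  rg <- rnorm(n_r); tg <- c(-1.5, 1.5)
  d <- expand.grid(ril = paste0("r", 1:n_r), tester = c("T1", "T2"),
                   environment = paste0("E", 1:3), stringsAsFactors = FALSE)
  ri <- match(d$ril, paste0("r", 1:n_r)); ti <- match(d$tester, c("T1", "T2"))
  # purely additive: SCA variance collapses
  d$value <- 10 + rg[ri] + tg[ti] + rnorm(nrow(d), 0, 0.3)
  g0 <- gca_sca_decompose(d)
  expect_lt(g0$sigma2_SCA, 0.1 * g0$sigma2_GCA_RIL)
  # add hybrid-specific deviations: the ratio becomes positive
  sca <- matrix(rnorm(n_r * 2, 0, 1), n_r, 2)
  d$value <- d$value + sca[cbind(ri, ti)]
  g1 <- gca_sca_decompose(d)
  expect_gt(g1$sca_gca_ratio, 0.1)
  # permuting tester labels within RIL destroys tester GCA
  set.seed(6)
  d2 <- d
  for (r in unique(d2$ril)) for (e in unique(d2$environment)) {
    i <- which(d2$ril == r & d2$environment == e)
    d2$tester[i] <- sample(d2$tester[i])
  }
  g2 <- gca_sca_decompose(d2)
  expect_lt(g2$sigma2_GCA_Tester, 0.25 * max(g1$sigma2_GCA_Tester, 0.4))
  expect_error(gca_sca_decompose(d[d$tester == "T1", ]), "single tester")
})

test_that("path coefficients follow the standardized-coefficient convention", {
  set.seed(8)
  n <- 200
  # single predictor: path coefficient equals the simple correlation
  x <- rnorm(n); y <- 0.6 * x + rnorm(n, 0, 0.8)
  tab1 <- data.frame(GY = y, X1 = x)
  p1 <- correlations_and_path(tab1, "GY")
  expect_equal(unname(p1$path["X1"]), cor(x, y), tolerance = 1e-10)
  # orthogonal (and centered) predictors: paths equal simple correlations
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  y2 <- X %*% c(0.5, -0.3, 0.2) + rnorm(n, 0, 0.5)
  tab2 <- data.frame(GY = y2, A = X[, 1], B = X[, 2], C = X[, 3])
  p2 <- correlations_and_path(tab2, "GY")
  for (v in c("A", "B", "C"))
    expect_equal(unname(p2$path[v]), cor(tab2[[v]], tab2$GY),
                 tolerance = 1e-8)
  # general case: matches the normal-equations solve on standardized data
  X3 <- matrix(rnorm(n * 4), n, 4) %*% matrix(rnorm(16), 4, 4)
  y3 <- X3 %*% c(1, -0.5, 0.25, 0) + rnorm(n)
  tab3 <- data.frame(GY = y3, X3)
  p3 <- correlations_and_path(tab3, "GY")
  Xs <- scale(X3); ys <- scale(y3)[, 1]
  b_direct <- solve(crossprod(Xs), crossprod(Xs, ys))[, 1]
  expect_equal(unname(p3$path), unname(b_direct), tolerance = 1e-10)
  # display thresholding hides small coefficients only in the display copy
  expect_true(all(is.na(p3$display[abs(p3$path) < 0.14])))
})

test_that("MPH assembly links hybrids to their parents per environment", {
  hb <- data.frame(hybrid = c("r1_TC", "r2_TC"), environment = "E1",
                   value = c(12, 14))
  links <- data.frame(hybrid = c("r1_TC", "r2_TC"), ril = c("r1", "r2"),
                      tester = c("T1", "T1"))
  pb <- data.frame(genotype = c("r1", "r2", "T1"), environment = "E1",
                   value = c(8, 10, 12))
  m <- build_mph_table(hb, links, pb)
  expect_equal(m$mph, c(12 - 10, 14 - 11))
})
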