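# Independent oracles used across the suite. Each is a deliberately naive,
# direct computation kept separate from the package's own code paths.

# Direct GLS/ML likelihood-ratio test for y ~ N(M beta, (K + I) sigma2),
# profiling beta (GLS) and sigma2; LRT between null and full fixed designs.
gls_ml_lrt_oracle <- function(y, X0, X1, K) {
  n <- length(y)
  V0 <- K + diag(n)
  Vi <- solve(V0)
  wrss <- function(M) {
    b <- solve(t(M) %*% Vi %*% M, t(M) %*% Vi %*% y)
    r <- y - M %*% b
    as.numeric(t(r) %*% Vi %*% r)
  }
  n * log(wrss(X0) / wrss(X1))
}

# Brute-force REML log-likelihood for an arbitrary set of random-effect
# design matrices (variance component models); direct dense algebra.
reml_loglik_oracle <- function(sigma2, y, X, Zlist) {
  n <- length(y); p <- qr(X)$rank
  V <- diag(sigma2[["residual"]], n)
  for (nm in names(Zlist)) V <- V + sigma2[[nm]] * tcrossprod(Zlist[[nm]])
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(r) %*% Vi %*% r))
}

# Closed-form mixed-model prediction for y_tr ~ N(X b, sum s2_x K_xx + s2e I)
# with KNOWN variances: BLUP of the test individuals.
gblup_oracle <- function(y_tr, train, test, kl, s2, s2e) {
  n <- length(train)
  V <- diag(s2e, n)
  for (nm in names(kl)) V <- V + s2[[nm]] * kl[[nm]][train, train]
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y_tr)
  r <- Vi %*% (y_tr - X %*% b)
  pred <- rep(as.numeric(b), length(test))
  for (nm in names(kl))
    pred <- pred + as.numeric(s2[[nm]] * kl[[nm]][test, train] %*% r)
  names(pred) <- test
  pred
}

# Small random hybrid-like design pair (Z, W) for kernel tests.
random_design <- function(n, m, seed) {
  set.seed(seed)
  Z <- matrix(sample(c(-1L, 0L, 1L), n * m, replace = TRUE), n, m)
  W <- matrix(as.integer(Z == 0L), n, m)
  dimnames(Z) <- dimnames(W) <-
    list(paste0("h", seq_len(n)), paste0("m", seq_len(m)))
  list(Z = Z, W = W)
}

# Compact synthetic study reused by several files.
tiny_study <- function(seed = 11, n_ril = 40, similarity = 0.5) {
  cfg <- sim_config(n_ril = n_ril, n_chromosomes = 2, markers_per_chrom = 25,
                    map_length_cM = 100, tester_similarity = similarity,
                    n_env = 2, n_rep = 2, seed = seed)
  list(cfg = cfg, study = simulate_ncii_study(cfg))
}

# Balanced multi-environment trial records with iid genotype, GxE and
# residual draws (direct generative model for the trial-model tests).
make_trial_records <- function(n_geno, n_env, n_rep, s2_G, s2_GxE, s2_eps,
                               seed, env_effects = NULL) {
  set.seed(seed)
  if (is.null(env_effects)) env_effects <- rnorm(n_env, 0, 1)
  G <- rnorm(n_geno, 0, sqrt(s2_G))
  GxE <- matrix(rnorm(n_geno * n_env, 0, sqrt(s2_GxE)), n_geno, n_env)
  out <- expand.grid(genotype = sprintf("g%03d", seq_len(n_geno)),
                     environment = paste0("E", seq_len(n_env)),
                     replicate = paste0("R", seq_len(n_rep)),
                     stringsAsFactors = FALSE)
  gi <- match(out$genotype, sprintf("g%03d", seq_len(n_geno)))
  ei <- match(out$environment, paste0("E", seq_len(n_env)))
  out$trait <- "t1"
  out$value <- 50 + G[gi] + env_effects[ei] + GxE[cbind(gi, ei)] +
    rnorm(nrow(out), 0, sqrt(s2_eps))
  out
}
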