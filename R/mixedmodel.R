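#' Compose the polygenic background covariance
#'
#' K = sum_x K_x * lambda_x over the supplied kernels, with
#' lambda_x = sigma2_x / sigma2 the variance ratios.
#'
#' @param kinships named list of n x n kernels (any subset of a, d, aa, ad,
#'   dd), or a \code{kinship_set}.
#' @param lambdas named non-negative vector; names must match the kernels.
#' @return the composed n x n background matrix K (symmetric PSD).
#' @export
compose_background <- function(kinships, lambdas) {
  kl <- as_kernel_list(kinships)
  if (any(lambdas < 0)) stop("lambda values must be non-negative")
  use <- intersect(names(lambdas), names(kl))
  n <- nrow(kl[[1]])
  K <- matrix(0, n, n)
  for (nm in use) K <- K + lambdas[[nm]] * kl[[nm]]
  K
}

# Normalize kinship containers to a plain named list of kernels.
as_kernel_list <- function(kinships) {
  if (inherits(kinships, "kinship_set"))
    return(list(a = kinships$K_a, d = kinships$K_d, aa = kinships$K_aa,
                ad = kinships$K_ad, dd = kinships$K_dd))
  stopifnot(is.list(kinships), !is.null(names(kinships)))
  kinships
}

#' Whitening transform for a polygenic background
#'
#' Eigen-decomposes K = U D U' and applies Q' = (D + I)^(-1/2) U' to the
#' response, the fixed-effect design and any extra design columns, so that
#' the residual covariance (K + I) sigma2 becomes I sigma2 and ordinary
#' least squares applies downstream.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (should include the intercept).
#' @param K symmetric PSD background matrix.
#' @param extra optional matrix of additional columns to transform.
#' @return object of class \code{whitened_data}: list with \code{y_star},
#'   \code{X_star}, \code{extra_star}, \code{U}, \code{D} and \code{scale}
#'   (the vector (D+1)^(-1/2)).
#' @export
whiten <- function(y, X, K, extra = NULL) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (all(K == 0)) {
    U <- diag(n); d <- rep(0, n)
  } else {
    eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
    U <- eg$vectors; d <- pmax(eg$values, 0)
    if (min(eg$values) < -1e-6 * max(abs(eg$values)))
      stop("background matrix K is not positive semi-definite")
  }
  s <- 1 / sqrt(d + 1)
  tf <- function(M) s * crossprod(U, M)
  structure(list(y_star = as.numeric(s * crossprod(U, y)),
                 X_star = tf(X),
                 extra_star = if (is.null(extra)) NULL else tf(as.matrix(extra)),
                 U = U, D = d, scale = s, transform = tf),
            class = "whitened_data")
}

#' Transform additional design columns with a fitted whitening
#'
#' @param wh a \code{whitened_data}.
#' @param M matrix (or vector) of design columns on the original scale.
#' @return transformed columns Q' M.
#' @export
whiten_columns <- function(wh, M) wh$transform(as.matrix(M))

# Profile ML log-likelihood of y* ~ N(M beta, I sigma2) up to constants:
# -n/2 * log(RSS/n). Returns RSS, rank, coefficients.
.ols_fit <- function(M, y) {
  qr_ <- qr(M)
  rss <- sum(qr.resid(qr_, y)^2)
  list(rss = rss, rank = qr_$rank, coef = qr.coef(qr_, y))
}

#' Likelihood-ratio test between nested OLS models on whitened data
#'
#' Both models contain the whitened fixed-effect design; the full model adds
#' the tested columns. LRT = n * log(RSS_null / RSS_full) is the maximum-
#' likelihood ratio statistic (ML, not REML, since the fixed-effect
#' structure changes between the models); LOD = LRT / 4.61. Coefficients of
#' the tested columns are returned as effect estimates.
#'
#' @param wh a \code{whitened_data}.
#' @param null_cols optional matrix of whitened columns present in both
#'   models (e.g. main-effect columns when testing an interaction).
#' @param test_cols matrix (or vector) of whitened columns tested by the
#'   full model.
#' @return list with \code{lrt}, \code{lod}, \code{effects} (named by
#'   test-column names), \code{rss_null}, \code{rss_full}, \code{pve}
#'   (1 - RSS_full / RSS_null) and \code{estimable}.
#' @export
ml_lrt <- function(wh, null_cols = NULL, test_cols) {
  y <- wh$y_star
  n <- length(y)
  M0 <- wh$X_star
  if (!is.null(null_cols)) M0 <- cbind(M0, as.matrix(null_cols))
  test_cols <- as.matrix(test_cols)
  M1 <- cbind(M0, test_cols)
  f0 <- .ols_fit(M0, y)
  f1 <- .ols_fit(M1, y)
  if (f1$rank <= f0$rank || f1$rss <= 0) {
    eff <- rep(NA_real_, ncol(test_cols))
    names(eff) <- colnames(test_cols)
    return(list(lrt = 0, lod = 0, effects = eff, rss_null = f0$rss,
                rss_full = f0$rss, pve = 0, estimable = FALSE))
  }
  lrt <- max(0, n * log(f0$rss / f1$rss))
  eff <- f1$coef[seq(ncol(M0) + 1, ncol(M1))]
  names(eff) <- colnames(test_cols)
  list(lrt = lrt, lod = lrt / 4.61, effects = eff,
       rss_null = f0$rss, rss_full = f1$rss,
       pve = compute_pve(f1$rss, f0$rss), estimable = TRUE)
}

# REML log-likelihood for y ~ N(X beta, sigma2 (sum lambda_x K_x + I)),
# profiled over beta and sigma2; lambdas on the natural scale.
.reml_loglik <- function(lambdas, y, X, kl) {
  n <- length(y); p <- qr(X)$rank
  H <- diag(n)
  for (nm in names(lambdas)) H <- H + lambdas[[nm]] * kl[[nm]]
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  logdetH <- 2 * sum(log(diag(ch)))
  Hi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Hi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtHiX <- crossprod(X, Hi_X)
  ch2 <- tryCatch(chol(XtHiX), error = function(e) NULL)
  if (is.null(ch2)) return(-1e10)
  beta <- backsolve(ch2, forwardsolve(t(ch2), crossprod(X, Hi_y)))
  r <- y - X %*% beta
  Hi_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- as.numeric(crossprod(r, Hi_r)) / (n - p)
  if (s2 <= 0) return(-1e10)
  -0.5 * ((n - p) * log(s2) + logdetH + 2 * sum(log(diag(ch2))) + (n - p))
}

#' Estimate polygenic variance components on a multi-kernel model
#'
#' Fits y = X beta + sum_x xi_x + eps with xi_x ~ N(0, K_x sigma2_x) over an
#' arbitrary named set of kernels. Two backends: \code{"reml"} maximizes the
#' restricted likelihood over the variance ratios lambda_x = sigma2_x /
#' sigma2 by direct numerical optimization (deterministic); \code{"gibbs"}
#' is a Gibbs sampler with scaled-inverse-chi-square priors (default 15,000
#' iterations, 5,000 burn-in) that reports posterior means.
#'
#' @param y response vector.
#' @param X fixed-effect design (defaults to the intercept).
#' @param kinships named list of PSD kernels or a \code{kinship_set}.
#' @param backend "reml" or "gibbs".
#' @param n_iter,burn_in Gibbs chain settings.
#' @param seed seed for the sampler.
#' @return object of class \code{varcomp_estimates}: list with
#'   \code{sigma2} (named, genetic components plus \code{residual}),
#'   \code{lambda}, \code{proportions} (shares of total variance),
#'   \code{backend}, \code{loglik} (REML) or chain diagnostics (Gibbs).
#' @export
estimate_polygenic_varcomps <- function(y, X = NULL, kinships,
                                        backend = c("reml", "gibbs"),
                                        n_iter = 15000, burn_in = 5000,
                                        seed = 1L) {
  backend <- match.arg(backend)
  kl <- as_kernel_list(kinships)
  kl <- kl[vapply(kl, function(K) any(K != 0), logical(1))]
  if (!length(kl)) stop("no non-zero kernels supplied")
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  for (nm in names(kl)) {
    K <- kl[[nm]]
    if (nrow(K) != n) stop("kernel ", nm, " does not match n")
    ev_min <- min(eigen((K + t(K)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values)
    if (ev_min < -1e-6 * max(1, max(abs(K))))
      stop("kernel ", nm, " is not positive semi-definite")
  }
  if (backend == "reml") {
    nk <- length(kl)
    obj <- function(logl) {
      l <- stats::setNames(exp(logl), names(kl))
      -.reml_loglik(l, y, X, kl)
    }
    if (nk == 1) {
      opt1 <- stats::optimize(function(l) obj(l), c(-18, 12), tol = 1e-10)
      lam <- stats::setNames(exp(opt1$minimum), names(kl))
      best <- -opt1$objective
    } else {
      start <- rep(log(0.1), nk)
      opt <- stats::optim(start, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10))
      opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-12))
      lam <- stats::setNames(exp(opt2$par), names(kl))
      best <- -opt2$value
    }
    lam[lam < 1e-6] <- 0
    # residual sigma2 at the optimum
    H <- diag(n)
    for (nm in names(lam)) H <- H + lam[[nm]] * kl[[nm]]
    ch <- chol(H)
    Hi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Hi_X <- backsolve(ch, forwardsolve(t(ch), X))
    beta <- solve(crossprod(X, Hi_X), crossprod(X, Hi_y))
    r <- y - X %*% beta
    s2 <- as.numeric(crossprod(r, backsolve(ch, forwardsolve(t(ch), r)))) /
      (n - qr(X)$rank)
    sigma2 <- c(lam * s2, residual = s2)
    props <- sigma2 / sum(sigma2)
    return(structure(list(sigma2 = sigma2, lambda = lam,
                          proportions = props, backend = "reml",
                          loglik = best, beta = as.numeric(beta)),
                     class = "varcomp_estimates"))
  }
  gibbs_varcomps(y, X, kl, n_iter = n_iter, burn_in = burn_in, seed = seed)
}

# Gibbs sampler over beta, the per-kernel effect vectors (in each kernel's
# eigenbasis) and the variances, with scaled-inverse-chi-square priors
# (df0 = 5, scale anchored at a fraction of var(y)).
gibbs_varcomps <- function(y, X, kl, n_iter = 15000, burn_in = 5000,
                           seed = 1L) {
  set.seed(seed)
  n <- length(y); nk <- length(kl)
  eg <- lapply(kl, function(K) {
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    keep <- e$values > 1e-8 * max(e$values)
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })
  df0 <- 5
  S0 <- stats::var(y) / (nk + 1) * (df0 - 2) / df0   # prior mean ~ equal split
  XtX <- crossprod(X)
  p <- ncol(X)
  beta <- solve(XtX, crossprod(X, y))
  gamma <- lapply(eg, function(e) numeric(length(e$d)))  # eigen-basis effects
  xi <- lapply(eg, function(e) numeric(n))
  s2g <- stats::setNames(rep(stats::var(y) / (nk + 1), nk), names(kl))
  s2e <- stats::var(y) / 2
  keep_iter <- n_iter - burn_in
  sums_g <- stats::setNames(numeric(nk), names(kl)); sum_e <- 0
  for (it in seq_len(n_iter)) {
    resid_all <- y - X %*% beta
    for (x in names(kl)) resid_all <- resid_all - xi[[x]]
    # beta | rest
    rb <- resid_all + X %*% beta
    Vb <- solve(XtX) * s2e
    mb <- solve(XtX, crossprod(X, rb))
    beta <- mb + t(chol(Vb)) %*% stats::rnorm(p)
    resid_all <- rb - X %*% beta
    # each component in its eigenbasis
    for (x in names(kl)) {
      e <- eg[[x]]
      r_x <- resid_all + xi[[x]]
      rt <- crossprod(e$U, r_x)
      vpost <- e$d * s2g[[x]] * s2e / (e$d * s2g[[x]] + s2e)
      mpost <- (e$d * s2g[[x]] / (e$d * s2g[[x]] + s2e)) * rt
      gamma[[x]] <- as.numeric(mpost + sqrt(vpost) * stats::rnorm(length(e$d)))
      xi[[x]] <- as.numeric(e$U %*% gamma[[x]])
      resid_all <- r_x - xi[[x]]
      ss <- sum(gamma[[x]]^2 / e$d)
      s2g[[x]] <- (ss + df0 * S0) / stats::rchisq(1, length(e$d) + df0)
    }
    s2e <- (sum(resid_all^2) + df0 * S0) / stats::rchisq(1, n + df0)
    if (it > burn_in) {
      sums_g <- sums_g + s2g
      sum_e <- sum_e + s2e
    }
  }
  sigma2 <- c(sums_g / keep_iter, residual = sum_e / keep_iter)
  props <- sigma2 / sum(sigma2)
  structure(list(sigma2 = sigma2,
                 lambda = sigma2[names(kl)] / sigma2[["residual"]],
                 proportions = props, backend = "gibbs",
                 n_iter = n_iter, burn_in = burn_in, seed = seed),
            class = "varcomp_estimates")
}
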