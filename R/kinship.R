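# Shared kernel preprocessing: mean-impute missing codes per column, then
# center each column, so that sigma2_x is the variance contributed across
# individuals (the usual genomic-relationship convention) rather than an
# uncentered cross-product scale.
.prep_design <- function(M, center = TRUE) {
  M <- impute_column_means(M)
  if (center) M <- sweep(M, 2, colMeans(M))
  M
}

#' First-order (additive and dominance) kinship kernels
#'
#' K_a is proportional to Z Z' and K_d to W W' with the design columns
#' mean-imputed and centered, each kernel rescaled so its mean diagonal
#' equals 1, so that variance ratios are comparable across kernels.
#'
#' @param Z additive design matrix (hybrids x markers, entries 1/0/-1/NA).
#' @param W dominance design matrix (entries 0/1/NA).
#' @param center center each design column (default TRUE).
#' @return list with matrices \code{K_a}, \code{K_d} and the normalization
#'   constants \code{c_a}, \code{c_d} (mean raw diagonals).
#' @export
compute_first_order_kinships <- function(Z, W, center = TRUE) {
  Z <- .prep_design(Z, center); W <- .prep_design(W, center)
  norm_k <- function(K) {
    c0 <- mean(diag(K))
    if (c0 <= .Machine$double.eps) {
      warning("zero-variance design; kernel of ones returned")
      return(list(K = matrix(1, nrow(K), ncol(K),
                             dimnames = dimnames(K)), c = 0))
    }
    list(K = K / c0, c = c0)
  }
  ka <- norm_k(tcrossprod(Z))
  kd <- norm_k(tcrossprod(W))
  list(K_a = ka$K, K_d = kd$K, c_a = ka$c, c_d = kd$c)
}

#' Epistatic kinship kernels via closed-form Hadamard identities
#'
#' The three pairwise-interaction kernels are the cross-products of the
#' element-wise-product design vectors over marker pairs:
#' unordered pairs k < k' for additive-by-additive and
#' dominance-by-dominance, ordered pairs k != k' for additive-by-dominance.
#' They are computed without pair enumeration using
#' raw K_aa = (G_a o G_a - D_a) / 2 with G_a = Z Z' and
#' D_a = (Z o Z)(Z o Z)' (the self-pair correction), raw K_dd analogously
#' from W, and raw K_ad = G_a o G_d - (Z o W)(Z o W)'. Each kernel is then
#' rescaled to mean diagonal 1.
#'
#' @inheritParams compute_first_order_kinships
#' @return list with \code{K_aa}, \code{K_ad}, \code{K_dd} and the
#'   normalization constants \code{c_aa}, \code{c_ad}, \code{c_dd}.
#' @export
compute_epistatic_kinships <- function(Z, W, center = TRUE) {
  Z <- .prep_design(Z, center); W <- .prep_design(W, center)
  n <- nrow(Z)
  if (ncol(Z) < 2) {
    warning("fewer than two markers; epistatic kernels are zero")
    zero <- matrix(0, n, n, dimnames = list(rownames(Z), rownames(Z)))
    return(list(K_aa = zero, K_ad = zero, K_dd = zero,
                c_aa = 0, c_ad = 0, c_dd = 0))
  }
  Ga <- tcrossprod(Z); Gd <- tcrossprod(W)
  raw_aa <- (Ga * Ga - tcrossprod(Z * Z)) / 2
  raw_dd <- (Gd * Gd - tcrossprod(W * W)) / 2
  raw_ad <- Ga * Gd - tcrossprod(Z * W)
  norm_k <- function(K) {
    c0 <- mean(diag(K))
    if (abs(c0) <= .Machine$double.eps) return(list(K = K * 0, c = 0))
    list(K = K / c0, c = c0)
  }
  aa <- norm_k(raw_aa); ad <- norm_k(raw_ad); dd <- norm_k(raw_dd)
  list(K_aa = aa$K, K_ad = ad$K, K_dd = dd$K,
       c_aa = aa$c, c_ad = ad$c, c_dd = dd$c)
}

#' Build the full five-kernel set for a hybrid coding
#'
#' @param coding a \code{hybrid_coding}.
#' @return object of class \code{kinship_set}: list with K_a, K_d, K_aa,
#'   K_ad, K_dd and the normalization constants.
#' @export
compute_kinship_set <- function(coding) {
  fo <- compute_first_order_kinships(coding$Z, coding$W)
  ep <- compute_epistatic_kinships(coding$Z, coding$W)
  structure(c(fo[c("K_a", "K_d")], ep[c("K_aa", "K_ad", "K_dd")],
              fo[c("c_a", "c_d")], ep[c("c_aa", "c_ad", "c_dd")]),
            class = "kinship_set")
}

# Brute-force pair-enumeration construction of the epistatic kernels; the
# O(m^2) oracle that the Hadamard identities are tested against.
enumerate_epistatic_kinships <- function(Z, W, center = TRUE) {
  Z <- .prep_design(Z, center); W <- .prep_design(W, center)
  n <- nrow(Z); m <- ncol(Z)
  raw_aa <- raw_ad <- raw_dd <- matrix(0, n, n)
  for (k in seq_len(m)) for (kp in seq_len(m)) {
    if (kp > k) {
      raw_aa <- raw_aa + tcrossprod(Z[, k] * Z[, kp])
      raw_dd <- raw_dd + tcrossprod(W[, k] * W[, kp])
    }
    if (kp != k) raw_ad <- raw_ad + tcrossprod(Z[, k] * W[, kp])
  }
  norm_k <- function(K) {
    c0 <- mean(diag(K))
    if (abs(c0) <= .Machine$double.eps) return(K * 0)
    K / c0
  }
  list(K_aa = norm_k(raw_aa), K_ad = norm_k(raw_ad), K_dd = norm_k(raw_dd))
}
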