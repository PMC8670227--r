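#' GBLUP fit and prediction with additive (and dominance) kernels
#'
#' Fits y = X beta + xi_a (+ xi_d) + eps on the training individuals by
#' multi-kernel REML and predicts the test individuals by BLUP:
#' xi_hat(test) = sigma2_x K_x[test, train] V^-1 (y - X beta_hat).
#' Optional fixed SNP columns (weighted genomic selection, wGS) enter the
#' fixed-effect design; constant columns on the training set are dropped
#' with a warning. With no fixed SNPs, wGS reduces exactly to GS.
#'
#' @param y named phenotype vector covering the training ids.
#' @param kinships named list of joint kernels over train + test individuals
#'   (entries "a" and optionally "d"), rows/cols named by id.
#' @param train_ids,test_ids id vectors.
#' @param fixed_snps optional matrix of marker codes (rows = all
#'   individuals, named) used as fixed effects.
#' @return list with \code{predictions} (named, test ids), \code{varcomp}
#'   (the REML fit), \code{beta}.
#' @export
gblup_fit_predict <- function(y, kinships, train_ids, test_ids,
                              fixed_snps = NULL) {
  kl <- as_kernel_list(kinships)
  stopifnot(all(train_ids %in% rownames(kl[[1]])),
            all(test_ids %in% rownames(kl[[1]])))
  y_tr <- y[train_ids]
  n_tr <- length(train_ids)
  X_tr <- matrix(1, n_tr, 1)
  X_te <- matrix(1, length(test_ids), 1)
  if (!is.null(fixed_snps)) {
    fixed_snps <- as.matrix(fixed_snps)
    keep <- apply(fixed_snps[train_ids, , drop = FALSE], 2,
                  function(col) stats::var(col, na.rm = TRUE) > 0)
    if (any(!keep))
      warning("dropping constant fixed-SNP column(s): ",
              paste(colnames(fixed_snps)[!keep], collapse = ", "))
    if (any(keep)) {
      fs <- impute_column_means(fixed_snps[, keep, drop = FALSE])
      X_tr <- cbind(X_tr, fs[train_ids, , drop = FALSE])
      X_te <- cbind(X_te, fs[test_ids, , drop = FALSE])
    }
  }
  kl_tr <- lapply(kl, function(K) K[train_ids, train_ids])
  vc <- estimate_polygenic_varcomps(y_tr, X_tr, kl_tr, backend = "reml")
  s2 <- vc$sigma2
  V <- diag(s2[["residual"]], n_tr)
  for (nm in names(kl)) V <- V + s2[[nm]] * kl_tr[[nm]]
  ch <- chol(V)
  Vi <- chol2inv(ch)
  beta <- solve(crossprod(X_tr, Vi %*% X_tr), crossprod(X_tr, Vi %*% y_tr))
  r <- Vi %*% (y_tr - X_tr %*% beta)
  pred <- as.numeric(X_te %*% beta)
  for (nm in names(kl))
    pred <- pred + as.numeric(s2[[nm]] * kl[[nm]][test_ids, train_ids] %*% r)
  names(pred) <- test_ids
  list(predictions = pred, varcomp = vc, beta = as.numeric(beta))
}

#' Cross-validation partitions for the NCII prediction schemes
#'
#' \itemize{
#' \item \code{within}: random \code{nfolds}-fold split inside one
#'   population.
#' \item \code{CV1}: across-population prediction — fold 1 trains on the
#'   entire first tester population and tests on the entire second, fold 2
#'   the reverse.
#' \item \code{CV2}: RILs are split in half; the training set contains the
#'   hybrids of the training RILs under \emph{both} testers (training
#'   hybrids share the same RILs across TC and TM), the test set the rest.
#' \item \code{CV3}: RILs are split in half; the training set contains the
#'   first-half RILs under tester 1 and the second-half RILs under tester 2
#'   (training hybrids use disjoint RIL sets across testers), so every test
#'   hybrid's RIL is in training under the other tester.
#' }
#'
#' @param links data.frame hybrid, ril, tester (the \code{parent_links} of a
#'   hybrid coding; for \code{within} a single population's links).
#' @param scheme one of "within", "CV1", "CV2", "CV3".
#' @param nfolds folds per repeat (2 in the study design).
#' @param repeats number of repeats (200 in the study design).
#' @param seed integer seed; partitions are deterministic given the seed.
#' @return list of partitions, each a list(train, test, fold, repeat_idx).
#' @export
make_cv_partitions <- function(links, scheme = c("within", "CV1", "CV2", "CV3"),
                               nfolds = 2, repeats = 200, seed = 1L) {
  scheme <- match.arg(scheme)
  testers <- unique(links$tester)
  if (scheme != "within" && length(testers) != 2)
    stop(scheme, " requires exactly two tester populations")
  set.seed(seed)
  parts <- list()
  for (rep_i in seq_len(repeats)) {
    if (scheme == "within") {
      ids <- sample(links$hybrid)
      fold_of <- rep_len(seq_len(nfolds), length(ids))
      for (f in seq_len(nfolds)) {
        te <- ids[fold_of == f]
        parts[[length(parts) + 1]] <- list(train = setdiff(links$hybrid, te),
                                           test = te, fold = f,
                                           repeat_idx = rep_i)
      }
    } else if (scheme == "CV1") {
      for (f in seq_len(2)) {
        tr_pop <- testers[f]; te_pop <- testers[3 - f]
        parts[[length(parts) + 1]] <- list(
          train = links$hybrid[links$tester == tr_pop],
          test = links$hybrid[links$tester == te_pop],
          fold = f, repeat_idx = rep_i)
      }
    } else {
      rils <- unique(links$ril)
      half <- sample(rils, floor(length(rils) / 2))
      other <- setdiff(rils, half)
      halves <- list(half, other)
      for (f in seq_len(2)) {
        A <- halves[[f]]; B <- halves[[3 - f]]
        if (scheme == "CV2") {
          tr <- links$hybrid[links$ril %in% A]
        } else {
          tr <- links$hybrid[(links$ril %in% A & links$tester == testers[1]) |
                               (links$ril %in% B & links$tester == testers[2])]
        }
        parts[[length(parts) + 1]] <- list(train = tr,
                                           test = setdiff(links$hybrid, tr),
                                           fold = f, repeat_idx = rep_i)
      }
    }
  }
  parts
}

#' Run a cross-validation experiment
#'
#' For each partition, fits GBLUP (additive-only for CV1 across-population
#' prediction, additive + dominance otherwise) on the training hybrids and
#' correlates predictions with the observed values of the test hybrids. For
#' wGS the fixed significant markers are re-derived from the training
#' portion only via \code{fixed_snp_rule}, so test phenotypes are never
#' touched by marker selection.
#'
#' @param y named phenotype vector over all hybrids.
#' @param kinships joint kernels (list with "a" and "d").
#' @param partitions from \code{\link{make_cv_partitions}}.
#' @param model "GS" or "wGS".
#' @param use_dominance include the dominance kernel (TRUE for CV2/CV3,
#'   FALSE for CV1).
#' @param fixed_snp_rule for wGS: function(train_ids) returning a matrix of
#'   fixed marker columns over all hybrids (or NULL for none).
#' @return list with \code{results} (data.frame fold, repeat_idx, accuracy)
#'   and \code{summary} (mean, sd over defined accuracies).
#' @export
run_cross_validation <- function(y, kinships, partitions, model = c("GS", "wGS"),
                                 use_dominance = TRUE, fixed_snp_rule = NULL) {
  model <- match.arg(model)
  if (model == "wGS" && is.null(fixed_snp_rule))
    stop("wGS needs a fixed_snp_rule")
  kl <- as_kernel_list(kinships)
  if (!use_dominance) kl <- kl["a"]
  rows <- lapply(partitions, function(p) {
    fs <- if (model == "wGS") fixed_snp_rule(p$train) else NULL
    fit <- gblup_fit_predict(y, kl, p$train, p$test, fixed_snps = fs)
    obs <- y[p$test]
    pred <- fit$predictions
    acc <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) NA_real_
           else stats::cor(pred, obs)
    data.frame(fold = p$fold, repeat_idx = p$repeat_idx, accuracy = acc)
  })
  res <- do.call(rbind, rows)
  list(results = res,
       summary = c(mean = mean(res$accuracy, na.rm = TRUE),
                   sd = stats::sd(res$accuracy, na.rm = TRUE),
                   n = sum(!is.na(res$accuracy))))
}

#' Default fixed-SNP rule for weighted genomic selection
#'
#' Returns a closure that maps QTL on the training hybrids only: it
#' estimates the additive background ratio by REML, whitens, runs the
#' additive main-effect scan and returns the peak-marker columns of QTL
#' passing \code{lod_threshold}. Intended for wGS inside
#' \code{\link{run_cross_validation}}.
#'
#' @param y named phenotype vector over all hybrids.
#' @param coding the (pooled) \code{hybrid_coding}.
#' @param map marker map.
#' @param kinships joint kernels (list with "a", possibly more).
#' @param lod_threshold scan threshold for fixed-marker selection.
#' @param max_snps cap on the number of fixed markers (strongest first).
#' @return function(train_ids) -> matrix of marker columns (all hybrids) or
#'   NULL when no marker passes.
#' @export
default_fixed_snp_rule <- function(y, coding, map, kinships,
                                   lod_threshold = 2.5, max_snps = 10) {
  kl <- as_kernel_list(kinships)
  Zimp <- impute_column_means(coding$Z)
  function(train_ids) {
    kl_tr <- lapply(kl["a"], function(K) K[train_ids, train_ids])
    y_tr <- y[train_ids]
    vc <- estimate_polygenic_varcomps(y_tr, NULL, kl_tr, backend = "reml")
    K <- compose_background(kl_tr, vc$lambda)
    wh <- whiten(y_tr, matrix(1, length(y_tr), 1), K)
    sc <- scan_main_effects(wh, coding$Z[train_ids, , drop = FALSE],
                            coding$W[train_ids, , drop = FALSE], map,
                            effects = "add")
    qt <- call_qtl_intervals(sc, lod_threshold = lod_threshold)
    if (nrow(qt) == 0) return(NULL)
    qt <- qt[order(-qt$peak_lod), ]
    mks <- utils::head(qt$peak_marker, max_snps)
    Zimp[, mks, drop = FALSE]
  }
}
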