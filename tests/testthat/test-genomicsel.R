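test_that("GBLUP predictions match the closed-form kernel solution", {
  d <- random_design(6, 8, seed = 121)
  kin <- compute_first_order_kinships(d$Z, d$W)
  kl <- list(a = kin$K_a, d = kin$K_d)
  set.seed(122)
  y <- setNames(rnorm(6), rownames(d$Z))
  train <- rownames(d$Z)[1:4]; test <- rownames(d$Z)[5:6]
  fit <- gblup_fit_predict(y, kl, train, test)
  s2 <- fit$varcomp$sigma2
  want <- gblup_oracle(y[train], train, test, kl,
                       s2[c("a", "d")], s2[["residual"]])
  expect_equal(fit$predictions, want, tolerance = 1e-8)
})

test_that("GBLUP is intercept-equivariant and wGS reduces to GS without SNPs", {
  ts <- tiny_study(seed = 131, n_ril = 40)
  kin <- compute_kinship_set(ts$study$pooled)
  kl <- as_kernel_list(kin)[c("a", "d")]
  ids <- rownames(ts$study$pooled$Z)
  set.seed(132)
  y <- setNames(as.numeric(t(chol(kin$K_a + diag(80))) %*% rnorm(80)), ids)
  train <- ids[1:60]; test <- ids[61:80]
  f1 <- gblup_fit_predict(y, kl, train, test)
  y2 <- y; y2[train] <- y2[train] + 5
  f2 <- gblup_fit_predict(y2, kl, train, test)
  expect_equal(f2$predictions, f1$predictions + 5, tolerance = 1e-6)
  f3 <- gblup_fit_predict(y, kl, train, test, fixed_snps = NULL)
  expect_identical(f1$predictions, f3$predictions)
  # constant fixed-SNP column is dropped with a warning
  fs <- cbind(const = rep(1, 80), ok = as.numeric(ts$study$pooled$Z[, 3]))
  rownames(fs) <- ids
  expect_warning(gblup_fit_predict(y, kl, train, test, fixed_snps = fs),
                 "constant")
})

test_that("cross-validation partitions implement the three NCII schemes", {
  ts <- tiny_study(seed = 141, n_ril = 20)
  links <- ts$study$pooled$parent_links
  # counting: 2 folds x 3 repeats = 6 partitions
  p_w <- make_cv_partitions(links[links$tester == "TC", ], "within",
                            nfolds = 2, repeats = 3, seed = 1)
  expect_equal(length(p_w), 6)
  for (p in p_w) expect_length(intersect(p$train, p$test), 0)
  # CV1: whole-population transfer
  p1 <- make_cv_partitions(links, "CV1", repeats = 1, seed = 1)
  expect_setequal(p1[[1]]$train, links$hybrid[links$tester == "TC"])
  expect_setequal(p1[[1]]$test, links$hybrid[links$tester == "TM"])
  # CV2: training hybrids share the same RILs across the two testers
  p2 <- make_cv_partitions(links, "CV2", repeats = 2, seed = 3)
  for (p in p2) {
    tr <- links[links$hybrid %in% p$train, ]
    expect_setequal(tr$ril[tr$tester == "TC"], tr$ril[tr$tester == "TM"])
  }
  # CV3: disjoint training RIL sets across testers; every test hybrid's RIL
  # is in training under the other tester
  p3 <- make_cv_partitions(links, "CV3", repeats = 2, seed = 5)
  for (p in p3) {
    tr <- links[links$hybrid %in% p$train, ]
    te <- links[links$hybrid %in% p$test, ]
    expect_length(intersect(tr$ril[tr$tester == "TC"],
                            tr$ril[tr$tester == "TM"]), 0)
    for (i in seq_len(nrow(te))) {
      other <- setdiff(c("TC", "TM"), te$tester[i])
      expect_true(te$ril[i] %in% tr$ril[tr$tester == other])
    }
  }
  # determinism under the seed
  p3b <- make_cv_partitions(links, "CV3", repeats = 2, seed = 5)
  expect_identical(p3, p3b)
  expect_error(make_cv_partitions(links[links$tester == "TC", ], "CV2"),
               "two tester")
})

test_that("cross-validation accuracy behaves sanely at null and rising h2", {
  ts <- tiny_study(seed = 151, n_ril = 40)
  st <- ts$study
  kin <- compute_kinship_set(st$pooled)
  kl <- as_kernel_list(kin)[c("a", "d")]
  ids <- rownames(st$pooled$Z)
  parts <- make_cv_partitions(st$pooled$parent_links, "CV2", repeats = 5,
                              seed = 2)
  # null trait: mean accuracy within Monte-Carlo error of zero
  set.seed(152)
  y0 <- setNames(rnorm(80), ids)
  cv0 <- run_cross_validation(y0, kl, parts, model = "GS")
  expect_lt(abs(cv0$summary[["mean"]]),
            3 * cv0$summary[["sd"]] / sqrt(cv0$summary[["n"]]) + 0.15)
  # accuracy rises with heritability
  g <- as.numeric(t(chol(kin$K_a + 1e-8 * diag(80))) %*% rnorm(80))
  g <- g / sd(g)
  acc <- sapply(c(0.2, 0.8), function(h2) {
    yh <- setNames(g * sqrt(h2) + rnorm(80, 0, sqrt(1 - h2)), ids)
    run_cross_validation(yh, kl, parts, model = "GS")$summary[["mean"]]
  })
  expect_gt(acc[2], acc[1])
  # determinism: identical partitions + data give identical summaries
  cv0b <- run_cross_validation(y0, kl, parts, model = "GS")
  expect_identical(cv0$summary, cv0b$summary)
})

test_that("the default wGS rule only ever sees training hybrids", {
  ts <- tiny_study(seed = 161, n_ril = 30)
  st <- ts$study
  kin <- compute_kinship_set(st$pooled)
  kl <- as_kernel_list(kin)[c("a", "d")]
  ids <- rownames(st$pooled$Z)
  set.seed(162)
  y <- setNames(rnorm(60) + 1.5 * ifelse(is.na(st$pooled$Z[, 7]), 0,
                                         st$pooled$Z[, 7]), ids)
  parts <- make_cv_partitions(st$pooled$parent_links, "CV2", repeats = 2,
                              seed = 3)
  seen <- list()
  audit_rule <- local({
    inner <- default_fixed_snp_rule(y, st$pooled, st$ril$map, kl,
                                    lod_threshold = 1)
    function(train_ids) {
      seen[[length(seen) + 1]] <<- train_ids
      inner(train_ids)
    }
  })
  cv <- run_cross_validation(y, kl, parts, model = "wGS",
                             fixed_snp_rule = audit_rule)
  expect_equal(length(seen), length(parts))
  for (i in seq_along(parts))
    expect_length(intersect(seen[[i]], parts[[i]]$test), 0)
  expect_true(is.finite(cv$summary[["mean"]]))
})
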