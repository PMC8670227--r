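test_that("a strong simulated additive QTL is found at the right place", {
  cfg <- sim_config(n_ril = 150, n_chromosomes = 2, markers_per_chrom = 40,
                    map_length_cM = 100, tester_similarity = 0.5,
                    residual_het_rate = 0, seed = 81)
  st <- simulate_ncii_study(cfg)
  map <- st$ril$map
  qtl_idx <- 20
  set.seed(82)
  z <- st$pooled$Z[, qtl_idx]
  z[is.na(z)] <- 0
  y <- 0.8 * z + rnorm(length(z), 0, 1)
  X <- cbind(1, st$pooled$population)
  # null background: this test exercises the scan mechanics in isolation
  wh <- whiten(y, X, matrix(0, length(y), length(y)))
  sc <- scan_main_effects(wh, st$pooled$Z, st$pooled$W, map,
                          effects = "add", dataset = "pooled")
  peak <- sc[which.max(sc$lod), ]
  expect_gte(peak$lod, 2.5)
  expect_lte(abs(peak$cM - map$cM[qtl_idx]), 5)
  expect_equal(peak$chrom, map$chrom[qtl_idx])
  # monomorphic marker is flagged with LOD 0
  Zm <- st$pooled$Z; Zm[, 1] <- 1L
  scm <- scan_main_effects(wh, Zm, st$pooled$W, map, effects = "add")
  expect_equal(scm$lod[1], 0)
  expect_false(scm$estimable[1])
})

test_that("additive and dominance LODs coincide at tester-shared loci", {
  ts <- tiny_study(seed = 91, n_ril = 60, similarity = 0.7)
  st <- ts$study
  shared <- which(st$testers$shared)
  set.seed(92)
  y <- rnorm(nrow(st$pooled$Z))
  X <- cbind(1, st$pooled$population)
  wh <- whiten(y, X, matrix(0, length(y), length(y)))
  sc <- scan_main_effects(wh, st$pooled$Z, st$pooled$W, st$ril$map)
  add <- sc[sc$effect_type == "add", ]
  dom <- sc[sc$effect_type == "dom", ]
  complete <- colSums(is.na(st$pooled$Z)) == 0
  for (k in intersect(shared, which(complete)))
    expect_equal(add$lod[k], dom$lod[k], tolerance = 1e-10)
})

test_that("epistasis scan detects a simulated dd interaction and skips self-pairs", {
  cfg <- sim_config(n_ril = 150, n_chromosomes = 2, markers_per_chrom = 30,
                    map_length_cM = 90, tester_similarity = 0.3,
                    residual_het_rate = 0, seed = 101)
  st <- simulate_ncii_study(cfg)
  map <- st$ril$map
  k1 <- 10; k2 <- 45
  set.seed(102)
  w1 <- st$pooled$W[, k1]; w2 <- st$pooled$W[, k2]
  y <- 1.6 * w1 * w2 + rnorm(length(w1))
  X <- cbind(1, st$pooled$population)
  wh <- whiten(y, X, matrix(0, length(y), length(y)))
  sc <- scan_epistasis(wh, st$pooled$Z, st$pooled$W, map, type = "dd",
                       step = 1)
  hit <- sc[which.max(sc$lod), ]
  expect_gte(hit$lod, 5)
  expect_lte(abs(hit$cM1 - map$cM[k1]), 5)
  expect_lte(abs(hit$cM2 - map$cM[k2]), 5)
  # anchor mode never pairs the anchor with itself
  sca <- scan_epistasis(wh, st$pooled$Z, st$pooled$W, map, type = "aa",
                        anchor = k1)
  expect_false(map$marker[k1] %in% sca$marker2)
  expect_equal(nrow(sca), nrow(map) - 1)
})

test_that("interval calling reproduces a hand-enumerated LOD profile", {
  prof <- data.frame(marker = paste0("m", 1:6), chrom = 1,
                     cM = seq(0, 10, by = 2),
                     lod = c(1, 2, 6, 4, 4.4, 1),
                     effect = 1, pve = 0.1, effect_type = "add",
                     dataset = "pooled", trait = "EH",
                     stringsAsFactors = FALSE)
  q <- call_qtl_intervals(prof, lod_threshold = 2.5, window_cM = 10,
                          drop = 1.5)
  expect_equal(nrow(q), 1)
  expect_equal(q$peak_marker, "m3")
  # support = contiguous markers with LOD >= 6 - 1.5 = 4.5: the peak itself
  expect_equal(c(q$start_cM, q$end_cM), c(4, 4))
  expect_equal(q$name, "pooled-qEH1")
  # no super-threshold marker: empty result
  expect_equal(nrow(call_qtl_intervals(transform(prof, lod = lod / 10),
                                       lod_threshold = 2.5)), 0)
  # two peaks far apart both called
  prof2 <- data.frame(marker = paste0("m", 1:7), chrom = 1,
                      cM = c(0, 5, 10, 20, 30, 35, 40),
                      lod = c(1, 4, 1, 0.5, 1, 5, 1),
                      effect = 1, pve = 0.1, effect_type = "add",
                      dataset = "pooled", trait = "EH",
                      stringsAsFactors = FALSE)
  q2 <- call_qtl_intervals(prof2, lod_threshold = 2.5, window_cM = 10)
  expect_equal(nrow(q2), 2)
  expect_setequal(q2$peak_marker, c("m2", "m6"))
})

test_that("pleiotropy grouping respects chromosome, proximity and overlap", {
  q <- data.frame(trait = c("EH", "GY", "PH", "KT"),
                  dataset = "pooled", chrom = c(1, 1, 1, 2),
                  peak_marker = paste0("p", 1:4),
                  peak_cM = c(10, 10.5, 40, 10),
                  peak_lod = 5, start_cM = c(9, 10.2, 38, 9),
                  end_cM = c(11, 12, 42, 11), effect = 1, pve = 0.1,
                  effect_type = "add", name = paste0("q", 1:4),
                  stringsAsFactors = FALSE)
  g <- group_pleiotropic(q, proximity_cM = 0.65)
  expect_equal(g$group[1], g$group[2])    # peaks 0.5 cM apart
  expect_false(g$group[1] == g$group[3])  # 30 cM away
  expect_false(g$group[1] == g$group[4])  # different chromosome
  # transitive closure through a chain of overlaps
  q2 <- q
  q2$chrom <- 1
  q2$start_cM <- c(0, 4, 8, 12); q2$end_cM <- c(5, 9, 13, 17)
  q2$peak_cM <- c(2, 6, 10, 14)
  g2 <- group_pleiotropic(q2)
  expect_equal(length(unique(g2$group)), 1)
})

test_that("PVE is the RSS ratio complement, clipped at zero", {
  expect_equal(compute_pve(5, 5), 0)
  expect_equal(compute_pve(0, 5), 1)
  expect_warning(p <- compute_pve(6, 5), "clipped")
  expect_equal(p, 0)
  set.seed(7)
  x <- rnorm(50); y <- x + rnorm(50)
  f1 <- lm(y ~ x); f0 <- lm(y ~ 1)
  expect_equal(compute_pve(sum(resid(f1)^2), sum(resid(f0)^2)),
               summary(f1)$r.squared, tolerance = 1e-12)
})

test_that("favorable-QTL analysis classifies loci and correlates counts", {
  ts <- tiny_study(seed = 111, n_ril = 120, similarity = 0.4)
  st <- ts$study
  coding <- st$coding_tc
  mks <- colnames(coding$Z)[c(10, 25, 40)]
  set.seed(112)
  # overdominant architecture: heterozygote best at every locus
  W <- coding$W; W[is.na(W)] <- 0
  perf_od <- rowSums(W[, mks]) * 2 + rnorm(nrow(W), 0, 0.1)
  names(perf_od) <- rownames(W)
  qtls <- data.frame(peak_marker = mks, trait = "GY", dataset = "TC",
                     stringsAsFactors = FALSE)
  fav <- favorable_qtl_analysis(qtls, coding$Z, coding$W, perf_od)
  expect_true(all(fav$qtl_class$class == "heterozygous"))
  expect_equal(fav$counts$total, fav$counts$hom + fav$counts$het)
  # additive-only architecture: total-count correlation positive, significant
  Z <- coding$Z; Z[is.na(Z)] <- 0
  perf_add <- as.numeric(Z[, mks] %*% c(1, 1, 1)) + rnorm(nrow(Z), 0, 1)
  names(perf_add) <- rownames(Z)
  fav2 <- favorable_qtl_analysis(qtls, coding$Z, coding$W, perf_add)
  expect_gt(fav2$correlations["r3", "r"], 0)
  expect_lt(fav2$correlations["r3", "p"], 0.05)
  expect_error(favorable_qtl_analysis(qtls[0, ], coding$Z, coding$W,
                                      perf_add), "at least one QTL")
})
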