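#' Genome scan for main (additive and dominance) effects
#'
#' Per marker, tests the whitened additive column Z_k (and/or the dominance
#' column W_k) against the whitened null model by maximum-likelihood ratio;
#' LOD = LRT / 4.61. For midparent-heterosis datasets only the dominance
#' test is meaningful (additive effects do not contribute to MPH), so pass
#' \code{effects = "dom"}. Missing marker codes are mean-imputed per column
#' before whitening; monomorphic markers are flagged with LOD 0.
#'
#' @param wh a \code{whitened_data} for the trait/dataset (background
#'   lambdas already composed into K).
#' @param Z,W raw design matrices (hybrids x markers).
#' @param map marker map (marker, chrom, cM) in Z column order.
#' @param effects subset of c("add", "dom").
#' @param dataset label recorded in the result (e.g. "TC-TM").
#' @param trait trait label.
#' @return data.frame of class \code{scan_result}: one row per marker x
#'   effect with columns marker, chrom, cM, effect_type, lrt, lod, effect,
#'   pve, estimable.
#' @export
scan_main_effects <- function(wh, Z, W, map, effects = c("add", "dom"),
                              dataset = "pooled", trait = "trait1") {
  effects <- match.arg(effects, several.ok = TRUE)
  stopifnot(identical(map$marker, colnames(Z)))
  designs <- list(add = impute_column_means(Z), dom = impute_column_means(W))
  out <- list()
  for (ef in effects) {
    M <- designs[[ef]]
    Ms <- whiten_columns(wh, M)
    rows <- lapply(seq_len(ncol(M)), function(k) {
      mono <- stats::var(M[, k]) < .Machine$double.eps
      if (mono) {
        data.frame(marker = map$marker[k], chrom = map$chrom[k],
                   cM = map$cM[k], effect_type = ef, lrt = 0, lod = 0,
                   effect = NA_real_, pve = 0, estimable = FALSE,
                   stringsAsFactors = FALSE)
      } else {
        t_ <- ml_lrt(wh, test_cols = Ms[, k, drop = FALSE])
        data.frame(marker = map$marker[k], chrom = map$chrom[k],
                   cM = map$cM[k], effect_type = ef, lrt = t_$lrt,
                   lod = t_$lod, effect = unname(t_$effects[1]),
                   pve = t_$pve, estimable = t_$estimable,
                   stringsAsFactors = FALSE)
      }
    })
    out[[ef]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$dataset <- dataset; res$trait <- trait
  class(res) <- c("scan_result", class(res))
  res
}

#' Pairwise epistasis scan
#'
#' For each marker pair (k, k'), tests the element-wise product of the two
#' whitened design columns against the two-main-effect null:
#' additive-by-additive uses (Z_k*, Z_k'*) mains with Z_k* o Z_k'*;
#' additive-by-dominance uses (Z_k*, W_k'*) with Z_k* o W_k'*;
#' dominance-by-additive uses the same mains with W_k* o Z_k'*;
#' dominance-by-dominance uses (W_k*, W_k'*) with W_k* o W_k'*.
#' Supports an explicit pair list, an exhaustive scan over all pairs
#' (optionally thinned to every \code{step}-th marker), or a fixed-anchor
#' scan of one marker against all others.
#'
#' @inheritParams scan_main_effects
#' @param type one of "aa", "ad", "da", "dd".
#' @param pairs optional 2-column matrix of marker indices.
#' @param anchor optional marker index (or name) scanned against all other
#'   markers.
#' @param step thinning step for the exhaustive mode.
#' @return data.frame of class \code{scan_result} with one row per pair:
#'   marker1, marker2, effect_type, lrt, lod, effect, pve, estimable.
#' @export
scan_epistasis <- function(wh, Z, W, map, type = c("aa", "ad", "da", "dd"),
                           pairs = NULL, anchor = NULL, step = 1,
                           dataset = "pooled", trait = "trait1") {
  type <- match.arg(type)
  m <- ncol(Z)
  Zs <- whiten_columns(wh, impute_column_means(Z))
  Ws <- whiten_columns(wh, impute_column_means(W))
  if (is.null(pairs)) {
    if (!is.null(anchor)) {
      if (is.character(anchor)) anchor <- match(anchor, map$marker)
      others <- setdiff(seq_len(m), anchor)   # a marker is never paired with itself
      pairs <- cbind(anchor, others)
    } else {
      idx <- seq(1, m, by = step)
      pairs <- t(utils::combn(idx, 2))
    }
  }
  first <- switch(type, aa = Zs, ad = Zs, da = Ws, dd = Ws)
  second <- switch(type, aa = Zs, ad = Ws, da = Zs, dd = Ws)
  # the two-main-effect null always carries the additive (or dominance)
  # columns of both loci as used by the corresponding full model
  main1 <- switch(type, aa = Zs, ad = Zs, da = Zs, dd = Ws)
  main2 <- switch(type, aa = Zs, ad = Ws, da = Ws, dd = Ws)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    k <- pairs[i, 1]; kp <- pairs[i, 2]
    inter <- first[, k] * second[, kp]
    t_ <- ml_lrt(wh, null_cols = cbind(main1[, k], main2[, kp]),
                 test_cols = matrix(inter, ncol = 1))
    data.frame(marker1 = map$marker[k], marker2 = map$marker[kp],
               chrom1 = map$chrom[k], chrom2 = map$chrom[kp],
               cM1 = map$cM[k], cM2 = map$cM[kp], effect_type = type,
               lrt = t_$lrt, lod = t_$lod, effect = unname(t_$effects[1]),
               pve = t_$pve, estimable = t_$estimable,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$dataset <- dataset; res$trait <- trait
  class(res) <- c("scan_result", class(res))
  res
}

#' Call QTL intervals from a scan profile
#'
#' Three-step interval caller: (1) keep markers passing the LOD threshold;
#' (2) greedy peak selection in descending LOD order (ties broken by lower
#' cM), suppressing other significant markers within \code{window_cM} on the
#' same chromosome; (3) support interval = the contiguous map region around
#' each peak over which LOD >= peak - \code{drop} (1.5-LOD drop-off),
#' snapped to marker positions.
#'
#' @param scan a per-marker \code{scan_result} (single effect type).
#' @param lod_threshold significance threshold (2.5 main, 5.0 epistasis,
#'   2.0 for the favorable-QTL analysis).
#' @param window_cM peak-suppression window.
#' @param drop LOD drop defining the support interval.
#' @return data.frame with one row per QTL: trait, dataset, chrom,
#'   peak_marker, peak_cM, peak_lod, start_cM, end_cM, effect, pve, name.
#' @export
call_qtl_intervals <- function(scan, lod_threshold = 2.5, window_cM = 10,
                               drop = 1.5) {
  stopifnot(all(c("marker", "chrom", "cM", "lod") %in% names(scan)))
  qtls <- list()
  for (ch in unique(scan$chrom)) {
    prof <- scan[scan$chrom == ch, ]
    prof <- prof[order(prof$cM), ]
    sig <- which(prof$lod > lod_threshold)
    while (length(sig)) {
      ord <- sig[order(-prof$lod[sig], prof$cM[sig])]
      pk <- ord[1]
      # contiguous 1.5-LOD support region around the peak
      lo <- pk
      while (lo > 1 && prof$lod[lo - 1] >= prof$lod[pk] - drop) lo <- lo - 1
      hi <- pk
      while (hi < nrow(prof) && prof$lod[hi + 1] >= prof$lod[pk] - drop)
        hi <- hi + 1
      qtls[[length(qtls) + 1]] <- data.frame(
        trait = prof$trait[pk], dataset = prof$dataset[pk],
        chrom = ch, peak_marker = prof$marker[pk], peak_cM = prof$cM[pk],
        peak_lod = prof$lod[pk], start_cM = prof$cM[lo], end_cM = prof$cM[hi],
        effect = prof$effect[pk], pve = prof$pve[pk],
        effect_type = prof$effect_type[pk], stringsAsFactors = FALSE)
      sig <- sig[abs(prof$cM[sig] - prof$cM[pk]) > window_cM]
    }
  }
  if (!length(qtls))
    return(data.frame(trait = character(), dataset = character(),
                      chrom = integer(), peak_marker = character(),
                      peak_cM = numeric(), peak_lod = numeric(),
                      start_cM = numeric(), end_cM = numeric(),
                      effect = numeric(), pve = numeric(),
                      effect_type = character(), name = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, qtls)
  out <- out[order(out$chrom, out$peak_cM), ]
  rownames(out) <- NULL
  # QTL named per the rice-nomenclature convention with a dataset prefix
  out$name <- paste0(out$dataset, "-q", out$trait, out$chrom)
  dup <- stats::ave(seq_len(nrow(out)), out$name, FUN = seq_along)
  multi <- out$name %in% out$name[duplicated(out$name)]
  out$name[multi] <- paste0(out$name[multi], ".", dup[multi])
  out
}

#' Group QTL into pleiotropic clusters
#'
#' QTL (possibly across traits and datasets) are merged into one group when
#' they sit on the same chromosome and their support intervals overlap or
#' their peaks are within \code{proximity_cM} of each other; grouping is the
#' transitive closure of this relation.
#'
#' @param qtls data.frame from \code{\link{call_qtl_intervals}} (rows may
#'   come from several traits/datasets but share one map).
#' @param proximity_cM peak-distance rule (default 0.65 cM, the genome-wide
#'   average bin spacing).
#' @return the input with an added integer \code{group} column.
#' @export
group_pleiotropic <- function(qtls, proximity_cM = 0.65) {
  n <- nrow(qtls)
  if (n == 0) { qtls$group <- integer(0); return(qtls) }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (qtls$chrom[i] != qtls$chrom[j]) next
    overlap <- qtls$start_cM[i] <= qtls$end_cM[j] &&
      qtls$start_cM[j] <= qtls$end_cM[i]
    near <- abs(qtls$peak_cM[i] - qtls$peak_cM[j]) <= proximity_cM
    if (overlap || near) parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  qtls$group <- match(roots, unique(roots))
  qtls
}

#' Proportion of phenotypic variance explained
#'
#' PVE = 1 - RSS_full / RSS_null; negative values (full RSS above null RSS,
#' possible only through numerical noise) are clipped to 0 with a warning.
#'
#' @param rss_full,rss_null residual sums of squares of the nested models.
#' @return PVE in [0, 1].
#' @export
compute_pve <- function(rss_full, rss_null) {
  stopifnot(rss_null > 0)
  if (rss_full > rss_null) {
    warning("RSS_full exceeds RSS_null; PVE clipped to 0")
    return(0)
  }
  1 - rss_full / rss_null
}

#' Favorable-QTL analysis
#'
#' Classifies each QTL as heterozygous-favorable (the heterozygote class
#' outperforms the homozygote classes on the hybrid performance) or
#' homozygous-favorable (otherwise, with the better homozygote as the
#' favorable class), counts the favorable QTL carried by each hybrid, and
#' correlates the counts with performance: r1 = homozygous-favorable count,
#' r2 = heterozygous-favorable count, r3 = total.
#'
#' @param qtls data.frame with a \code{peak_marker} column (scan at
#'   LOD >= 2.0 by convention).
#' @param Z,W hybrid design matrices over all markers.
#' @param performance named numeric vector of hybrid performance (BLUEs).
#' @return list with \code{qtl_class} (per-QTL classification),
#'   \code{counts} (per-hybrid data.frame hom, het, total), and
#'   \code{correlations} (r1, r2, r3 with p-values).
#' @export
favorable_qtl_analysis <- function(qtls, Z, W, performance) {
  if (nrow(qtls) < 1) stop("at least one QTL is required")
  ids <- rownames(Z)
  performance <- performance[ids]
  cls <- character(0); fav_geno <- character(0); kept <- integer(0)
  hom_cnt <- het_cnt <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_len(nrow(qtls))) {
    mk <- qtls$peak_marker[i]
    z <- Z[, mk]; w <- W[, mk]
    classes <- list(hom_p = !is.na(z) & z == 1, hom_m = !is.na(z) & z == -1,
                    het = !is.na(w) & w == 1)
    means <- vapply(classes, function(sel)
      if (any(sel)) mean(performance[sel], na.rm = TRUE) else NA_real_,
      numeric(1))
    present <- !is.na(means)
    if (is.na(means["het"]) || sum(present[c("hom_p", "hom_m")]) == 0) {
      warning("genotype class absent at ", mk, "; QTL skipped")
      next
    }
    kept <- c(kept, i)
    best_hom <- max(means[c("hom_p", "hom_m")], na.rm = TRUE)
    if (means[["het"]] > best_hom) {
      cls <- c(cls, "heterozygous"); fav_geno <- c(fav_geno, "het")
      het_cnt <- het_cnt + as.numeric(classes$het)
    } else {
      which_hom <- if (is.na(means[["hom_p"]]) ||
                       (!is.na(means[["hom_m"]]) &&
                        means[["hom_m"]] >= means[["hom_p"]])) "hom_m" else "hom_p"
      cls <- c(cls, "homozygous"); fav_geno <- c(fav_geno, which_hom)
      hom_cnt <- hom_cnt + as.numeric(classes[[which_hom]])
    }
  }
  if (!length(kept)) stop("no QTL with all genotype classes present")
  tot <- hom_cnt + het_cnt
  ctest <- function(x) {
    if (stats::sd(x) == 0) return(c(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x, performance)
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  list(qtl_class = data.frame(qtls[kept, c("peak_marker", "trait", "dataset")],
                              class = cls, favorable = fav_geno,
                              stringsAsFactors = FALSE),
       counts = data.frame(hybrid = ids, hom = hom_cnt, het = het_cnt,
                           total = tot, stringsAsFactors = FALSE),
       correlations = rbind(r1 = ctest(hom_cnt), r2 = ctest(het_cnt),
                            r3 = ctest(tot)))
}
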