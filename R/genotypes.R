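#' Derive additive/dominance hybrid codes from RIL and tester genotypes
#'
#' Hybrid genotypes are inferred from the parents. RIL and tester genotypes
#' are coded relative to the two RIL parents (+1 = first-parent allele,
#' -1 = second-parent allele). At each locus: equal parental alleles give a
#' homozygote (Z = that allele's code, W = 0); unequal alleles give a
#' heterozygote (Z = 0, W = 1); a missing parent gives missing hybrid codes.
#'
#' @param ril matrix of RIL codes (individuals x markers, values +1/-1/NA).
#' @param tester named integer vector of tester codes over the same markers.
#' @param suffix label appended to hybrid ids (e.g. "TC").
#' @param population_indicator 0/1 value for every hybrid in this population
#'   (0 = first tester population).
#' @return object of class \code{hybrid_coding}: list with matrices \code{Z}
#'   (entries 1/0/-1/NA) and \code{W} (entries 0/1/NA), \code{population}
#'   (0/1 per hybrid) and \code{parent_links} (data.frame hybrid, ril,
#'   tester).
#' @export
derive_hybrid_codes <- function(ril, tester, suffix = "H",
                                population_indicator = 0L) {
  if (is.null(names(tester))) names(tester) <- colnames(ril)
  if (!setequal(colnames(ril), names(tester))) {
    off <- union(setdiff(colnames(ril), names(tester)),
                 setdiff(names(tester), colnames(ril)))
    stop("marker sets differ between RILs and tester: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  tester <- tester[colnames(ril)]
  tmat <- matrix(tester, nrow(ril), ncol(ril), byrow = TRUE)
  Z <- ifelse(ril == tmat, ril, 0L)
  W <- ifelse(ril == tmat, 0L, 1L)
  miss <- is.na(ril) | is.na(tmat)
  Z[miss] <- NA_integer_; W[miss] <- NA_integer_
  ids <- paste0(rownames(ril), "_", suffix)
  dimnames(Z) <- dimnames(W) <- list(ids, colnames(ril))
  structure(list(Z = Z, W = W,
                 population = rep(as.integer(population_indicator), nrow(ril)),
                 parent_links = data.frame(hybrid = ids, ril = rownames(ril),
                                           tester = suffix,
                                           stringsAsFactors = FALSE)),
            class = "hybrid_coding")
}

#' Design coding for the RIL population itself
#'
#' RILs are (near-)fully inbred, so the additive design is the parental code
#' itself and the dominance design is all zero. Lets the RIL population run
#' through the same scan machinery as the hybrids (additive and
#' additive-by-additive terms only).
#'
#' @param ril matrix of RIL codes (individuals x markers, +1/-1/NA).
#' @return a \code{hybrid_coding} with W = 0.
#' @export
ril_coding <- function(ril) {
  W <- ril * 0L
  structure(list(Z = ril, W = W, population = rep(0L, nrow(ril)),
                 parent_links = data.frame(hybrid = rownames(ril),
                                           ril = rownames(ril),
                                           tester = "self",
                                           stringsAsFactors = FALSE)),
            class = "hybrid_coding")
}

#' Pool two hybrid populations into one coding
#'
#' Row-stacks the Z and W design matrices of the TC and TM populations and
#' sets the population indicator to 0 for the first and 1 for the second
#' population, matching the fixed population effect of the pooled model.
#'
#' @param coding_tc,coding_tm \code{hybrid_coding} objects over the same
#'   marker set.
#' @return a pooled \code{hybrid_coding}.
#' @export
pool_populations <- function(coding_tc, coding_tm) {
  if (!identical(colnames(coding_tc$Z), colnames(coding_tm$Z)))
    stop("marker sets (or their order) differ between the two populations")
  ids <- c(rownames(coding_tc$Z), rownames(coding_tm$Z))
  if (anyDuplicated(ids))
    stop("duplicated hybrid ids in pooled population: ",
         paste(utils::head(ids[duplicated(ids)], 5), collapse = ", "))
  structure(list(Z = rbind(coding_tc$Z, coding_tm$Z),
                 W = rbind(coding_tc$W, coding_tm$W),
                 population = c(rep(0L, nrow(coding_tc$Z)),
                                rep(1L, nrow(coding_tm$Z))),
                 parent_links = rbind(coding_tc$parent_links,
                                      coding_tm$parent_links)),
            class = "hybrid_coding")
}

#' Genetic distance between two mapped markers
#'
#' @param map marker map data.frame (marker, chrom, cM).
#' @param marker_a,marker_b marker ids.
#' @return absolute cM difference if the markers share a chromosome,
#'   \code{Inf} otherwise.
#' @export
genetic_distance <- function(map, marker_a, marker_b) {
  ia <- match(marker_a, map$marker); ib <- match(marker_b, map$marker)
  if (is.na(ia) || is.na(ib))
    stop("unknown marker: ",
         paste(c(marker_a, marker_b)[c(is.na(ia), is.na(ib))], collapse = ", "))
  if (map$chrom[ia] != map$chrom[ib]) return(Inf)
  abs(map$cM[ia] - map$cM[ib])
}

# Column mean imputation for design matrices; used when building kinship
# kernels and before whitening in genome scans. All-missing columns become 0.
impute_column_means <- function(M) {
  M <- apply(M, 2, function(col) {
    if (anyNA(col)) {
      mu <- mean(col, na.rm = TRUE)
      col[is.na(col)] <- if (is.nan(mu)) 0 else mu
    }
    col
  })
  M
}

#' Write / read genotype tables and maps as TSV
#'
#' The on-disk formats are plain TSV: genotype tables are individual x marker
#' with values in \{1, -1, NA\}; maps have columns marker, chrom, cM, bp;
#' trial records are long format (genotype, environment, replicate, trait,
#' value).
#'
#' @param x object to write (matrix or data.frame).
#' @param path file path.
#' @name ncii_io
#' @export
write_genotypes_tsv <- function(x, path) {
  df <- data.frame(individual = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname ncii_io
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname ncii_io
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname ncii_io
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
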