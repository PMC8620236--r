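## Population-genetic estimators on biallelic TE (and SNP) dosage matrices:
## individual heterozygosity, Nei's D, Wright and Weir-Cockerham Fst,
## PCA/PCoA and TE-vs-SNP concordance. TE markers are treated as biallelic
## co-dominant loci, so the classical SNP estimators apply directly.

#' Per-population insertion-allele frequencies
#'
#' @param matrix a `geno_matrix`.
#' @param by population column (`"subspecies"` or `"species"`).
#' @return List with `p` (loci x populations frequency matrix, `NaN` where a
#'   population has no calls) and `n` (diploid sample sizes with non-missing
#'   calls, same shape).
#' @export
pop_freqs <- function(matrix, by = "subspecies") {
  key <- matrix$populations[[by]]
  if (is.null(key)) stop("unknown population column: ", by)
  groups <- split(seq_len(ncol(matrix$geno)), key)
  n <- sapply(groups, function(j)
    rowSums(!is.na(matrix$geno[, j, drop = FALSE])))
  ac <- sapply(groups, function(j)
    rowSums(matrix$geno[, j, drop = FALSE], na.rm = TRUE))
  if (is.null(dim(n))) {  # single-locus matrices
    n <- matrix(n, nrow = 1, dimnames = list(NULL, names(groups)))
    ac <- matrix(ac, nrow = 1, dimnames = list(NULL, names(groups)))
  }
  list(p = ac / (2 * n), n = n)
}

#' Individual heterozygosity over all or segregating markers
#'
#' The proportion of heterozygous genotypes per individual,
#' n1 / (n0 + n1 + n2), over non-missing loci. `mode = "all"` uses every
#' locus (multi-locus heterozygosity, MLH); `mode = "seg"` restricts to loci
#' segregating (0 < p < 1) within the individual's assigned population,
#' excluding monomorphic markers that can only deflate the estimate. The
#' heterozygote count is the same whether alleles are polarized by insertion
#' or by minor frequency.
#'
#' @param matrix a `geno_matrix`.
#' @param mode `"all"` or `"seg"`.
#' @param by population column used for the segregation restriction.
#' @return data.frame with `sample`, `n_loci` (usable loci) and `he`
#'   (`NA` and a warning when an individual has no usable loci).
#' @export
heterozygosity <- function(matrix, mode = c("all", "seg"),
                           by = "subspecies") {
  mode <- match.arg(mode)
  g <- matrix$geno
  use <- !is.na(g)
  if (mode == "seg") {
    f <- pop_freqs(matrix, by = by)
    key <- matrix$populations[[by]]
    seg <- f$p > 0 & f$p < 1  # loci x pops
    use <- use & seg[, key, drop = FALSE]
    use[is.na(use)] <- FALSE
  }
  n_loci <- colSums(use)
  he <- colSums(g == 1L & use, na.rm = TRUE) / n_loci
  if (any(n_loci == 0)) {
    warning("individuals with no usable loci: ",
            paste(colnames(g)[n_loci == 0], collapse = ", "))
    he[n_loci == 0] <- NA_real_
  }
  data.frame(sample = colnames(g), n_loci = n_loci, he = he,
             row.names = NULL)
}

#' Nei's (1972) standard genetic distance between two populations
#'
#' For biallelic loci with insertion-allele frequencies p_a, p_b:
#' Jx = mean(p_a^2 + (1-p_a)^2), Jy likewise, Jxy = mean(p_a p_b +
#' (1-p_a)(1-p_b)); D = -ln(Jxy / sqrt(Jx Jy)). Loci missing in either
#' population are excluded.
#'
#' @param f a [pop_freqs()] result.
#' @param pop_a,pop_b population names.
#' @return D (>= 0 up to floating error; `Inf` with a warning when Jxy = 0).
#' @export
nei_distance <- function(f, pop_a, pop_b) {
  pa <- f$p[, pop_a]; pb <- f$p[, pop_b]
  ok <- is.finite(pa) & is.finite(pb)
  pa <- pa[ok]; pb <- pb[ok]
  if (!length(pa)) stop("no loci typed in both populations")
  jx <- mean(pa^2 + (1 - pa)^2)
  jy <- mean(pb^2 + (1 - pb)^2)
  jxy <- mean(pa * pb + (1 - pa) * (1 - pb))
  if (jxy == 0) {
    warning("Jxy = 0: infinite distance")
    return(Inf)
  }
  -log(jxy / sqrt(jx * jy))
}

#' Wright's Fst between two populations
#'
#' Fst = 1 - HS/HT with HS the mean within-population expected
#' heterozygosity (2p(1-p), averaged over the two populations then over
#' loci) and HT the expected heterozygosity at the across-population mean
#' frequency, averaged over loci.
#'
#' @inheritParams nei_distance
#' @return Fst in \[0, 1\] (NaN when HT = 0 at every locus).
#' @export
wright_fst <- function(f, pop_a, pop_b) {
  pa <- f$p[, pop_a]; pb <- f$p[, pop_b]
  ok <- is.finite(pa) & is.finite(pb)
  pa <- pa[ok]; pb <- pb[ok]
  hs <- mean((2 * pa * (1 - pa) + 2 * pb * (1 - pb)) / 2)
  pbar <- (pa + pb) / 2
  ht <- mean(2 * pbar * (1 - pbar))
  1 - hs / ht
}

#' Weir & Cockerham's (1984) theta between two populations
#'
#' Multi-locus ratio-of-averages estimator from the a (among-population),
#' b (among individuals within populations) and c (within-individual)
#' variance components, computed from sample sizes, allele frequencies and
#' observed heterozygote proportions. Unlike [wright_fst()] it corrects for
#' finite sample size and can be slightly negative under panmixia.
#'
#' @param matrix a `geno_matrix`.
#' @param pop_a,pop_b population names.
#' @param by population column.
#' @return theta-hat.
#' @export
wc_fst <- function(matrix, pop_a, pop_b, by = "subspecies") {
  key <- matrix$populations[[by]]
  g <- matrix$geno
  comp <- wc_components(g[, key == pop_a, drop = FALSE],
                        g[, key == pop_b, drop = FALSE])
  sum(comp$a) / sum(comp$a + comp$b + comp$c)
}

## W&C 1984 per-locus variance components for r = 2 populations.
wc_components <- function(ga, gb) {
  na <- rowSums(!is.na(ga)); nb <- rowSums(!is.na(gb))
  ok <- na > 0 & nb > 0
  if (!any(ok)) stop("no locus typed in both populations")
  ga <- ga[ok, , drop = FALSE]; gb <- gb[ok, , drop = FALSE]
  na <- na[ok]; nb <- nb[ok]
  pa <- rowSums(ga, na.rm = TRUE) / (2 * na)
  pb <- rowSums(gb, na.rm = TRUE) / (2 * nb)
  ha <- rowSums(ga == 1L, na.rm = TRUE) / na
  hb <- rowSums(gb == 1L, na.rm = TRUE) / nb
  r <- 2
  nbar <- (na + nb) / r
  nc <- (r * nbar - (na^2 + nb^2) / (r * nbar)) / (r - 1)
  pbar <- (na * pa + nb * pb) / (r * nbar)
  s2 <- (na * (pa - pbar)^2 + nb * (pb - pbar)^2) / ((r - 1) * nbar)
  hbar <- (na * ha + nb * hb) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  ## loci fixed in the pooled sample carry no information
  drop <- pbar %in% c(0, 1)
  list(a = a[!drop], b = b[!drop], c = c[!drop])
}

#' PCA of a genotype matrix
#'
#' Dosages are mean-imputed per locus, centered by twice the allele
#' frequency and (by default) scaled by sqrt(p(1-p)), the usual
#' genotype-PCA normalization; the sample covariance is then
#' eigendecomposed. Component signs are arbitrary.
#'
#' @param matrix a `geno_matrix`.
#' @param scale divide by sqrt(p(1-p)).
#' @return List with `scores` (individuals x components) and
#'   `explained` (fraction of variance per component, non-increasing).
#' @export
pca_genotypes <- function(matrix, scale = TRUE) {
  g <- t(matrix$geno)  # individuals x loci
  p <- colMeans(g, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1 & !is.na(p)
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  x <- sweep(g, 2, 2 * p)
  x[is.na(x)] <- 0  # mean imputation
  if (scale) x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x, explained = ev / sum(ev))
}

#' Classical principal coordinate analysis (metric MDS)
#'
#' Double-centers the squared distance matrix and eigendecomposes it
#' (cmdscale); on Euclidean distances this reproduces PCA up to rotation.
#'
#' @param dist a `dist` or symmetric matrix.
#' @param k number of coordinates.
#' @return List with `coords` and `eig`.
#' @export
pcoa_coords <- function(dist, k = 2) {
  res <- stats::cmdscale(stats::as.dist(dist), k = k, eig = TRUE)
  list(coords = res$points, eig = res$eig)
}

#' Pairwise-population differentiation vectors from a genotype matrix
#'
#' Computes Nei's D, Wright Fst and W&C theta for every population pair
#' (upper triangle, fixed order), the inputs to [concordance()].
#'
#' @param matrix a `geno_matrix`.
#' @param by population column.
#' @return data.frame with `pop_a`, `pop_b`, `nei_d`, `wright_fst`,
#'   `wc_fst`.
#' @export
pairwise_stats <- function(matrix, by = "subspecies") {
  f <- pop_freqs(matrix, by = by)
  pops <- sort(colnames(f$p))
  pairs <- utils::combn(pops, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    data.frame(pop_a = a, pop_b = b,
               nei_d = nei_distance(f, a, b),
               wright_fst = wright_fst(f, a, b),
               wc_fst = wc_fst(matrix, a, b, by = by))
  }))
}

#' Concordance between TE- and SNP-based differentiation estimates
#'
#' Pearson correlation of the pairwise-population vectors of each statistic
#' between two marker sets genotyped on the same populations.
#'
#' @param te_stats,snp_stats outputs of [pairwise_stats()] over the same
#'   population pairs.
#' @return Named numeric vector of Pearson r per statistic.
#' @export
concordance <- function(te_stats, snp_stats) {
  m <- merge(te_stats, snp_stats, by = c("pop_a", "pop_b"),
             suffixes = c("_te", "_snp"))
  if (nrow(m) < 3) stop("need at least 3 population pairs")
  vapply(c("nei_d", "wright_fst", "wc_fst"), function(s)
    stats::cor(m[[paste0(s, "_te")]], m[[paste0(s, "_snp")]]),
    numeric(1))
}
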