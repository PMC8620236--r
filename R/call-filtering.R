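## Cascading quality filter for mobile-element insertion calls, REF+ genotype
## inversion, merged matrix construction and descriptive genotype summaries.

#' Cascading filter for TE insertion calls
#'
#' Removes calls that (1) failed the caller's internal filters, (2) have fewer
#' than `min_support` supporting read pairs on either side, or (3) are shorter
#' than `min_len` bp. Thresholds are inclusive-retain: a call with exactly
#' `min_support` pairs per side and exactly `min_len` bp survives, matching
#' removal of calls with "less than" the threshold. Each removed call is
#' attributed to the first criterion it fails, in cascade order
#' internal -> support -> length.
#'
#' @param calls a [insertion_calls()] object.
#' @param min_support minimum supporting read pairs required on each side.
#' @param min_len minimum element length in bp.
#' @return A list with `calls` (the retained subset, order preserved) and
#'   `report` (named counts removed per criterion: `internal`, `support`,
#'   `length`, plus `retained`).
#' @export
cascade_filter <- function(calls, min_support = 5, min_len = 100) {
  stopifnot(inherits(calls, "te_calls"))
  if (min_support < 0 || min_len < 0) stop("thresholds must be >= 0")
  info <- calls$info
  fail_internal <- !info$filter_pass
  fail_support <- info$left_support < min_support |
    info$right_support < min_support
  fail_length <- info$svlen < min_len
  first_fail <- rep(NA_character_, nrow(info))
  first_fail[fail_length] <- "length"
  first_fail[fail_support] <- "support"
  first_fail[fail_internal] <- "internal"
  keep <- is.na(first_fail)
  report <- c(internal = sum(first_fail == "internal", na.rm = TRUE),
              support = sum(first_fail == "support", na.rm = TRUE),
              length = sum(first_fail == "length", na.rm = TRUE),
              retained = sum(keep))
  out <- insertion_calls(info[keep, , drop = FALSE],
                         calls$geno[keep, , drop = FALSE],
                         call_class = calls$call_class,
                         inverted = calls$inverted)
  list(calls = out, report = report)
}

#' Invert REF+ (deletion-style) genotypes to insertion dosages
#'
#' Deletion callers genotype the *absence* of a reference TE copy: GT 1/1
#' means the element is deleted in the individual. Inversion maps deletion
#' dosage d to insertion dosage 2 - d so that, as in the REF- calls, 0 means
#' no insertion allele. Heterozygotes and missing calls are fixed points. A
#' flag on the object prevents accidental double inversion.
#'
#' @param calls a [insertion_calls()] object with `call_class = "REF_PLUS"`.
#' @return The calls with inverted dosages and `inverted = TRUE`.
#' @export
invert_deletion_calls <- function(calls) {
  stopifnot(inherits(calls, "te_calls"))
  if (calls$call_class != "REF_PLUS")
    stop("genotype inversion applies to REF_PLUS (deletion) calls only")
  if (calls$inverted) stop("calls are already inverted; refusing to invert twice")
  calls$geno <- invert_dosage(calls$geno)
  calls$inverted <- TRUE
  calls
}

## pure dosage involution, exported for property testing
#' @rdname invert_deletion_calls
#' @param geno a dosage matrix.
#' @export
invert_dosage <- function(geno) 2L - geno

#' Merge filtered REF- and REF+ calls into one genotype matrix
#'
#' Takes the union of the two locus sets. Two loci of the same family on the
#' same chromosome within `collision_bp` of each other are considered the same
#' insertion seen by both pipelines and are merged; where the two records
#' disagree on a sample's dosage the merged cell is set to missing.
#'
#' @param ref_minus filtered REF- calls.
#' @param ref_plus_inverted filtered, genotype-inverted REF+ calls.
#' @param populations population table (see [genotype_matrix()]).
#' @param collision_bp merge radius in bp.
#' @return A `geno_matrix`.
#' @export
build_matrix <- function(ref_minus, ref_plus_inverted, populations,
                         collision_bp = 50) {
  stopifnot(inherits(ref_minus, "te_calls"),
            inherits(ref_plus_inverted, "te_calls"))
  if (ref_plus_inverted$call_class == "REF_PLUS" && !ref_plus_inverted$inverted)
    stop("REF_PLUS calls must be inverted before merging")
  if (!identical(sort(colnames(ref_minus$geno)),
                 sort(colnames(ref_plus_inverted$geno))))
    stop("sample rosters of the two call sets differ")
  roster <- colnames(ref_minus$geno)
  info <- rbind(ref_minus$info[c("chrom", "pos", "family", "svlen")],
                ref_plus_inverted$info[c("chrom", "pos", "family", "svlen")])
  geno <- rbind(ref_minus$geno,
                ref_plus_inverted$geno[, roster, drop = FALSE])

  ## group loci: same family+chrom, positions within collision_bp are chained
  ord <- order(info$family, info$chrom, info$pos)
  info <- info[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  same_grp <- c(FALSE, info$family[-1] == info$family[-nrow(info)] &
                  info$chrom[-1] == info$chrom[-nrow(info)] &
                  diff(info$pos) <= collision_bp)
  grp <- cumsum(!same_grp)
  keep_rows <- !duplicated(grp)
  merged_geno <- geno[keep_rows, , drop = FALSE]
  n_conflict <- 0L
  for (g in unique(grp[duplicated(grp)])) {
    idx <- which(grp == g)
    sub <- geno[idx, , drop = FALSE]
    cell <- apply(sub, 2, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_integer_)
      if (length(unique(v)) > 1L) return(NA_integer_)  # conflict -> missing
      v[1]
    })
    conf <- apply(sub, 2, function(v) length(unique(v[!is.na(v)])) > 1L)
    n_conflict <- n_conflict + sum(conf)
    merged_geno[which(which(keep_rows) == idx[1]), ] <- cell
  }
  if (n_conflict > 0)
    message("build_matrix: ", n_conflict,
            " conflicting genotype cells set to missing during locus merging")
  genotype_matrix(merged_geno, info[keep_rows, , drop = FALSE], populations)
}

#' Genotype summaries per species, subspecies or family
#'
#' For each group: number of loci present (dosage >= 1 in at least one
#' member), counts of heterozygous and homozygous-insertion genotype calls,
#' and the heterozygous ratio HET / (HET + HOM_ALT).
#'
#' @param matrix a `geno_matrix`.
#' @param by grouping key: `"species"`, `"subspecies"` or `"family"`.
#' @return data.frame with columns `group`, `present`, `het`, `hom`,
#'   `het_ratio`.
#' @export
genotype_summary <- function(matrix, by = c("subspecies", "species", "family")) {
  by <- match.arg(by)
  g <- matrix$geno
  if (by == "family") {
    groups <- split(seq_len(nrow(g)), matrix$loci$family)
    rows <- lapply(names(groups), function(nm) {
      sub <- g[groups[[nm]], , drop = FALSE]
      het <- sum(sub == 1L, na.rm = TRUE)
      hom <- sum(sub == 2L, na.rm = TRUE)
      data.frame(group = nm,
                 present = sum(rowSums(sub >= 1L, na.rm = TRUE) > 0),
                 het = het, hom = hom,
                 het_ratio = if (het + hom > 0) het / (het + hom) else NaN)
    })
  } else {
    key <- matrix$populations[[by]]
    groups <- split(seq_len(ncol(g)), key)
    rows <- lapply(names(groups), function(nm) {
      sub <- g[, groups[[nm]], drop = FALSE]
      het <- sum(sub == 1L, na.rm = TRUE)
      hom <- sum(sub == 2L, na.rm = TRUE)
      data.frame(group = nm,
                 present = sum(rowSums(sub >= 1L, na.rm = TRUE) > 0),
                 het = het, hom = hom,
                 het_ratio = if (het + hom > 0) het / (het + hom) else NaN)
    })
  }
  do.call(rbind, rows)
}

#' Count full-length insertions per family
#'
#' An insertion counts as full length when its element length is strictly
#' greater than the family's threshold (just below the consensus length, so
#' near-complete copies count but 5'-truncated ones do not).
#'
#' @param calls a `te_calls` object or `geno_matrix`.
#' @param thresholds named vector of bp thresholds per family; families not
#'   listed are skipped. Defaults follow the two autonomous giraffe families:
#'   7980 bp (LINE1-like, consensus 7997) and 3850 bp (RTE-like, consensus
#'   3872).
#' @return data.frame with `family`, `n_total`, `n_full_length`.
#' @export
full_length_summary <- function(calls,
                                thresholds = c("L1-1_Gir" = 7980,
                                               "RTE-1_Gir" = 3850)) {
  tab <- if (inherits(calls, "te_calls")) calls$info else calls$loci
  fams <- intersect(names(thresholds), unique(tab$family))
  do.call(rbind, lapply(fams, function(fm) {
    len <- tab$svlen[tab$family == fm]
    data.frame(family = fm, n_total = length(len),
               n_full_length = sum(len > thresholds[[fm]]))
  }))
}
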