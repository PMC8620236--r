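#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

GT_CODES <- c(HOM_REF = 0L, HET = 1L, HOM_ALT = 2L)

#' Construct a genotype matrix of TE (or SNP) markers
#'
#' The central container of the package: an integer matrix of insertion-allele
#' dosages (0 = homozygous reference, 1 = heterozygous, 2 = homozygous for the
#' insertion, `NA` = missing) with per-locus metadata and a population
#' assignment for every individual.
#'
#' @param geno integer matrix, loci in rows, individuals in columns; values in
#'   \{0, 1, 2, NA\}.
#' @param loci data.frame with one row per locus and columns `chrom`, `pos`,
#'   `family`, `svlen`.
#' @param populations data.frame with columns `sample`, `species`,
#'   `subspecies`, one row per individual; must cover every column of `geno`.
#' @return An object of class `geno_matrix`.
#' @export
genotype_matrix <- function(geno, loci, populations) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(loci) != nrow(geno))
    stop("loci table (", nrow(loci), " rows) does not match genotype matrix (",
         nrow(geno), " loci)")
  req <- c("chrom", "pos", "family", "svlen")
  if (!all(req %in% names(loci)))
    stop("loci table must have columns: ", paste(req, collapse = ", "))
  if (is.null(colnames(geno))) stop("genotype matrix must have sample names")
  bad <- setdiff(colnames(geno), populations$sample)
  if (length(bad))
    stop("samples without population assignment: ", paste(bad, collapse = ", "))
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  populations <- populations[match(colnames(geno), populations$sample), ,
                             drop = FALSE]
  rownames(populations) <- NULL
  structure(list(geno = geno, loci = as.data.frame(loci, optional = TRUE),
                 populations = as.data.frame(populations)),
            class = "geno_matrix")
}

#' @method print geno_matrix
#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix: ", nrow(x$geno), " loci x ", ncol(x$geno),
      " individuals\n", sep = "")
  cat("families: ", paste(unique(x$loci$family), collapse = ", "), "\n",
      sep = "")
  cat("populations: ", length(unique(x$populations$subspecies)),
      " subspecies in ", length(unique(x$populations$species)),
      " species\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Samples of a genotype matrix
#' @param x a `geno_matrix`.
#' @return Character vector of individual IDs (column order).
#' @export
samples <- function(x) colnames(x$geno)

#' Subset a genotype matrix by loci and/or individuals
#' @param x a `geno_matrix`.
#' @param i locus index. @param j sample index (name or position).
#' @param ... ignored.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  genotype_matrix(x$geno[i, j, drop = FALSE], x$loci[i, , drop = FALSE],
                  x$populations)
}

#' Construct a set of mobile-element insertion calls
#'
#' Holds one TE insertion call per row: locus coordinates, family, inserted
#' length, per-side supporting read-pair counts, the caller's internal PASS
#' flag, and per-individual genotype dosages. REF- calls describe insertions
#' absent from the reference assembly; REF+ calls are deletion-style records of
#' insertions the reference carries.
#'
#' @param info data.frame with columns `chrom`, `pos`, `family`, `svlen`,
#'   `left_support`, `right_support`, `filter_pass`.
#' @param geno dosage matrix (calls x samples), values 0/1/2/NA.
#' @param call_class `"REF_MINUS"` or `"REF_PLUS"`.
#' @param inverted has a REF+ set already been genotype-inverted?
#' @return An object of class `te_calls`.
#' @export
insertion_calls <- function(info, geno, call_class = c("REF_MINUS", "REF_PLUS"),
                            inverted = FALSE) {
  call_class <- match.arg(call_class)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(info) != nrow(geno)) stop("info/geno row mismatch")
  req <- c("chrom", "pos", "family", "svlen", "left_support", "right_support",
           "filter_pass")
  if (!all(req %in% names(info)))
    stop("call table must have columns: ", paste(req, collapse = ", "))
  if (any(info$pos < 1)) stop("positions are 1-based; pos >= 1 required")
  if (any(info$svlen < 0)) stop("svlen must be >= 0")
  if (any(info$left_support < 0) || any(info$right_support < 0))
    stop("support counts must be >= 0")
  structure(list(info = as.data.frame(info), geno = geno,
                 call_class = call_class, inverted = inverted),
            class = "te_calls")
}

#' @method print te_calls
#' @export
print.te_calls <- function(x, ...) {
  cat("te_calls: ", nrow(x$info), " ", x$call_class, " calls, ",
      ncol(x$geno), " samples",
      if (x$inverted) " (genotypes inverted)", "\n", sep = "")
  invisible(x)
}

#' @export
length.te_calls <- function(x) nrow(x$info)

#' Construct a binary presence/absence matrix over taxa
#'
#' @param codes integer matrix, loci x taxa, values 0/1 with NA for unknown
#'   ('?' in Nexus).
#' @param outgroup name of the all-zero artificial outgroup column, or NULL.
#' @return An object of class `presence_matrix` (an integer matrix with an
#'   `outgroup` attribute).
#' @export
presence_matrix <- function(codes, outgroup = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (!all(codes %in% c(0L, 1L) | is.na(codes)))
    stop("presence codes must be 0, 1 or NA")
  if (is.null(colnames(codes))) stop("taxa must be named")
  if (!is.null(outgroup)) {
    if (!outgroup %in% colnames(codes))
      stop("outgroup '", outgroup, "' not among taxa")
    og <- codes[, outgroup]
    if (any(og != 0L, na.rm = TRUE) || anyNA(og))
      stop("outgroup column must be all 0")
  }
  structure(codes, outgroup = outgroup, class = c("presence_matrix", "matrix",
                                                  "array"))
}

#' @method print presence_matrix
#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix: ", nrow(x), " loci x ", ncol(x), " taxa",
      if (!is.null(attr(x, "outgroup")))
        paste0(" (outgroup: ", attr(x, "outgroup"), ")"),
      "\n", sep = "")
  invisible(x)
}

ingroup_taxa <- function(pm) setdiff(colnames(pm), attr(pm, "outgroup"))

#' Construct a table of SINE copies with flanking sequence
#'
#' @param id copy identifiers (unique).
#' @param element_seq element nucleotide sequences (A/C/G/T/N).
#' @param left_flank,right_flank flanking sequences (possibly shorter than the
#'   requested flank length at contig ends).
#' @param family family label per copy.
#' @param chrom,start,end optional source coordinates (0-based, half-open).
#' @return data.frame of class `sine_copies`.
#' @export
sine_copies <- function(id, element_seq, left_flank = "", right_flank = "",
                        family = "SINE", chrom = NA_character_, start = NA_integer_,
                        end = NA_integer_) {
  if (anyDuplicated(id)) stop("copy IDs must be unique")
  seqs <- toupper(c(element_seq, left_flank, right_flank))
  if (any(grepl("[^ACGTN]", seqs[nzchar(seqs)])))
    stop("sequences must be over {A,C,G,T,N}")
  df <- data.frame(id = as.character(id), element_seq = toupper(element_seq),
                   left_flank = toupper(left_flank),
                   right_flank = toupper(right_flank),
                   family = family, chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  class(df) <- c("sine_copies", "data.frame")
  df
}
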