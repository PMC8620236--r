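## Consensus curation and divergence: end-gap-free identity, segmental
## duplication dedup, majority-rule consensus with CpG restoration, Kimura
## 2-parameter distance, repeat landscapes and intact-ORF scanning.

## Substitution matrix over {A,C,G,T,N}: match +1, mismatch -1, and N never
## matches anything (conservative for 100%-identity clustering).
.retropop_submat <- local({
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
})

align_overlap <- function(a, b) {
  Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                substitutionMatrix = .retropop_submat,
                                gapOpening = 0, gapExtension = 2)
}

#' End-gap-free pairwise sequence identity
#'
#' Identity is matches / aligned columns under a deterministic end-gap-free
#' (overlap) global alignment with match +1, mismatch -1, gap -2; `N` counts
#' as a mismatch against everything including `N`. The denominator is never
#' smaller than the shorter sequence's length, so a short incidental perfect
#' overlap between unrelated sequences does not inflate the identity: the
#' free end gaps absorb terminal overhangs only.
#'
#' @param a,b nucleotide strings.
#' @return Fraction in \[0, 1\] (0 for an empty overlap).
#' @export
seq_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  pa <- align_overlap(a, b)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  if (!length(p)) return(0)
  sum(p == s & p != "-" & p != "N") /
    max(length(p), min(nchar(a), nchar(b)))
}

#' Remove SINE/TE copies created by segmental duplication
#'
#' Segmental duplications copy the element together with its flanks; among any
#' pair of copies whose concatenated 350 bp flanks align at >= the identity
#' threshold, the later-listed copy is discarded as a duplication artifact.
#'
#' @param copies a [sine_copies()] table carrying flanks.
#' @param flank_len flank length used (bp); flanks longer than this are
#'   trimmed to the element-proximal `flank_len` bases.
#' @param max_flank_identity identity threshold at or above which the pair is
#'   treated as one segmental-duplication event.
#' @return The retained copies (input order preserved).
#' @export
dedup_segmental <- function(copies, flank_len = 350,
                            max_flank_identity = 0.98) {
  if (flank_len <= 0) stop("flank_len must be positive")
  n <- nrow(copies)
  if (n < 2) return(copies)
  lf <- substring(copies$left_flank,
                  pmax(1L, nchar(copies$left_flank) - flank_len + 1L))
  rf <- substring(copies$right_flank, 1L, flank_len)
  cat_flank <- paste0(lf, rf)
  keep <- rep(TRUE, n)
  for (i in seq_len(n - 1)) {
    if (!keep[i]) next
    for (j in seq((i + 1), n)) {
      if (!keep[j]) next
      if (seq_identity(cat_flank[i], cat_flank[j]) >= max_flank_identity)
        keep[j] <- FALSE
    }
  }
  copies[keep, , drop = FALSE]
}

#' Majority-rule consensus with CpG restoration
#'
#' Builds the per-column majority consensus of an alignment (gap wins a column
#' only when more than half of the rows are gapped), then restores ancestral
#' CpG dinucleotides: methylated CpG sites decay to TpG and CpA much faster
#' than the background substitution rate, so a consensus TG or CA column pair
#' is rewritten to CG when at least `cpg_fraction` of rows still show CG there
#' and the decayed state together with CG forms the majority of rows.
#'
#' @param aln character vector of aligned sequences (equal length, gap `-`).
#' @param cpg_fraction minimum fraction of rows retaining CG for restoration.
#' @return Consensus string (gap columns removed).
#' @export
majority_consensus <- function(aln, cpg_fraction = 0.10) {
  if (length(aln) < 2) stop("consensus building needs >= 2 aligned sequences")
  if (length(unique(nchar(aln))) != 1) stop("ragged alignment")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  L <- ncol(m)
  cons <- vapply(seq_len(L), function(j) {
    col <- m[, j]
    if (mean(col == "-") > 0.5) return("-")
    col <- col[col != "-"]
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  }, character(1))
  ## CpG restoration on the plain consensus
  nrows <- nrow(m)
  for (j in seq_len(L - 1)) {
    pair <- paste0(cons[j], cons[j + 1])
    if (pair != "TG" && pair != "CA") next
    dints <- paste0(m[, j], m[, j + 1])
    n_cg <- sum(dints == "CG")
    n_decay <- sum(dints == pair)
    if (n_cg / nrows >= cpg_fraction && (n_cg + n_decay) > nrows / 2) {
      cons[j] <- "C"
      cons[j + 1] <- "G"
    }
  }
  paste(cons[cons != "-"], collapse = "")
}

## per-column mode without the CpG step; kept separate so the consensus rule
## can be cross-checked against a brute-force column scan
plain_consensus <- function(aln) {
  majority_consensus(aln, cpg_fraction = Inf)
}

#' Kimura 2-parameter distance between aligned sequences
#'
#' Separates transitions (A<->G, C<->T; proportion P) from transversions
#' (proportion Q) and returns d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q).
#' Columns containing a gap or `N` in either sequence are excluded from the
#' denominator. When 1 - 2P - Q <= 0 or 1 - 2Q <= 0 the distance is saturated
#' and `d` is `NA` with `saturated = TRUE`.
#'
#' @param seq_a,seq_b equal-length aligned nucleotide strings.
#' @return List with `P`, `Q`, `d`, `valid_sites`, `saturated`.
#' @export
k2p <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) stop("no valid (gap- and N-free) columns")
  diff <- a != b
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  transition <- diff & (purine[a] == purine[b])
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(P = P, Q = Q, d = NA_real_, valid_sites = n, saturated = TRUE))
  list(P = P, Q = Q, d = -0.5 * log(w1) - 0.25 * log(w2), valid_sites = n,
       saturated = FALSE)
}

#' Repeat landscape: genome share binned by divergence
#'
#' Bins copies into half-open K2P-distance bins `[k w, (k+1) w)` and reports,
#' per family and bin, the summed copy length as a percentage of the genome.
#' Bin totals conserve each family's overall genomic percentage.
#'
#' @param records data.frame with columns `copy_id`, `family`, `d` (K2P
#'   substitutions/site) and `length` (bp).
#' @param genome_size assembly size in bp.
#' @param bin_width bin width in substitutions/site.
#' @return data.frame with `family`, `bin_low`, `bin_high`, `pct_genome`.
#' @export
repeat_landscape <- function(records, genome_size, bin_width = 0.01) {
  if (nrow(records) == 0)
    return(data.frame(family = character(), bin_low = numeric(),
                      bin_high = numeric(), pct_genome = numeric()))
  stopifnot(genome_size > 0, bin_width > 0)
  bin <- floor(records$d / bin_width)
  agg <- stats::aggregate(records$length,
                          by = list(family = records$family, bin = bin), sum)
  data.frame(family = agg$family, bin_low = agg$bin * bin_width,
             bin_high = (agg$bin + 1) * bin_width,
             pct_genome = agg$x / genome_size * 100)[order(agg$family,
                                                           agg$bin), ]
}

#' Scan a sequence for long intact open reading frames
#'
#' Finds forward-frame ORFs (ATG to stop, standard code) of at least `min_aa`
#' codons with no internal stop and no `N` inside; autonomous non-LTR elements
#' are recognized by an intact ORF coding for the ~1000 aa endonuclease /
#' reverse-transcriptase protein. Copies are assumed already oriented;
#' reverse-complement scanning is left to the caller.
#'
#' @param seq nucleotide string.
#' @param min_aa minimum protein length in amino acids (stop excluded).
#' @return data.frame with 0-based half-open `start`, `end` (including the
#'   stop codon), `frame` (0-2) and `aa_length`; empty when nothing qualifies.
#' @export
scan_intact_orfs <- function(seq, min_aa = 1000) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    if (length(starts) == 0) next
    codons <- substring(seq, starts, starts + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% stops
    has_n <- grepl("N", codons, fixed = TRUE)
    i <- 1L
    while (i <= length(codons)) {
      if (is_start[i]) {
        j <- i
        first_n <- 0L
        while (j <= length(codons) && !is_stop[j]) {
          if (has_n[j] && first_n == 0L) first_n <- j
          j <- j + 1L
        }
        if (first_n == 0L && j <= length(codons) && !has_n[j]) {  # clean stop
          aa <- j - i
          if (aa >= min_aa)
            out[[length(out) + 1L]] <-
              data.frame(start = starts[i] - 1L, end = starts[j] + 2L,
                         frame = frame, aa_length = aa)
        }
        # resume after the break (N or stop), so ORFs behind an N are found
        i <- if (first_n > 0L) first_n + 1L else j + 1L
      } else i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      aa_length = integer()))
  do.call(rbind, out)
}
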