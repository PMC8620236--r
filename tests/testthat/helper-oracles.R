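# Independent oracles used to verify the package's own algorithms. These are
# deliberately naive (enumeration / dynamic programming at tiny sizes) and
# share no code with the implementation paths they check.

# --- brute-force irreversible parsimony -------------------------------------
# Minimum number of 0->1 gains for one binary character on a rooted tree,
# by exhaustive enumeration over all subsets of gain nodes (a gain on the
# branch above node v makes every leaf below v state 1). Feasible subsets
# cover every 1-leaf and contain no 0-leaf; '?' leaves are unconstrained.

# Per-tree precomputation: descendant-tip bitmask of every node, and the
# union mask + cardinality of every subset of nodes.
cs_oracle_prep <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- integer(nnode)
  tr <- ape::reorder.phylo(tree, "postorder")
  desc[seq_len(ntip)] <- bitwShiftL(1L, seq_len(ntip) - 1L)
  for (e in seq_len(nrow(tr$edge)))
    desc[tr$edge[e, 1]] <- bitwOr(desc[tr$edge[e, 1]], desc[tr$edge[e, 2]])
  nsub <- bitwShiftL(1L, nnode)
  union_mask <- integer(nsub)
  card <- integer(nsub)
  for (v in seq_len(nnode)) {
    block <- bitwShiftL(1L, v - 1L)          # subsets with node v as top bit
    idx <- seq_len(block)
    union_mask[block + idx] <- bitwOr(union_mask[idx], desc[v])
    card[block + idx] <- card[idx] + 1L
  }
  list(ntip = ntip, tips = tree$tip.label, union_mask = union_mask,
       card = card)
}

# char: vector of 0/1/NA in prep$tips order
cs_oracle_min_gains <- function(prep, char) {
  bits <- bitwShiftL(1L, seq_len(prep$ntip) - 1L)
  ones <- Reduce(bitwOr, bits[!is.na(char) & char == 1L], 0L)
  zeros <- Reduce(bitwOr, bits[!is.na(char) & char == 0L], 0L)
  if (ones == 0L) return(0L)
  feas <- bitwAnd(prep$union_mask, zeros) == 0L &
    bitwAnd(prep$union_mask, ones) == ones
  min(prep$card[feas])
}

# --- union-find + all-pairs clustering oracle -------------------------------
uf_cluster_oracle <- function(seqs, min_coverage = 0.98) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq(i + 1, n)) {
      a <- seqs[i]; b <- seqs[j]
      s <- if (nchar(a) <= nchar(b)) a else b
      l <- if (nchar(a) <= nchar(b)) b else a
      linked <- nchar(s) / nchar(l) >= min_coverage &&
        !grepl("N", s, fixed = TRUE) &&
        regexpr(s, l, fixed = TRUE)[1] > 0
      if (linked) parent[find(i)] <- find(j)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# --- Needleman-Wunsch with free end gaps (overlap) identity oracle ----------
# match +1, mismatch -1, gap -2, N matches nothing; identity over the aligned
# region of the best-scoring end-gap-free alignment.
nw_overlap_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)          # free leading end gaps
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (A[i] == B[j] && A[i] != "N") 1 else -1
      S[i + 1, j + 1] <- max(S[i, j] + sub, S[i, j + 1] - 2, S[i + 1, j] - 2)
    }
  }
  ends <- rbind(cbind(n + 1, seq_len(m + 1)), cbind(seq_len(n + 1), m + 1))
  best <- ends[which.max(S[ends]), ]
  i <- best[1] - 1; j <- best[2] - 1
  matches <- 0; cols <- 0
  while (i > 0 && j > 0) {
    sub <- if (A[i] == B[j] && A[i] != "N") 1 else -1
    if (S[i + 1, j + 1] == S[i, j] + sub) {
      matches <- matches + (sub == 1); cols <- cols + 1
      i <- i - 1; j <- j - 1
    } else if (S[i + 1, j + 1] == S[i, j + 1] - 2) {
      cols <- cols + 1; i <- i - 1
    } else {
      cols <- cols + 1; j <- j - 1
    }
  }
  if (cols == 0) 0 else matches / max(cols, min(n, m))
}

# --- Weir & Cockerham 1984, independent single-locus transcription ----------
# From genotype counts (nAA, nAa, naa) per population; returns the per-locus
# a, b, c components. Written directly from the published component formulas.
wc_oracle_components <- function(counts_a, counts_b) {
  n_i <- c(sum(counts_a), sum(counts_b))
  p_i <- c((2 * counts_a[1] + counts_a[2]) / (2 * n_i[1]),
           (2 * counts_b[1] + counts_b[2]) / (2 * n_i[2]))
  h_i <- c(counts_a[2] / n_i[1], counts_b[2] / n_i[2])
  r <- 2
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

# --- fixture builders --------------------------------------------------------
toy_populations <- function(samples, species = "sp", subspecies = "ssp") {
  data.frame(sample = samples, species = species, subspecies = subspecies)
}

# genotype matrix from a plain dosage matrix with default metadata
toy_matrix <- function(geno, populations = NULL, family = "L1-1_Gir") {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("S", seq_len(ncol(geno)))
  if (is.null(populations)) populations <- toy_populations(colnames(geno))
  genotype_matrix(geno,
                  data.frame(chrom = "chr1", pos = seq_len(nrow(geno)),
                             family = family, svlen = 1000),
                  populations)
}

# the six-call cascade fixture: 2 failing the internal filter, 1 low-support,
# 1 short, 2 clean (one exactly at the support/length boundary)
six_call_fixture <- function() {
  info <- data.frame(
    chrom = "chr1", pos = c(100, 200, 300, 400, 500, 600),
    family = "L1-1_Gir",
    svlen = c(500, 4000, 500, 80, 500, 100),
    left_support = c(10, 9, 4, 8, 12, 5),
    right_support = c(10, 9, 9, 8, 11, 5),
    filter_pass = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  geno <- matrix(c(0L, 1L), 6, 2, dimnames = list(NULL, c("S1", "S2")))
  insertion_calls(info, geno, "REF_MINUS")
}

# mean silhouette width for a 2-group labeling of 1-d or n-d coordinates
mean_silhouette <- function(coords, labels) {
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  s <- vapply(seq_len(nrow(d)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- min(vapply(unique(labels[!own]), function(g)
      mean(d[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
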