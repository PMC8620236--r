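## Synthetic inputs with the statistical structure the pipeline assumes:
## TE insertions placed on a species tree, MELT-dialect call emission with
## injected noise, SINE copies from retrotransposition vs segmental
## duplication, and a drift-based SNP comparator. All generators are pure
## functions of (config, seed).

#' Default study-system species tree
#'
#' A rooted ultrametric tree over 8 population units (7 subspecies plus the
#' reticulated giraffe, which has none): four species in the topology
#' ((northern, reticulated), (southern, Masai)), crown age 1.2 Myr, with a
#' 10.3 Myr root stem representing the time back to the okapi split (11.5
#' Myr). Branch lengths are in Myr. Internal nodes are labeled.
#'
#' @return A rooted `ape::phylo` with `root.edge` set.
#' @export
giraffe_species_tree <- function() {
  txt <- paste0("(((Kordofan:0.3,(Nubian:0.2,WestAfrican:0.2)nub_waf:0.1)",
                "northern:0.3,Reticulated:0.6)north_ret:0.6,",
                "((Angolan:0.35,SouthAfrican:0.35)southern:0.45,",
                "(Masai:0.3,Luangwa:0.3)masai_sl:0.5)south_masai:0.4)",
                "giraffe_mrca:10.3;")
  tr <- ape::read.tree(text = txt)
  ## ape stores the trailing length of the root label as root.edge
  if (is.null(tr$root.edge)) tr$root.edge <- 10.3
  tr
}

#' Default individual roster and population assignment
#'
#' 48 individuals across 4 species: 15 northern (5 Kordofan, 5 Nubian,
#' 5 West African), 10 reticulated, 11 southern (5 Angolan, 6 South
#' African), 12 Masai sensu lato (6 Masai sensu stricto, 6 Luangwa).
#'
#' @return data.frame with `sample`, `species`, `subspecies` (subspecies
#'   names match the tips of [giraffe_species_tree()]).
#' @export
giraffe_roster <- function() {
  spec <- list(
    Kordofan = c("northern", 5), Nubian = c("northern", 5),
    WestAfrican = c("northern", 5), Reticulated = c("reticulated", 10),
    Angolan = c("southern", 5), SouthAfrican = c("southern", 6),
    Masai = c("masai", 6), Luangwa = c("masai", 6))
  do.call(rbind, lapply(names(spec), function(tx) {
    n <- as.integer(spec[[tx]][2])
    data.frame(sample = sprintf("%s%02d", toupper(substr(tx, 1, 3)),
                                seq_len(n)),
               species = spec[[tx]][1], subspecies = tx)
  }))
}

#' Simulation configuration
#'
#' Bundles the generative parameters for [simulate_insertions()] and
#' [emit_melt_calls()]. Defaults mirror the study system: two TE families
#' with a ~6.6:1 gain-rate ratio (the LINE1:RTE insertion-count ratio),
#' full lengths 7997 and 3872 bp with full-length probabilities 5.3% and
#' 0.32%, per-side read support averaging 19 pairs (the data's mean
#' coverage), and a heterozygosity decay calibrated so insertions on the
#' root stem are ~40% heterozygous among carriers.
#'
#' @param tree rooted taxon tree with branch lengths (and optionally a
#'   `root.edge` for the shared stem).
#' @param individuals roster data.frame (`sample`, `species`, `subspecies`);
#'   `subspecies` must be tree tips.
#' @param gain_rate named per-family expected insertions per unit branch
#'   length.
#' @param het_decay decay constant of the heterozygous fraction among
#'   carriers, h(age) = exp(-het_decay * age).
#' @param full_length,full_length_prob named per-family consensus length (bp)
#'   and point mass of full-length insertions; other lengths are uniform
#'   5'-truncations down to `min_len`.
#' @param min_len shortest simulated true insertion (bp).
#' @param min_truncation smallest 5' truncation (bp) of a non-full-length
#'   copy; truncations below ~50 bp are not realistically distinguishable
#'   from full-length copies.
#' @param support_mean mean per-side supporting read pairs (Poisson).
#' @param noise_nonpass,noise_short rates (per true locus) of injected calls
#'   failing the caller-internal filter and of short spurious calls.
#' @param reference_individual sample treated as the reference assembly
#'   (defaults to the first Kordofan-labeled sample; the reference is nested
#'   inside the analyzed population).
#' @param seed RNG seed fixing all randomness.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(tree = giraffe_species_tree(),
                       individuals = giraffe_roster(),
                       gain_rate = c("L1-1_Gir" = 40, "RTE-1_Gir" = 6),
                       het_decay = -log(0.4) / 6.35,
                       full_length = c("L1-1_Gir" = 7997, "RTE-1_Gir" = 3872),
                       full_length_prob = c("L1-1_Gir" = 0.053,
                                            "RTE-1_Gir" = 0.0032),
                       min_len = 100,
                       min_truncation = 50,
                       support_mean = 19,
                       noise_nonpass = 0.05,
                       noise_short = 0.05,
                       reference_individual = NULL,
                       seed = 1L) {
  stopifnot(all(gain_rate >= 0), het_decay >= 0, support_mean >= 0,
            noise_nonpass >= 0, noise_short >= 0)
  if (!all(individuals$subspecies %in% tree$tip.label))
    stop("roster taxa missing from tree: ",
         paste(setdiff(individuals$subspecies, tree$tip.label),
               collapse = ", "))
  if (is.null(reference_individual)) {
    kord <- individuals$sample[individuals$subspecies == "Kordofan"]
    reference_individual <- if (length(kord)) kord[1] else
      individuals$sample[1]
  }
  structure(list(tree = tree, individuals = individuals,
                 gain_rate = gain_rate, het_decay = het_decay,
                 full_length = full_length,
                 full_length_prob = full_length_prob, min_len = min_len,
                 min_truncation = min_truncation,
                 support_mean = support_mean, noise_nonpass = noise_nonpass,
                 noise_short = noise_short,
                 reference_individual = reference_individual,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## branch table of a rooted tree: one row per edge plus the root stem.
## age = midpoint depth (time before present at the branch midpoint).
branch_table <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  h <- node_heights(tree)
  labels <- c(tree$tip.label,
              tree$node.label %||% paste0("node", (ntip + 1):(ntip + tree$Nnode)))
  rows <- data.frame(node = tree$edge[, 2],
                     branch = labels[tree$edge[, 2]],
                     length = tree$edge.length,
                     age = h[tree$edge[, 2]] + tree$edge.length / 2,
                     is_tip = tree$edge[, 2] <= ntip)
  root <- ntip + 1L
  if (!is.null(tree$root.edge) && tree$root.edge > 0)
    rows <- rbind(rows, data.frame(node = root, branch = labels[root],
                                   length = tree$root.edge,
                                   age = h[root] + tree$root.edge / 2,
                                   is_tip = FALSE))
  rows$taxa <- lapply(rows$node, function(nd)
    tree$tip.label[tip_descendants(tree, nd)])
  rows
}

#' Simulate TE insertion genotypes along a species tree
#'
#' For each family, the number of insertion loci arising on a branch is
#' Poisson(gain_rate x branch length). A locus on an internal branch is
#' carried by every individual of the descendant taxa; among carriers the
#' genotype is heterozygous with probability h(age) = exp(-het_decay x age)
#' and homozygous otherwise, reflecting drift towards fixation with
#' insertion age. Tip-branch (young) loci instead segregate within the taxon
#' at a per-locus carrier frequency ~ Uniform(1/(2n), 1). Non-carriers are
#' homozygous reference.
#'
#' @param config a [sim_config()].
#' @return List with `matrix` (a `geno_matrix`) and `truth` (data.frame with
#'   the originating branch, age and expected heterozygous fraction per
#'   locus).
#' @export
simulate_insertions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$tree$tip.label) == 0) stop("empty tree")
  set.seed(config$seed)
  br <- branch_table(config$tree)
  ind <- config$individuals
  samples <- ind$sample
  geno_rows <- list()
  t_family <- character(); t_branch <- character()
  t_age <- numeric(); t_h <- numeric(); svlen <- numeric()
  for (fam in names(config$gain_rate)) {
    rate <- config$gain_rate[[fam]]
    for (k in seq_len(nrow(br))) {
      n_loci <- stats::rpois(1, rate * br$length[k])
      if (n_loci == 0) next
      members <- which(ind$subspecies %in% br$taxa[[k]])
      h_age <- exp(-config$het_decay * br$age[k])
      g_block <- matrix(0L, n_loci, length(samples))
      for (l in seq_len(n_loci)) {
        if (br$is_tip[k]) {
          n_tax <- length(members)
          p <- stats::runif(1, 1 / (2 * n_tax), 1)
          carriers <- members[stats::runif(n_tax) < p]
          while (!length(carriers))
            carriers <- members[stats::runif(n_tax) < p]
        } else {
          carriers <- members
        }
        g_block[l, carriers] <-
          ifelse(stats::runif(length(carriers)) < h_age, 1L, 2L)
      }
      full <- stats::runif(n_loci) < config$full_length_prob[[fam]]
      len <- floor(stats::runif(n_loci, config$min_len,
                                config$full_length[[fam]] -
                                  config$min_truncation))
      len[full] <- config$full_length[[fam]]
      geno_rows[[length(geno_rows) + 1]] <- g_block
      svlen <- c(svlen, len)
      t_family <- c(t_family, rep(fam, n_loci))
      t_branch <- c(t_branch, rep(br$branch[k], n_loci))
      t_age <- c(t_age, rep(br$age[k], n_loci))
      t_h <- c(t_h, rep(h_age, n_loci))
    }
  }
  n <- length(t_family)
  if (n == 0) {
    geno <- matrix(integer(), 0, length(samples),
                   dimnames = list(NULL, samples))
    loci <- data.frame(chrom = character(), pos = integer(),
                       family = character(), svlen = numeric())
    return(list(matrix = genotype_matrix(geno, loci, ind),
                truth = data.frame(locus = integer(), family = character(),
                                   branch = character(), age = numeric(),
                                   h_true = numeric())))
  }
  geno <- do.call(rbind, geno_rows)
  colnames(geno) <- samples
  loci <- data.frame(chrom = paste0("chr", sample.int(14, n, replace = TRUE)),
                     pos = sample.int(1e8, n), family = t_family,
                     svlen = svlen)
  truth <- data.frame(locus = seq_len(n), family = t_family,
                      branch = t_branch, age = t_age, h_true = t_h)
  list(matrix = genotype_matrix(geno, loci, ind), truth = truth)
}

#' Emit REF- and REF+ MELT-style call sets from simulated genotypes
#'
#' Loci carried by the designated reference individual are emitted as REF+
#' deletion-style calls (their genotypes are deletion dosages, 2 - insertion
#' dosage, exactly what [invert_deletion_calls()] undoes); all other loci
#' are REF- insertion calls. Per-side read support is Poisson(support_mean).
#' Noise calls violating the cascade filter (non-PASS records and short
#' spurious calls) are appended to the REF- set at the configured rates.
#'
#' @param matrix,truth output of [simulate_insertions()].
#' @param config the same [sim_config()].
#' @return List with `ref_minus` and `ref_plus` ([insertion_calls()]
#'   objects).
#' @export
emit_melt_calls <- function(matrix, truth, config) {
  set.seed(config$seed + 1L)
  g <- matrix$geno
  samples <- colnames(g)
  ref <- config$reference_individual
  if (!ref %in% samples) stop("reference individual not in roster")
  n <- nrow(g)
  is_plus <- !is.na(g[, ref]) & g[, ref] >= 1L
  mk_info <- function(idx) {
    data.frame(chrom = matrix$loci$chrom[idx], pos = matrix$loci$pos[idx],
               family = matrix$loci$family[idx],
               svlen = matrix$loci$svlen[idx],
               left_support = stats::rpois(length(idx), config$support_mean),
               right_support = stats::rpois(length(idx), config$support_mean),
               filter_pass = TRUE)
  }
  minus_idx <- which(!is_plus)
  plus_idx <- which(is_plus)
  ref_minus <- insertion_calls(mk_info(minus_idx),
                               g[minus_idx, , drop = FALSE], "REF_MINUS")
  ref_plus <- insertion_calls(mk_info(plus_idx),
                              invert_dosage(g[plus_idx, , drop = FALSE]),
                              "REF_PLUS")
  ## injected noise, appended to the REF- set
  n_nonpass <- stats::rpois(1, config$noise_nonpass * n)
  n_short <- stats::rpois(1, config$noise_short * n)
  if (n_nonpass + n_short > 0) {
    nz <- n_nonpass + n_short
    fam <- sample(names(config$gain_rate), nz, replace = TRUE)
    noise_info <- data.frame(
      chrom = paste0("chr", sample.int(14, nz, replace = TRUE)),
      pos = sample.int(1e8, nz), family = fam,
      svlen = c(floor(stats::runif(n_nonpass, config$min_len, 4000)),
                floor(stats::runif(n_short, 30, config$min_len))),
      left_support = stats::rpois(nz, config$support_mean),
      right_support = stats::rpois(nz, config$support_mean),
      filter_pass = rep(c(FALSE, TRUE), c(n_nonpass, n_short)))
    noise_geno <- matrix(0L, nz, length(samples),
                         dimnames = list(NULL, samples))
    noise_geno[cbind(seq_len(nz), sample.int(length(samples), nz,
                                             replace = TRUE))] <- 1L
    ref_minus <- insertion_calls(rbind(ref_minus$info, noise_info),
                                 rbind(ref_minus$geno, noise_geno),
                                 "REF_MINUS")
  }
  list(ref_minus = ref_minus, ref_plus = ref_plus)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

mutate_seq <- function(seq, n_subst) {
  if (n_subst == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(ch), min(n_subst, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulate SINE copies from retrotransposition, segmental duplication and
#' background decay
#'
#' Emits three classes: (a) retrotransposition clusters - byte-identical
#' element copies with mutually unrelated flanks; (b) segmental-duplication
#' pairs - identical elements *and* near-identical (>= 0.98) flanks; (c)
#' background copies whose element divergence is drawn from an old/young
#' mixture and whose termini are randomly truncated, to shape the repeat
#' landscape.
#'
#' @param retro_sizes integer vector of retrotransposition cluster sizes.
#' @param n_segdup number of segmental-duplication pairs.
#' @param n_background number of background copies.
#' @param consensus_len element (consensus) length in bp.
#' @param flank_len flank length in bp.
#' @param truncation emit background copies with uniformly truncated termini
#'   (up to 60 bp).
#' @param family family label.
#' @param seed RNG seed.
#' @return List with `copies` (a [sine_copies()] table), `consensus`, and
#'   `truth` (data.frame `id`, `class`, `cluster`).
#' @export
simulate_sine_copies <- function(retro_sizes = c(11, 3, 2), n_segdup = 4,
                                 n_background = 20, consensus_len = 210,
                                 flank_len = 350, truncation = TRUE,
                                 family = "Bov-tA", seed = 1L) {
  set.seed(seed)
  consensus <- random_seq(consensus_len)
  ids <- character(); el <- character(); lf <- character(); rf <- character()
  cls <- character(); clu <- character()
  add <- function(id, e, l, r, class, cluster) {
    ids <<- c(ids, id); el <<- c(el, e); lf <<- c(lf, l); rf <<- c(rf, r)
    cls <<- c(cls, class); clu <<- c(clu, cluster)
  }
  for (ci in seq_along(retro_sizes)) {
    elem <- mutate_seq(consensus, 2)  # cluster-private variant, still full length
    for (m in seq_len(retro_sizes[ci]))
      add(sprintf("retro%02d_%02d", ci, m), elem, random_seq(flank_len),
          random_seq(flank_len), "retrotransposition",
          sprintf("retro%02d", ci))
  }
  for (ci in seq_len(n_segdup)) {
    elem <- mutate_seq(consensus, 2)
    l <- random_seq(flank_len); r <- random_seq(flank_len)
    add(sprintf("segdup%02d_a", ci), elem, l, r, "segmental_duplication",
        sprintf("segdup%02d", ci))
    add(sprintf("segdup%02d_b", ci), elem, mutate_seq(l, 2), mutate_seq(r, 2),
        "segmental_duplication", sprintf("segdup%02d", ci))
  }
  for (ci in seq_len(n_background)) {
    young <- stats::runif(1) < 0.3
    d <- if (young) abs(stats::rnorm(1, 0.02, 0.01)) else
      abs(stats::rnorm(1, 0.15, 0.03))
    elem <- mutate_seq(consensus, round(d * consensus_len))
    if (truncation && stats::runif(1) < 0.5) {
      cut5 <- sample.int(60, 1)
      cut3 <- sample.int(60, 1)
      elem <- substr(elem, cut5 + 1, nchar(elem) - cut3)
    }
    add(sprintf("bg%03d", ci), elem, random_seq(flank_len),
        random_seq(flank_len), "background", NA_character_)
  }
  list(copies = sine_copies(ids, el, lf, rf, family = family),
       consensus = consensus,
       truth = data.frame(id = ids, class = cls, cluster = clu))
}

#' Simulate a comparator SNP genotype matrix under drift on the tree
#'
#' Each SNP starts at ancestral frequency 0.5 and diffuses along branches
#' (Gaussian increments with variance proportional to branch length, clamped
#' away from fixation); individuals draw binomial dosages from their taxon's
#' tip frequency. Same demography as the TE simulation, for TE-vs-SNP
#' concordance checks.
#'
#' @param tree rooted taxon tree with branch lengths.
#' @param roster individuals data.frame (`sample`, `species`, `subspecies`).
#' @param n_snps number of biallelic markers.
#' @param seed RNG seed.
#' @param drift_var frequency-diffusion variance per unit branch length.
#' @return A `geno_matrix`.
#' @export
simulate_snp_matrix <- function(tree, roster, n_snps, seed = 1L,
                                drift_var = 0.05) {
  set.seed(seed)
  samples <- roster$sample
  if (n_snps == 0) {
    geno <- matrix(integer(), 0, length(samples),
                   dimnames = list(NULL, samples))
    return(genotype_matrix(geno, data.frame(chrom = character(),
                                            pos = integer(),
                                            family = character(),
                                            svlen = numeric()), roster))
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  freq <- matrix(NA_real_, nnode, n_snps)
  freq[root, ] <- 0.5
  ## walk edges root-down (reverse postorder)
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    freq[ch, ] <- pmin(0.99, pmax(0.01, freq[p, ] +
      stats::rnorm(n_snps, 0, sqrt(drift_var * tree$edge.length[e]))))
  }
  tip_of <- match(roster$subspecies, tree$tip.label)
  geno <- vapply(seq_along(samples), function(i)
    stats::rbinom(n_snps, 2L, freq[tip_of[i], ]), integer(n_snps))
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = n_snps)
  colnames(geno) <- samples
  genotype_matrix(geno,
                  data.frame(chrom = paste0("chr",
                                            sample.int(14, n_snps,
                                                       replace = TRUE)),
                             pos = sample.int(1e8, n_snps), family = "SNP",
                             svlen = 1),
                  roster)
}
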