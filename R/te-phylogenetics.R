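## Irreversible-character (Camin-Sokal) parsimony on TE presence/absence
## matrices: encoding, site patterns, tree scoring and search, bootstrap,
## branch mapping, UpSet intersections, per-node heterozygosity, NJ.

#' Encode a genotype matrix as binary presence/absence
#'
#' Heterozygous insertions count as presence (dosage >= 1 -> 1), missing
#' genotypes become `?`, and an artificial outgroup coded 0 at every locus is
#' appended (TE insertions are derived characters; a TE-free outgroup roots
#' the irreversible parsimony). Loci absent from every ingroup individual
#' carry no signal and are dropped with a message.
#'
#' @param matrix a `geno_matrix`.
#' @param outgroup_name name for the artificial outgroup taxon.
#' @return A [presence_matrix()] (loci x taxa; rownames keep the original
#'   locus indices).
#' @export
encode_presence <- function(matrix, outgroup_name = "okapi") {
  g <- matrix$geno
  codes <- ifelse(is.na(g), NA_integer_, as.integer(g >= 1L))
  rownames(codes) <- as.character(seq_len(nrow(codes)))
  all_zero <- rowSums(codes == 1L, na.rm = TRUE) == 0L
  if (any(all_zero))
    message("encode_presence: dropping ", sum(all_zero),
            " loci with no presence in the ingroup")
  codes <- codes[!all_zero, , drop = FALSE]
  if (outgroup_name %in% colnames(codes))
    stop("'", outgroup_name, "' is already a sample name")
  codes <- cbind(codes, matrix(0L, nrow(codes), 1,
                               dimnames = list(NULL, outgroup_name)))
  presence_matrix(codes, outgroup = outgroup_name)
}

#' Collapse an individual-level presence matrix to groups
#'
#' Group-level presence is called when at least `min_individuals` members
#' carry the insertion; absence when all non-missing members lack it; `?`
#' when every member is missing.
#'
#' @param pm a `presence_matrix` over individuals.
#' @param groups named character vector mapping individual -> group (the
#'   outgroup maps to itself automatically).
#' @param min_individuals carriers required to call group-level presence.
#' @return A `presence_matrix` over groups.
#' @export
collapse_presence <- function(pm, groups, min_individuals = 1) {
  og <- attr(pm, "outgroup")
  if (!is.null(og)) groups[og] <- og
  missing_g <- setdiff(colnames(pm), names(groups))
  if (length(missing_g))
    stop("no group for: ", paste(missing_g, collapse = ", "))
  glev <- unique(groups[colnames(pm)])
  out <- sapply(glev, function(g) {
    sub <- pm[, colnames(pm)[groups[colnames(pm)] == g], drop = FALSE]
    n1 <- rowSums(sub == 1L, na.rm = TRUE)
    n_obs <- rowSums(!is.na(sub))
    ifelse(n1 >= min_individuals, 1L, ifelse(n_obs > 0, 0L, NA_integer_))
  })
  rownames(out) <- rownames(pm)
  presence_matrix(out, outgroup = og)
}

#' Classify loci into parsimony site-pattern classes
#'
#' Per locus, over non-missing codes: constant when only one state occurs,
#' singleton when the minority state occurs in exactly one taxon, and
#' parsimony-informative when both states occur in at least two taxa.
#'
#' @param pm a `presence_matrix` (outgroup included in the tally).
#' @return Named integer vector `c(informative, singleton, constant)`.
#' @export
site_pattern_counts <- function(pm) {
  n1 <- rowSums(pm == 1L, na.rm = TRUE)
  n0 <- rowSums(pm == 0L, na.rm = TRUE)
  constant <- sum((n1 == 0) | (n0 == 0))
  singleton <- sum(pmin(n1, n0) == 1)
  informative <- sum(n1 >= 2 & n0 >= 2)
  c(informative = informative, singleton = singleton, constant = constant)
}

## Per-locus purity analysis on a rooted phylo tree. A node is "pure" for a
## locus when its non-missing descendant leaves are all state 1 (and at least
## one exists); the minimum number of 0->1 gains under irreversible parsimony
## is the number of maximal pure nodes. Missing leaves never force or forbid
## a gain. Returns the per-locus gain count and, per locus, the maximal pure
## nodes.
.cs_analysis <- function(tree, pm) {
  taxa <- setdiff(colnames(pm), NULL)
  if (!setequal(tree$tip.label, taxa))
    stop("tree leaves and matrix taxa differ: tree has ",
         paste(setdiff(tree$tip.label, taxa), collapse = ","),
         " / matrix has ", paste(setdiff(taxa, tree$tip.label), collapse = ","))
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  L <- nrow(pm)
  codes <- pm[, tree$tip.label, drop = FALSE]
  has1 <- matrix(FALSE, nnode, L)
  has0 <- matrix(FALSE, nnode, L)
  has1[seq_len(ntip), ] <- t(codes == 1L & !is.na(codes))
  has0[seq_len(ntip), ] <- t(codes == 0L & !is.na(codes))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    has1[p, ] <- has1[p, ] | has1[ch, ]
    has0[p, ] <- has0[p, ] | has0[ch, ]
  }
  pure <- has1 & !has0
  root <- ntip + 1L
  maximal <- pure
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    maximal[ch, ] <- pure[ch, ] & !pure[p, ]
  }
  list(tree = tree, gains = colSums(maximal), maximal = maximal, root = root)
}

#' Camin-Sokal (irreversible) parsimony length of a tree
#'
#' Scores a rooted tree under irreversible parsimony: the root state is 0
#' (absence) and only 0 -> 1 changes (insertions) are allowed, the natural
#' model for TEs that insert irreversibly and are rarely excised. The length
#' of a locus is its minimum number of gains; the tree length is the sum over
#' loci. Missing codes (`?`) impose no constraint. The tree may or may not
#' include the all-zero outgroup tip; the score is unaffected.
#'
#' @param tree rooted `ape::phylo`; leaves must match the matrix taxa exactly
#'   (drop the outgroup column first if the tree lacks that tip).
#' @param pm a `presence_matrix`.
#' @param per_locus return the per-locus gain vector instead of the total.
#' @return Integer tree length (or per-locus integer vector).
#' @export
camin_sokal_length <- function(tree, pm, per_locus = FALSE) {
  if (!ape::is.rooted(tree)) stop("irreversible parsimony needs a rooted tree")
  res <- .cs_analysis(tree, pm)
  if (per_locus) res$gains else sum(res$gains)
}

#' Consistency and homoplasy index of a tree
#'
#' CI is the minimum conceivable number of steps (one gain per variable
#' binary locus) divided by the realized tree length; HI = 1 - CI. A low CI
#' indicates many loci requiring multiple independent gains, i.e. conflicting
#' signal.
#'
#' @inheritParams camin_sokal_length
#' @return Named numeric vector `c(CI, HI)`.
#' @export
ci_hi <- function(tree, pm) {
  len <- camin_sokal_length(tree, pm)
  min_steps <- sum(rowSums(pm == 1L, na.rm = TRUE) > 0)
  ci <- min_steps / len
  c(CI = ci, HI = 1 - ci)
}

## ---- rooted-topology enumeration and rearrangement ------------------------
## Search operates on unlabeled nested-list trees (leaf = character scalar,
## internal node = list(left, right)); conversion to ape::phylo happens at
## the API boundary.

nested_to_newick <- function(t) {
  if (is.character(t)) t else
    paste0("(", nested_to_newick(t[[1]]), ",", nested_to_newick(t[[2]]), ")")
}

canonical_nested <- function(t) {
  if (is.character(t)) return(t)
  a <- canonical_nested(t[[1]])
  b <- canonical_nested(t[[2]])
  if (a <= b) paste0("(", a, ",", b, ")") else paste0("(", b, ",", a, ")")
}

## every tree obtained by attaching leaf/subtree x on an edge of t,
## including the edge above t's root
all_insert <- function(t, x) {
  out <- list(list(t, x))
  if (is.list(t)) {
    for (t2 in all_insert(t[[1]], x)) out[[length(out) + 1]] <- list(t2, t[[2]])
    for (t2 in all_insert(t[[2]], x)) out[[length(out) + 1]] <- list(t[[1]], t2)
  }
  out
}

## all (pruned subtree, remainder) pairs; pruning a child of the root leaves
## the sibling as the remainder
prune_all <- function(t) {
  if (is.character(t)) return(list())
  out <- list(list(sub = t[[1]], rem = t[[2]]),
              list(sub = t[[2]], rem = t[[1]]))
  for (pr in prune_all(t[[1]]))
    out[[length(out) + 1]] <- list(sub = pr$sub, rem = list(pr$rem, t[[2]]))
  for (pr in prune_all(t[[2]]))
    out[[length(out) + 1]] <- list(sub = pr$sub, rem = list(t[[1]], pr$rem))
  out
}

spr_neighbors <- function(t) {
  out <- list()
  seen <- character()
  self <- canonical_nested(t)
  for (pr in prune_all(t)) {
    for (t2 in all_insert(pr$rem, pr$sub)) {
      key <- canonical_nested(t2)
      if (key != self && !(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1]] <- t2
      }
    }
  }
  out
}

#' Enumerate all rooted binary topologies over a set of labels
#'
#' There are (2n-3)!! rooted binary trees on n labeled leaves; enumeration by
#' stepwise leaf insertion yields each exactly once. Practical for n <= 8.
#'
#' @param labels leaf labels (n >= 1).
#' @return List of `ape::phylo` trees (no branch lengths).
#' @export
enumerate_rooted_topologies <- function(labels) {
  stopifnot(length(labels) >= 1)
  trees <- list(labels[1])
  for (lab in labels[-1])
    trees <- unlist(lapply(trees, all_insert, x = lab), recursive = FALSE)
  lapply(trees, function(t)
    ape::read.tree(text = paste0(nested_to_newick(t), ";")))
}

## vectorized irreversible-parsimony score of a nested tree; codes is a list
## of per-taxon integer vectors (0/1/NA) of equal length L.
## Recursion returns (has1, has0, gains-so-far assuming parent not pure).
score_nested <- function(t, codes) {
  rec <- function(t) {
    if (is.character(t)) {
      v <- codes[[t]]
      h1 <- !is.na(v) & v == 1L
      list(h1 = h1, h0 = !is.na(v) & v == 0L, g = as.integer(h1))
    } else {
      a <- rec(t[[1]]); b <- rec(t[[2]])
      h1 <- a$h1 | b$h1
      h0 <- a$h0 | b$h0
      pure <- h1 & !h0
      list(h1 = h1, h0 = h0, g = ifelse(pure, 1L, a$g + b$g))
    }
  }
  sum(rec(t)$g)
}

nested_from_phylo <- function(tree) {
  ntip <- length(tree$tip.label)
  build <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) != 2) stop("tree must be strictly bifurcating")
    list(build(kids[1]), build(kids[2]))
  }
  build(ntip + 1L)
}

#' Search for most-parsimonious trees under irreversible parsimony
#'
#' Exhaustive search enumerates every rooted ingroup topology (feasible for
#' <= 8 ingroup taxa; collapse individuals to populations first for larger
#' rosters) and returns all minima. The heuristic performs random-addition
#' stepwise insertion followed by SPR hill climbing (SPR includes all NNI
#' moves) repeated `reps` times; it approximates TBR-based searches and is
#' guarded by the exhaustive oracle at small sizes.
#'
#' @param pm a `presence_matrix`; the outgroup column (if flagged) is excluded
#'   from the searched topology, as its position is fixed at the root.
#' @param strategy `"exhaustive"` or `"hillclimb"`.
#' @param reps random-addition repetitions for the heuristic.
#' @param seed RNG seed (heuristic only); fixes the result.
#' @return List with `trees` (all best rooted ingroup topologies as
#'   `ape::phylo`), `length` (best score) and `newicks` (canonical forms).
#' @export
parsimony_search <- function(pm, strategy = c("hillclimb", "exhaustive"),
                             reps = 100, seed = NULL) {
  strategy <- match.arg(strategy)
  og <- attr(pm, "outgroup")
  ing <- ingroup_taxa(pm)
  codes <- lapply(ing, function(tx) pm[, tx])
  names(codes) <- ing
  if (length(ing) == 1)  # trivial: one gain per locus present in the taxon
    return(list(trees = list(),
                length = sum(pm[, ing] == 1L, na.rm = TRUE),
                newicks = paste0(ing, ";")))
  if (strategy == "exhaustive") {
    if (length(ing) > 8)
      stop("exhaustive search supports at most 8 ingroup taxa (",
           length(ing), " given); collapse to populations or use hillclimb")
    trees <- list(ing[1])
    for (lab in ing[-1])
      trees <- unlist(lapply(trees, all_insert, x = lab), recursive = FALSE)
    scores <- vapply(trees, score_nested, numeric(1), codes = codes)
    best <- trees[scores == min(scores)]
  } else {
    if (!is.null(seed)) set.seed(seed)
    best_len <- Inf
    best_keys <- character()
    best <- list()
    for (r in seq_len(reps)) {
      ord <- sample(ing)
      t <- ord[1]
      for (lab in ord[-1]) {
        cands <- all_insert(t, lab)
        sc <- vapply(cands, score_nested, numeric(1), codes = codes)
        t <- cands[[which.min(sc)]]
      }
      len <- score_nested(t, codes)
      repeat {
        nb <- spr_neighbors(t)
        if (!length(nb)) break
        sc <- vapply(nb, score_nested, numeric(1), codes = codes)
        if (min(sc) < len) {
          len <- min(sc)
          t <- nb[[which.min(sc)]]
        } else break
      }
      key <- canonical_nested(t)
      if (len < best_len) {
        best_len <- len
        best <- list(t)
        best_keys <- key
      } else if (len == best_len && !(key %in% best_keys)) {
        best[[length(best) + 1]] <- t
        best_keys <- c(best_keys, key)
      }
    }
  }
  keys <- vapply(best, canonical_nested, character(1))
  uniq <- !duplicated(keys)
  best <- best[uniq]
  keys <- keys[uniq]
  ord <- order(keys)
  best <- best[ord]
  keys <- keys[ord]
  list(trees = lapply(best, function(t)
         ape::read.tree(text = paste0(nested_to_newick(t), ";"))),
       length = if (length(best)) score_nested(best[[1]], codes) else NA,
       newicks = paste0(keys, ";"))
}

nested_clades <- function(t) {
  out <- list()
  rec <- function(t) {
    if (is.character(t)) return(t)
    tips <- c(rec(t[[1]]), rec(t[[2]]))
    out[[length(out) + 1]] <<- sort(tips)
    tips
  }
  rec(t)
  out
}

phylo_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  lapply((ntip + 1):(ntip + tree$Nnode), function(nd)
    sort(tree$tip.label[tip_descendants(tree, nd)]))
}

#' Bootstrap support for the clades of a tree
#'
#' Resamples loci with replacement; each replicate is re-searched with the
#' SPR heuristic and a clade's support is the percentage of replicates whose
#' best tree contains it.
#'
#' @param pm a `presence_matrix`.
#' @param tree rooted ingroup tree whose clades are evaluated.
#' @param replicates bootstrap replicates.
#' @param seed RNG seed; fixes the supports.
#' @param search_reps random-addition repetitions per replicate.
#' @return data.frame with `clade` (tip sets as `a|b|c`) and `support` (%).
#' @export
bootstrap_support <- function(pm, tree, replicates = 1000, seed = NULL,
                              search_reps = 3) {
  if (!is.null(seed)) set.seed(seed)
  clades <- phylo_clades(tree)
  keys <- vapply(clades, paste, character(1), collapse = "|")
  hits <- setNames(numeric(length(keys)), keys)
  for (b in seq_len(replicates)) {
    idx <- sample.int(nrow(pm), replace = TRUE)
    pm_b <- presence_matrix(pm[idx, , drop = FALSE],
                            outgroup = attr(pm, "outgroup"))
    res <- parsimony_search(pm_b, "hillclimb", reps = search_reps)
    rep_keys <- unique(unlist(lapply(res$trees, function(tr)
      vapply(phylo_clades(tr), paste, character(1), collapse = "|"))))
    hits[keys %in% rep_keys] <- hits[keys %in% rep_keys] + 1
  }
  data.frame(clade = keys, support = 100 * hits / replicates,
             row.names = NULL)
}

## height of every node above the tips (max distance to a descendant tip)
node_heights <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  h <- numeric(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    h[p] <- max(h[p], h[ch] + tree$edge.length[e])
  }
  h
}

#' Map each locus to its branch of origin
#'
#' A locus whose presence taxa form exactly one clade is parsimoniously
#' explained by a single insertion on that clade's stem branch; its age is
#' the stem midpoint depth (time before present, in the tree's branch-length
#' units). Loci whose presence taxa are scattered over several clades require
#' multiple gains and are flagged `conflicting`. Loci present in all ingroup
#' taxa map to the root stem (supply `tree$root.edge` for a meaningful age).
#'
#' @param pm a `presence_matrix`; taxa must match the tree tips (outgroup
#'   excluded automatically).
#' @param tree rooted ingroup `ape::phylo` with branch lengths.
#' @return data.frame with `locus` (rownames of `pm`), `status`, `branch`
#'   (label of the clade's ancestral node), `age`, `pattern`.
#' @export
map_to_branches <- function(pm, tree) {
  og <- attr(pm, "outgroup")
  if (!is.null(og)) pm <- presence_matrix(pm[, ingroup_taxa(pm), drop = FALSE])
  res <- .cs_analysis(tree, pm)
  tree <- res$tree
  ntip <- length(tree$tip.label)
  h <- node_heights(tree)
  elen <- numeric(ntip + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  elen[ntip + 1L] <- tree$root.edge %||% 0
  labels <- c(tree$tip.label,
              tree$node.label %||% paste0("node", seq_len(tree$Nnode)))
  if (!length(tree$node.label)) labels <- c(tree$tip.label,
                                            paste0("node", (ntip + 1):(ntip + tree$Nnode)))
  n_max <- colSums(res$maximal)
  node_of <- apply(res$maximal, 2, function(col) which(col)[1])
  pattern <- apply(pm == 1L, 1, function(x)
    paste(sort(colnames(pm)[which(x)]), collapse = "+"))
  assigned <- n_max == 1L
  data.frame(locus = rownames(pm) %||% as.character(seq_len(nrow(pm))),
             status = ifelse(assigned, "assigned", "conflicting"),
             branch = ifelse(assigned, labels[node_of], NA_character_),
             age = ifelse(assigned, h[node_of] + elen[node_of] / 2, NA_real_),
             pattern = pattern, row.names = NULL)
}

#' Counts of loci per species-presence intersection (UpSet table)
#'
#' Species-level presence is called when at least `min_individuals` of the
#' species' members carry the insertion; each locus contributes to exactly
#' one intersection pattern, so the counts partition the locus set.
#'
#' @param matrix a `geno_matrix`.
#' @param by population column to intersect over (`"species"` or
#'   `"subspecies"`).
#' @param min_individuals carriers needed to count a species as present.
#' @return data.frame with `pattern` (species set as `a+b`), `degree` and
#'   `count`, sorted by decreasing count.
#' @export
upset_counts <- function(matrix, by = "species", min_individuals = 1) {
  key <- matrix$populations[[by]]
  if (is.null(key)) stop("unknown grouping column: ", by)
  groups <- split(seq_len(ncol(matrix$geno)), key)
  pres <- sapply(groups, function(j)
    rowSums(matrix$geno[, j, drop = FALSE] >= 1L, na.rm = TRUE) >=
      min_individuals)
  pattern <- apply(pres, 1, function(x) paste(sort(names(groups)[x]),
                                              collapse = "+"))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab),
                    degree = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                    count = as.integer(tab), row.names = NULL)
  out[order(-out$count), ]
}

#' Heterozygous and homozygous insertion counts per branch
#'
#' For loci mapped to a branch, tallies heterozygous (dosage 1) versus
#' homozygous (dosage 2) genotype calls among carrier individuals. Old
#' insertions drift towards fixation, so the heterozygous percentage decays
#' with branch age.
#'
#' @param matrix the `geno_matrix` the presence matrix was encoded from.
#' @param assignments output of [map_to_branches()] (`locus` must index rows
#'   of `matrix`).
#' @return data.frame per branch: `branch`, `n_loci`, `hom`, `het`,
#'   `het_pct`.
#' @export
node_heterozygosity <- function(matrix, assignments) {
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  idx <- as.integer(a$locus)
  if (anyNA(idx) || any(idx < 1 | idx > nrow(matrix$geno)))
    stop("assignments$locus must index rows of the genotype matrix")
  do.call(rbind, lapply(split(seq_len(nrow(a)), a$branch), function(rows) {
    g <- matrix$geno[idx[rows], , drop = FALSE]
    het <- sum(g == 1L, na.rm = TRUE)
    hom <- sum(g == 2L, na.rm = TRUE)
    data.frame(branch = a$branch[rows[1]], n_loci = length(rows),
               hom = hom, het = het,
               het_pct = if (het + hom > 0) 100 * het / (het + hom) else NaN)
  }))
}

#' Pairwise Hamming distances between individuals
#'
#' Counts loci at which two individuals' dosages differ, over loci where both
#' are non-missing.
#'
#' @param matrix a `geno_matrix`.
#' @param proportion divide by the number of comparable loci.
#' @return A `dist` object over individuals.
#' @export
hamming_distance <- function(matrix, proportion = FALSE) {
  g <- matrix$geno
  n <- ncol(g)
  d <- matrix(0, n, n, dimnames = list(colnames(g), colnames(g)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      dd <- sum(g[ok, i] != g[ok, j])
      d[i, j] <- d[j, i] <- if (proportion) dd / max(1, sum(ok)) else dd
    }
  }
  stats::as.dist(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining (Saitou & Nei); additive distances are
#' recovered exactly.
#'
#' @param dist a `dist` or symmetric matrix.
#' @return Unrooted `ape::phylo`.
#' @export
nj_tree <- function(dist) ape::nj(stats::as.dist(dist))
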