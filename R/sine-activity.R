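## Detection of currently active SINE families: full-length filtering,
## exact-identity clustering, pseudocluster (segmental duplication)
## classification and cross-assembly insertion dating.

#' Retain only full-length SINE copies
#'
#' A copy is full length when its termini are truncated by strictly less than
#' `max_truncation` bp relative to the family consensus at both the 5' and 3'
#' end. Truncation is measured from an end-gap-free alignment of the copy to
#' the consensus: the unaligned consensus overhang at each terminus.
#'
#' @param copies a [sine_copies()] table.
#' @param consensus family consensus sequence.
#' @param max_truncation copies truncated by this many bp or more (either
#'   terminus) are removed.
#' @return The retained copies.
#' @export
full_length_filter <- function(copies, consensus, max_truncation = 15) {
  if (!nzchar(consensus)) stop("empty consensus sequence")
  clen <- nchar(consensus)
  keep <- vapply(copies$element_seq, function(s) {
    if (!nzchar(s)) return(FALSE)
    pa <- align_overlap(s, consensus)
    sub <- Biostrings::subject(pa)
    trunc5 <- Biostrings::start(sub) - 1L
    trunc3 <- clen - Biostrings::end(sub)
    trunc5 < max_truncation && trunc3 < max_truncation
  }, logical(1), USE.NAMES = FALSE)
  copies[keep, , drop = FALSE]
}

## linking predicate of the identity clustering: exact substring containment
## with bidirectional (cov-mode 0 style) length-ratio coverage
.identity_linked <- function(a, b, min_identity, min_coverage) {
  if (min_identity >= 1) {
    shorter <- if (nchar(a) <= nchar(b)) a else b
    longer <- if (nchar(a) <= nchar(b)) b else a
    if (nchar(shorter) / nchar(longer) < min_coverage) return(FALSE)
    if (grepl("N", shorter, fixed = TRUE)) return(FALSE)  # N never matches
    grepl(shorter, longer, fixed = TRUE)
  } else {
    if (min(nchar(a), nchar(b)) / max(nchar(a), nchar(b)) < min_coverage)
      return(FALSE)
    seq_identity(a, b) >= min_identity
  }
}

#' Cluster SINE copies at exact identity
#'
#' Two copies are linked when one is an exact substring of the other (100%
#' identity) and the shorter covers at least `min_coverage` of the longer
#' (coverage of both sequences, as in bidirectional-coverage clustering).
#' Clusters are connected components of the link relation; the representative
#' is the longest member (ties broken by lexicographically smallest ID), so
#' clustering is invariant to input order.
#'
#' @param copies a [sine_copies()] table (run [full_length_filter()] first;
#'   fragmented copies must not enter the clustering).
#' @param min_identity required identity (1.0 = byte-identical/substring).
#' @param min_coverage minimum length ratio shorter/longer.
#' @return data.frame with one row per cluster: `cluster_id`, `representative`,
#'   `size`, `family` and a list-column `members` of copy IDs.
#' @export
identity_cluster <- function(copies, min_identity = 1.0, min_coverage = 0.98) {
  if (min_identity > 1) stop("min_identity cannot exceed 1")
  n <- nrow(copies)
  if (n == 0)
    return(data.frame(cluster_id = character(), representative = character(),
                      size = integer(), family = character()))
  ## canonical order first, so components and representatives are
  ## independent of input order
  ord <- order(-nchar(copies$element_seq), copies$id)
  copies <- copies[ord, , drop = FALSE]
  edges <- matrix(integer(), 0, 2)
  if (n > 1) {
    ## group identical sequences cheaply, test substring links across groups
    pairs <- utils::combn(n, 2)
    linked <- vapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      .identity_linked(copies$element_seq[i], copies$element_seq[j],
                       min_identity, min_coverage)
    }, logical(1))
    edges <- t(pairs[, linked, drop = FALSE])
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  clusters <- split(seq_len(n), comp)
  rows <- lapply(clusters, function(idx) {
    idx <- idx[order(-nchar(copies$element_seq[idx]), copies$id[idx])]
    data.frame(representative = copies$id[idx[1]], size = length(idx),
               family = copies$family[idx[1]],
               members = I(list(copies$id[idx])))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$size, out$representative), , drop = FALSE]
  out$cluster_id <- sprintf("cluster_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c("cluster_id", "representative", "size", "family", "members")]
}

#' Label clusters as retrotransposition or segmental duplication
#'
#' Retrotransposition copies an element into an unrelated genomic context, so
#' identical copies have unrelated flanks; segmental duplication copies the
#' element together with its flanks. A multi-copy cluster is labeled
#' `segmental_duplication` when any member pair reaches the flank-identity
#' threshold on *both* flanks, `retrotransposition` otherwise; single-copy
#' clusters are `singleton`.
#'
#' @param clusters output of [identity_cluster()].
#' @param copies the [sine_copies()] table with flanks.
#' @param flank_len flank length to compare (bp, element-proximal).
#' @param flank_identity_threshold per-flank identity at or above which a
#'   pair is a duplication.
#' @return `clusters` with an added `label` column.
#' @export
classify_cluster <- function(clusters, copies, flank_len = 350,
                             flank_identity_threshold = 0.98) {
  idx <- match(unlist(clusters$members), copies$id)
  if (anyNA(idx))
    stop("copies missing from table: ",
         paste(unlist(clusters$members)[is.na(idx)], collapse = ", "))
  labels <- vapply(clusters$members, function(ids) {
    if (length(ids) == 1) return("singleton")
    rows <- copies[match(ids, copies$id), , drop = FALSE]
    if (any(!nzchar(rows$left_flank)) || any(!nzchar(rows$right_flank)))
      stop("missing flanks for copy: ",
           paste(rows$id[!nzchar(rows$left_flank) |
                           !nzchar(rows$right_flank)], collapse = ", "))
    lf <- substring(rows$left_flank,
                    pmax(1L, nchar(rows$left_flank) - flank_len + 1L))
    rf <- substring(rows$right_flank, 1L, flank_len)
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        if (seq_identity(lf[i], lf[j]) >= flank_identity_threshold &&
            seq_identity(rf[i], rf[j]) >= flank_identity_threshold)
          return("segmental_duplication")
      }
    }
    "retrotransposition"
  }, character(1))
  clusters$label <- labels
  clusters
}

#' Summarize SINE cluster activity per family
#'
#' @param clusters labeled clusters from [classify_cluster()].
#' @return data.frame per family: number of retrotransposition clusters (size
#'   >= 2), largest retrotransposition cluster size, number of
#'   segmental-duplication clusters, number of singletons, and total copies.
#' @export
activity_report <- function(clusters) {
  do.call(rbind, lapply(split(clusters, clusters$family), function(cl) {
    retro <- cl[cl$label == "retrotransposition", , drop = FALSE]
    data.frame(family = cl$family[1],
               n_retro_clusters = nrow(retro),
               max_retro_cluster = if (nrow(retro)) max(retro$size) else 0L,
               n_segdup_clusters = sum(cl$label == "segmental_duplication"),
               n_singletons = sum(cl$label == "singleton"),
               n_copies = sum(cl$size))
  }))
}

#' Date insertions from presence/absence across genome assemblies
#'
#' A copy present in a monophyletic set of assemblies and absent (or unknown)
#' elsewhere inserted on the stem branch above that set's most recent common
#' ancestor; e.g. a copy present in giraffe but absent in okapi postdates the
#' giraffe MRCA. Copies present in a non-monophyletic set (an assembly inside
#' the MRCA clade is scored absent) are labeled `homoplastic/unknown`.
#'
#' @param presence matrix or data.frame (copies x assemblies) with values
#'   `"present"`, `"absent"` or `"unknown"`; column names must be tree leaves.
#' @param species_tree rooted `ape::phylo` over the assemblies.
#' @return data.frame with `copy`, `era` (stem-branch label: the MRCA clade's
#'   tip set, `root` for presence in all assemblies, or
#'   `homoplastic/unknown`).
#' @export
date_insertions <- function(presence, species_tree) {
  presence <- as.matrix(presence)
  if (!all(colnames(presence) %in% species_tree$tip.label))
    stop("assemblies not on the tree: ",
         paste(setdiff(colnames(presence), species_tree$tip.label),
               collapse = ", "))
  eras <- apply(presence, 1, function(row) {
    pres <- colnames(presence)[row == "present"]
    if (length(pres) == 0) return("unknown")
    if (length(pres) == 1) {
      clade_tips <- pres
    } else {
      mrca <- ape::getMRCA(species_tree, pres)
      clade_tips <- species_tree$tip.label[
        unlist(tip_descendants(species_tree, mrca))]
    }
    inside <- row[intersect(clade_tips, colnames(presence))]
    if (any(inside == "absent")) return("homoplastic/unknown")
    if (setequal(clade_tips, species_tree$tip.label)) return("root")
    paste0("stem:", paste(sort(clade_tips), collapse = "+"))
  })
  data.frame(copy = rownames(presence) %||% seq_len(nrow(presence)),
             era = unname(eras))
}

## tip indices descending from an internal node (self for tips)
tip_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer()
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- kids[kids <= ntip]
    out <- c(out, tips)
    stack <- c(stack, kids[kids > ntip])
  }
  out
}
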