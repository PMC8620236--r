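## small helpers shared by the parsimony tests
pm4 <- function(codes, taxa = c("A", "B", "C", "D")) {
  m <- matrix(codes, ncol = length(taxa), byrow = TRUE,
              dimnames = list(NULL, taxa))
  presence_matrix(m)
}
tree4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("presence encoding maps dosage, missing and drops empty loci", {
  geno <- matrix(c(0L, 1L, 2L,
                   NA, 0L, 1L,
                   0L, 0L, 0L), 3, 3, byrow = TRUE,
                 dimnames = list(NULL, c("S1", "S2", "S3")))
  gm <- toy_matrix(geno)
  expect_message(pm <- encode_presence(gm, "okapi"), "dropping 1")
  expect_equal(nrow(pm), 2)
  expect_identical(unname(pm[1, c("S1", "S2", "S3")]), c(0L, 1L, 1L))
  expect_true(is.na(pm[2, "S1"]))
  expect_true(all(pm[, "okapi"] == 0))
  expect_equal(attr(pm, "outgroup"), "okapi")
  expect_equal(rownames(pm), c("1", "2"))  # original locus indices
})

test_that("site-pattern classes partition loci and match a brute scan", {
  pm <- pm4(c(1, 0, 0, 0,
              1, 1, 0, 0,
              1, 1, 1, 1,
              1, NA, 0, 0))
  counts <- site_pattern_counts(pm)
  expect_equal(unname(counts["singleton"]), 2)  # one 1 / one 1 among typed
  expect_equal(unname(counts["informative"]), 1)
  expect_equal(unname(counts["constant"]), 1)
  expect_equal(sum(counts), nrow(pm))

  set.seed(41)
  big <- matrix(sample(c(0L, 1L, NA), 500 * 10, TRUE, prob = c(.4, .5, .1)),
                500, 10, dimnames = list(NULL, paste0("t", 1:10)))
  pmb <- presence_matrix(big)
  brute <- table(factor(apply(big, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(unique(x)) <= 1) "constant"
    else if (min(sum(x == 0), sum(x == 1)) == 1) "singleton"
    else "informative"
  }), levels = c("informative", "singleton", "constant")))
  expect_equal(unname(site_pattern_counts(pmb)),
               as.integer(brute))
})

test_that("irreversible parsimony counts minimal gains", {
  ## 1-leaves forming one clade: a single gain
  expect_equal(camin_sokal_length(tree4, pm4(c(1, 1, 0, 0))), 1)
  ## 1s at A and C on ((A,B),(C,D)): two independent gains
  expect_equal(camin_sokal_length(tree4, pm4(c(1, 0, 1, 0))), 2)
  ## missing leaves are free: all-? except one 1 needs one gain
  expect_equal(camin_sokal_length(tree4, pm4(c(1, NA, NA, NA))), 1)
  ## missing data cannot force extra gains
  expect_equal(camin_sokal_length(tree4, pm4(c(1, NA, 1, NA))), 1)
  expect_error(camin_sokal_length(tree4, pm4(c(1, 0, 0), c("A", "B", "X"))),
               "differ")
  expect_error(camin_sokal_length(ape::read.tree(text = "(A:1,B:1,C:1);"),
                                  pm4(c(1, 0, 1), c("A", "B", "C"))),
               "rooted")
})

test_that("parsimony equals the gain-subset oracle, with missing data", {
  set.seed(42)
  for (n in 4:5) {
    topos <- enumerate_rooted_topologies(LETTERS[1:n])
    for (tr in topos[sample(length(topos), min(10, length(topos)))]) {
      chars <- matrix(sample(c(0L, 1L, NA), 50 * n, TRUE,
                             prob = c(.4, .4, .2)), 50, n,
                      dimnames = list(NULL, tr$tip.label))
      pm <- presence_matrix(chars)
      prep <- cs_oracle_prep(tr)
      impl <- camin_sokal_length(tr, pm, per_locus = TRUE)
      orac <- vapply(seq_len(50), function(l)
        cs_oracle_min_gains(prep, chars[l, prep$tips]), integer(1))
      expect_identical(as.integer(impl), orac)
    }
  }
})

test_that("parsimony length ignores locus order and taxon relabeling", {
  set.seed(43)
  chars <- matrix(sample(c(0L, 1L), 200, TRUE), 50, 4,
                  dimnames = list(NULL, c("A", "B", "C", "D")))
  pm <- presence_matrix(chars)
  len <- camin_sokal_length(tree4, pm)
  expect_equal(camin_sokal_length(tree4,
                                  presence_matrix(chars[sample(50), ])), len)
  ## consistent relabeling of tree and matrix leaves the score unchanged
  perm <- c(A = "W", B = "X", C = "Y", D = "Z")
  tr2 <- tree4; tr2$tip.label <- unname(perm[tr2$tip.label])
  chars2 <- chars; colnames(chars2) <- unname(perm[colnames(chars)])
  expect_equal(camin_sokal_length(tr2, presence_matrix(chars2)), len)
})

test_that("CI/HI reflect homoplasy and always sum to one", {
  clean <- pm4(c(1, 1, 0, 0,
                 0, 0, 1, 1,
                 1, 1, 1, 1))
  expect_equal(unname(ci_hi(tree4, clean)), c(1, 0))

  ## equal parts clean and two-step loci: 3 realized steps per 2 minimum
  mixed <- pm4(c(rep(c(1, 1, 0, 0), 20), rep(c(1, 0, 1, 0), 20)))
  expect_equal(unname(ci_hi(tree4, mixed)[1]), 10 / 15, tolerance = 1e-12)

  set.seed(44)
  rnd <- presence_matrix(matrix(sample(c(0L, 1L), 400, TRUE), 100, 4,
                                dimnames = list(NULL, c("A", "B", "C", "D"))))
  ch <- ci_hi(tree4, rnd)
  expect_equal(unname(ch[1] + ch[2]), 1)
})

test_that("exhaustive search recovers clean topologies at minimal length", {
  cfg <- sim_config(gain_rate = c("L1-1_Gir" = 12), seed = 45)
  sim <- simulate_insertions(cfg)
  pm <- encode_presence(sim$matrix)
  spp <- setNames(cfg$individuals$species, cfg$individuals$sample)
  pm_sp <- collapse_presence(pm, spp)
  res <- parsimony_search(pm_sp, "exhaustive")
  expect_equal(length(res$trees), 1)
  expect_equal(res$newicks, "((masai,southern),(northern,reticulated));")
  ## every simulated locus is clean at the species level: length = #loci
  expect_equal(res$length, nrow(pm_sp))
  expect_error(parsimony_search(
    presence_matrix(matrix(0:1, 2, 9,
                           dimnames = list(NULL, letters[1:9]))),
    "exhaustive"), "at most 8")
})

test_that("SPR hill climbing finds the exhaustive optimum on 6 taxa", {
  set.seed(46)
  hit <- 0
  for (s in 1:20) {
    chars <- matrix(sample(c(0L, 1L), 60 * 6, TRUE, prob = c(.55, .45)),
                    60, 6, dimnames = list(NULL, letters[1:6]))
    chars <- chars[rowSums(chars) > 0, , drop = FALSE]
    pm <- presence_matrix(chars)
    ex <- parsimony_search(pm, "exhaustive")
    hc <- parsimony_search(pm, "hillclimb", reps = 10, seed = s)
    hit <- hit + (hc$length == ex$length)
  }
  expect_gte(hit, 19)
})

test_that("single-taxon ingroup reduces to counting variable loci", {
  codes <- matrix(c(1L, 0L, 1L, 0L, 0L, 0L), 3, 2,
                  dimnames = list(NULL, c("A", "okapi")))
  pm <- presence_matrix(codes, outgroup = "okapi")
  res <- parsimony_search(pm, "exhaustive")
  expect_equal(res$length, 2)
})

test_that("bootstrap supports are deterministic, bounded and high on clean data", {
  set.seed(47)
  ## strong clean signal: many loci per clade of ((A,B),(C,D))
  chars <- rbind(matrix(rep(c(1L, 1L, 0L, 0L), 30), 30, byrow = TRUE),
                 matrix(rep(c(0L, 0L, 1L, 1L), 30), 30, byrow = TRUE),
                 matrix(rep(c(1L, 0L, 0L, 0L), 10), 10, byrow = TRUE))
  colnames(chars) <- c("A", "B", "C", "D")
  pm <- presence_matrix(chars)
  bs <- bootstrap_support(pm, tree4, replicates = 60, seed = 1,
                          search_reps = 2)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  expect_true(all(bs$support[bs$clade %in% c("A|B", "C|D")] >= 95))
  bs2 <- bootstrap_support(pm, tree4, replicates = 60, seed = 1,
                           search_reps = 2)
  expect_identical(bs, bs2)
})

test_that("branch mapping assigns clean loci and flags conflicts", {
  tr <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r:1;")
  tr$root.edge <- 1
  pm <- pm4(c(1, 1, 1, 1,
              1, 0, 1, 0,
              1, 1, 0, 0,
              0, 0, 0, 1))
  asg <- map_to_branches(pm, tr)
  expect_equal(asg$status, c("assigned", "conflicting", "assigned",
                             "assigned"))
  expect_equal(asg$branch[1], "r")      # present in all -> root stem
  expect_equal(asg$age[1], 2.5)         # root height 2 + root.edge/2
  expect_equal(asg$branch[3], "ab")
  expect_equal(asg$age[3], 1.5)
  expect_equal(asg$branch[4], "D")
  expect_equal(asg$age[4], 0.5)

  ## noise-free simulation: assigned loci recover their true branch
  cfg <- sim_config(seed = 48)
  sim <- simulate_insertions(cfg)
  pm_ind <- encode_presence(sim$matrix)
  ssp <- setNames(cfg$individuals$subspecies, cfg$individuals$sample)
  pm_tax <- collapse_presence(pm_ind, ssp)
  asg2 <- map_to_branches(pm_tax, cfg$tree)
  ok <- asg2$status == "assigned"
  expect_gte(mean(ok), 0.99)
  truth_branch <- sim$truth$branch[as.integer(asg2$locus)]
  expect_gte(mean(asg2$branch[ok] == truth_branch[ok]), 0.99)
})

test_that("UpSet intersections partition loci and match a brute tally", {
  pops <- data.frame(sample = c("n1", "n2", "r1", "m1", "s1"),
                     species = c("northern", "northern", "reticulated",
                                 "masai", "southern"),
                     subspecies = c("Kordofan", "Nubian", "Reticulated",
                                    "Masai", "Angolan"))
  geno <- matrix(c(1L, 2L, 1L, 1L, 2L,   # all four species
                   0L, 1L, 0L, 0L, 0L,   # northern only
                   0L, 0L, 0L, 1L, 0L),  # Masai only
                 3, 5, byrow = TRUE, dimnames = list(NULL, pops$sample))
  gm <- genotype_matrix(geno, data.frame(chrom = "c", pos = 1:3,
                                         family = "f", svlen = 1), pops)
  up <- upset_counts(gm, by = "species")
  expect_equal(up$count[up$pattern == "masai+northern+reticulated+southern"],
               1)
  expect_equal(up$count[up$pattern == "northern"], 1)
  expect_equal(up$count[up$pattern == "masai"], 1)
  expect_equal(sum(up$count), 3)

  set.seed(49)
  cfg <- sim_config(seed = 49)
  sim <- simulate_insertions(cfg)
  up2 <- upset_counts(sim$matrix, by = "species")
  expect_equal(sum(up2$count), nrow(sim$matrix$geno))
  brute <- table(apply(sim$matrix$geno, 1, function(g) {
    sp <- sort(unique(cfg$individuals$species[which(g >= 1)]))
    paste(sp, collapse = "+")
  }))
  expect_equal(setNames(up2$count, up2$pattern)[names(brute)],
               setNames(as.integer(brute), names(brute)))
})

test_that("per-branch heterozygosity conserves genotype calls", {
  cfg <- sim_config(seed = 50)
  sim <- simulate_insertions(cfg)
  pm <- encode_presence(sim$matrix)
  ssp <- setNames(cfg$individuals$subspecies, cfg$individuals$sample)
  asg <- map_to_branches(collapse_presence(pm, ssp), cfg$tree)
  nh <- node_heterozygosity(sim$matrix, asg)
  idx <- as.integer(asg$locus[asg$status == "assigned"])
  g <- sim$matrix$geno[idx, , drop = FALSE]
  expect_equal(sum(nh$hom + nh$het), sum(g >= 1L, na.rm = TRUE))
  ## a branch whose loci are all homozygous among carriers scores 0%
  gm0 <- toy_matrix(matrix(c(2L, 2L, 0L), 1, 3))
  asg0 <- data.frame(locus = "1", status = "assigned", branch = "b",
                     age = 1, pattern = "x")
  expect_equal(node_heterozygosity(gm0, asg0)$het_pct, 0)
})

test_that("neighbor joining recovers additive distances exactly", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("A", "B", "C")]), c(1, 1, 2))

  set.seed(51)
  true <- ape::rtree(5)
  dd <- stats::as.dist(ape::cophenetic.phylo(true))
  rec <- nj_tree(dd)
  expect_equal(ape::dist.topo(ape::unroot(true), rec),
               structure(0, names = "PH85"), ignore_attr = TRUE)
  expect_equal(max(abs(ape::cophenetic.phylo(rec)[true$tip.label,
                                                  true$tip.label] -
                         as.matrix(dd)[true$tip.label, true$tip.label])),
               0, tolerance = 1e-9)
})

test_that("Hamming distance counts genotype mismatches over shared calls", {
  gm <- toy_matrix(matrix(c(0L, 1L, 2L,
                            0L, 1L, 2L,
                            2L, 0L, NA), 3, 3,
                          dimnames = list(NULL, c("x", "y", "z"))))
  d <- as.matrix(hamming_distance(gm))
  expect_equal(d["x", "y"], 0)
  expect_equal(d["x", "z"], 2)  # third locus missing in z: not compared
  expect_equal(d["y", "z"], 2)
})
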