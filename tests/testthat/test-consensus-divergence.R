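random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

test_that("end-gap-free identity agrees with the DP alignment oracle", {
  set.seed(21)
  ## identical, substring and point-mutated pairs have unambiguous optimal
  ## alignments, so the two independent implementations must agree exactly
  for (i in 1:15) {
    a <- random_dna(sample(40:80, 1))
    cases <- list(c(a, a),
                  c(a, substr(a, 5, nchar(a) - 3)),
                  c(a, {   # ~10% substitutions, no indels
                    ch <- strsplit(a, "")[[1]]
                    k <- max(1, round(length(ch) * 0.1))
                    pos <- sample(seq_along(ch), k)
                    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                           ch[p]), 1)
                    paste(ch, collapse = "")
                  }))
    for (cs in cases)
      expect_equal(seq_identity(cs[1], cs[2]),
                   nw_overlap_identity(cs[1], cs[2]), tolerance = 1e-12)
  }
  ## N never matches, even against N
  expect_lt(seq_identity("ACGTNACGT", "ACGTNACGT"), 1)
})

test_that("segmental-duplication dedup drops later copies with shared flanks", {
  set.seed(22)
  fl <- random_dna(350); fr <- random_dna(350)
  copies <- sine_copies(c("a", "b", "c"),
                        element_seq = rep(random_dna(200), 3),
                        left_flank = c(fl, fl, random_dna(350)),
                        right_flank = c(fr, fr, random_dna(350)))
  kept <- dedup_segmental(copies)
  expect_equal(kept$id, c("a", "c"))  # b discarded: identical flanks, later
  ## ~50% identical flanks (random sequences): both retained
  two <- copies[c(1, 3), ]
  expect_equal(dedup_segmental(two)$id, c("a", "c"))
  expect_lt(nw_overlap_identity(paste0(two$left_flank[1], two$right_flank[1]),
                                paste0(two$left_flank[2], two$right_flank[2])),
            0.98)
  expect_equal(dedup_segmental(copies[1, , drop = FALSE])$id, "a")
  expect_error(dedup_segmental(copies, flank_len = 0), "positive")
})

test_that("majority consensus applies the CpG restoration rule", {
  expect_equal(majority_consensus(rep("ACGT", 3)), "ACGT")
  ## rows with dinucleotides TG,TG,CG,TG,CA: CG fraction 0.2 >= 0.1 and
  ## TG+CG = 4/5 is the majority -> restored to CG
  aln <- c("TG", "TG", "CG", "TG", "CA")
  expect_equal(majority_consensus(aln, cpg_fraction = 0.10), "CG")
  ## raising the threshold above the observed CG fraction keeps the decayed
  ## state
  expect_equal(majority_consensus(aln, cpg_fraction = 0.5), "TG")
  expect_error(majority_consensus(c("AC", "ACG")), "ragged")
  expect_error(majority_consensus("ACGT"), ">= 2")
})

test_that("plain consensus equals a brute-force per-column mode", {
  set.seed(23)
  for (rep in 1:10) {
    nrow_ <- sample(3:9, 1); L <- sample(10:40, 1)
    m <- matrix(sample(c("A", "C", "G", "T", "-"), nrow_ * L, TRUE,
                       prob = c(.22, .22, .22, .22, .12)), nrow_, L)
    aln <- apply(m, 1, paste, collapse = "")
    brute <- paste(Filter(function(x) x != "-",
                          vapply(seq_len(L), function(j) {
      col <- m[, j]
      if (mean(col == "-") > 0.5) return("-")
      col <- col[col != "-"]
      names(sort(table(col), decreasing = TRUE))[1]
    }, "")), collapse = "")
    expect_equal(plain_consensus(aln), brute)
  }
})

test_that("K2P distance follows the closed form and flags saturation", {
  same <- k2p("ACGTACGT", "ACGTACGT")
  expect_equal(same$P, 0); expect_equal(same$Q, 0); expect_equal(same$d, 0)

  ## constructed 100 bp pair with 10 transitions and 5 transversions
  a <- strsplit(paste(rep("ACGT", 25), collapse = ""), "")[[1]]
  b <- a
  b[1:10] <- c(G = "A", T = "C", A = "G", C = "T")[a[1:10]]   # transitions
  b[11:15] <- c(A = "T", C = "G", G = "C", T = "A")[a[11:15]] # transversions
  res <- k2p(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(res$P, 0.10)
  expect_equal(res$Q, 0.05)
  expect_equal(res$d, 0.17018, tolerance = 1e-4)

  ## 1 - 2P - Q = 0 -> saturated
  a2 <- rep("A", 100)
  b2 <- c(rep("G", 30), rep("T", 40), rep("A", 30))
  sat <- k2p(paste(a2, collapse = ""), paste(b2, collapse = ""))
  expect_true(sat$saturated)
  expect_true(is.na(sat$d))

  ## gaps and N excluded from the denominator
  expect_equal(k2p("ACG-N", "ACGTA")$valid_sites, 3)
  expect_error(k2p("NNN", "NNN"), "valid")
})

test_that("K2P agrees with an established K80 implementation", {
  set.seed(24)
  for (i in 1:10) {
    a <- sample(c("a", "c", "g", "t"), 500, TRUE)
    b <- a
    mut <- sample(500, 60)
    b[mut] <- sample(c("a", "c", "g", "t"), 60, TRUE)
    bin <- ape::as.DNAbin(rbind(a, b))
    ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
    mine <- k2p(paste(a, collapse = ""), paste(b, collapse = ""))$d
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("K2P exceeds the raw mismatch fraction (convexity bound)", {
  set.seed(25)
  for (i in 1:20) {
    a <- sample(c("A", "C", "G", "T"), 300, TRUE)
    b <- a
    mut <- sample(300, sample(5:60, 1))
    b[mut] <- sample(c("A", "C", "G", "T"), length(mut), TRUE)
    r <- k2p(paste(a, collapse = ""), paste(b, collapse = ""))
    if (!r$saturated && r$P + r$Q > 0) expect_gt(r$d, r$P + r$Q)
  }
})

test_that("repeat landscape bins conserve each family's genome share", {
  one <- repeat_landscape(data.frame(copy_id = "c1", family = "L1",
                                     d = 0.005, length = 1000), 1e5)
  expect_equal(one$pct_genome, 1.0)
  expect_equal(one$bin_low, 0)
  expect_equal(one$bin_high, 0.01)

  expect_equal(nrow(repeat_landscape(
    data.frame(copy_id = character(), family = character(), d = numeric(),
               length = numeric()), 1e5)), 0)

  set.seed(26)
  rec <- data.frame(copy_id = paste0("c", 1:200),
                    family = sample(c("L1", "RTE"), 200, TRUE),
                    d = c(abs(rnorm(100, 0.02, 0.01)),
                          abs(rnorm(100, 0.15, 0.03))),
                    length = sample(300:8000, 200, TRUE))
  ls <- repeat_landscape(rec, 1e7)
  for (fam in c("L1", "RTE"))
    expect_equal(sum(ls$pct_genome[ls$family == fam]),
                 sum(rec$length[rec$family == fam]) / 1e7 * 100)

  ## a young family holds more low-divergence mass than an old one
  young <- data.frame(copy_id = paste0("y", 1:100), family = "L1",
                      d = pmin(abs(rnorm(100, 0.01, 0.005)), 0.5),
                      length = 1000)
  old <- data.frame(copy_id = paste0("o", 1:100), family = "RTE",
                    d = pmin(abs(rnorm(100, 0.15, 0.03)), 0.5), length = 1000)
  ls2 <- repeat_landscape(rbind(young, old), 1e6)
  low <- ls2$bin_low < 0.03
  expect_gt(sum(ls2$pct_genome[low & ls2$family == "L1"]),
            sum(ls2$pct_genome[low & ls2$family == "RTE"]))
})

test_that("ORF scan finds long intact frames and rejects disrupted ones", {
  set.seed(27)
  sense <- c("GCT", "GGA", "TCA"[0], "AAA", "CCC", "GGG", "TTC", "ATC",
             "GAA", "CTG")
  body <- paste(sample(sense, 1043, TRUE), collapse = "")
  orf <- paste0("ATG", body, "TAA")
  leader <- paste(sample(c("C", "G", "T"), 30, TRUE), collapse = "")  # no ATG
  seq <- paste0(leader, orf, random_dna(30))
  hits <- scan_intact_orfs(orf, min_aa = 1000)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$aa_length, 1044)
  expect_equal(hits$start, 0)
  expect_equal(hits$end, nchar(orf))

  hits2 <- scan_intact_orfs(seq, min_aa = 1000)
  expect_true(any(hits2$aa_length == 1044))

  broken <- paste0("ATG", substr(body, 1, 1500), "TAG",
                   substr(body, 1504, nchar(body)), "TAA")
  expect_equal(nrow(scan_intact_orfs(broken, min_aa = 1000)), 0)

  expect_equal(nrow(scan_intact_orfs(strrep("N", 5000))), 0)
})
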