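# Reciprocal-best-hit orthology and distance trees.

blosum50 <- regufoot:::substitution_matrix("BLOSUM50")
blosum62 <- regufoot:::substitution_matrix("BLOSUM62")

test_that("local alignment scores match an independent affine-gap DP", {
  # the classic textbook pair, frozen from the oracle under the stated
  # affine parameters (gap of length L costs open + L * extend)
  expect_equal(sw_oracle("HEAGAWGHEE", "PAWHEAE", blosum50, 10, 1), 25)
  al <- local_align("HEAGAWGHEE", "PAWHEAE", "BLOSUM50",
                    gap_open = 10, gap_extend = 1)
  expect_equal(al$score, 25)
  set.seed(13)
  aas <- rownames(blosum62)[1:20]
  for (rep in 1:8) {
    a <- paste(sample(aas, sample(8:20, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(8:20, 1), TRUE), collapse = "")
    expect_equal(local_align(a, b)$score,
                 sw_oracle(a, b, blosum62, 11, 1),
                 info = paste(a, b))
  }
})

test_that("identity covers the limit cases and is symmetric in score", {
  a <- paste(rep("ACDEFGHIKL", 5), collapse = "")
  self <- local_align(a, a)
  expect_equal(self$identity, 1.0)
  expect_equal(self$aligned_length, 50L)
  # disjoint residue usage: best local block shares nothing
  dis <- local_align("AAAAAAAA", "WWWWWWWW")
  expect_equal(dis$identity, 0)
  expect_equal(local_align("MKVLA", "MKQLAW")$score,
               local_align("MKQLAW", "MKVLA")$score)
  expect_error(local_align("", "MK"), "non-empty")
})

make_prot_genome <- function(id, prots) {
  # one synthetic CDS per protein via reverse translation table 11
  rev_codon <- c(M = "ATG", K = "AAA", V = "GTT", L = "CTT", A = "GCT",
                 Q = "CAA", W = "TGG", E = "GAA", R = "CGT", G = "GGT",
                 H = "CAT", S = "TCT", T = "ACT", N = "AAT", D = "GAT",
                 F = "TTT", P = "CCT", I = "ATT", Y = "TAT", C = "TGT")
  dnas <- vapply(prots, function(p) {
    paste(c(rev_codon[strsplit(p, "")[[1]]], "TAA"), collapse = "")
  }, character(1))
  starts <- cumsum(c(50, head(nchar(dnas) + 200, -1)))
  contig <- random_seq(max(starts + nchar(dnas)) + 100)
  for (i in seq_along(dnas)) {
    substr(contig, starts[i] + 1, starts[i] + nchar(dnas[i])) <- dnas[i]
  }
  g <- toy_genome(id, contig, lapply(seq_along(prots), function(i) {
    list(names(prots)[i], starts[i], starts[i] + nchar(dnas[i]), "+")
  }))
  regufoot:::fill_translations(g)
}

test_that("reciprocal best hits require mutual top scores", {
  set.seed(5)
  pa <- "MKVLAQWERMKVLAQWERMKVLAQWER"
  pb <- "MKVLAQWDRMKVLAQWDRMKVLAQWER"   # close homolog of pa
  pc <- "GGGHHHSSSTTTNNNDDDFFFPPPIII"   # unrelated
  ga <- make_prot_genome("ga", c(a1 = pa, a2 = pc))
  gb <- make_prot_genome("gb", c(b1 = pb,
                                 b2 = "GGGHHHSSSTTTNNNDDDFFFPPPIIY"))
  bbh <- find_bbh(ga, gb)
  expect_equal(bbh$tag_a, c("a1", "a2"))
  expect_equal(bbh$tag_b, c("b1", "b2"))
  # exhaustive check of the mutual-best definition on the same toy
  for (k in seq_len(nrow(bbh))) {
    x <- bbh$tag_a[k]; y <- bbh$tag_b[k]
    prots_a <- regufoot:::genome_proteins(ga)
    prots_b <- regufoot:::genome_proteins(gb)
    sx <- vapply(prots_b, function(p) local_align(prots_a[[x]], p)$score,
                 numeric(1))
    sy <- vapply(prots_a, function(p) local_align(p, prots_b[[y]])$score,
                 numeric(1))
    expect_equal(names(which.max(sx)), y)
    expect_equal(names(which.max(sy)), x)
  }
})

test_that("one-sided best hits are rejected", {
  # y's best hit is z, not x, so (x, y) must not be reported
  x <- "MKVLAQWERHSTMKVLAQWERHST"
  y <- "MKVLAQWERHSTMKVLAQWERHSTAAAA"
  z <- "MKVLAQWERHSTMKVLAQWERHSTAAAA"  # identical to y, beats x for y
  ga <- make_prot_genome("ga", c(x = x))
  gb <- make_prot_genome("gb", c(y = y))
  gb2 <- make_prot_genome("ga", c(x = x, z = z))
  bbh <- find_bbh(gb2, gb)
  # z (identical) is y's best; x loses: only (z, y) survives
  expect_equal(nrow(bbh), 1L)
  expect_equal(bbh$tag_a, "z")
})

test_that("the identity threshold is inclusive at its boundary", {
  pa <- "MKVLAQWERHSTNDFPIYCGMKVLAQWERHSTNDFPIYCG"
  pb <- "MKVLAQWERHSTNDFPIYCGAAAAAAAAAAAAAAAAAAAA"
  ga <- make_prot_genome("ga", c(a = pa))
  gb <- make_prot_genome("gb", c(b = pb))
  id <- local_align(pa, pb)$identity
  expect_gt(id, 0.3)
  at <- find_bbh(ga, gb, min_identity = id)        # inclusive: kept
  above <- find_bbh(ga, gb, min_identity = id + 1e-6)
  expect_equal(nrow(at), 1L)
  expect_equal(nrow(above), 0L)
})

test_that("BBH pairs are symmetric under genome swap", {
  set.seed(6)
  ga <- make_prot_genome("ga", c(a1 = "MKVLAQWERHST", a2 = "GGHHSSTTNNDD"))
  gb <- make_prot_genome("gb", c(b1 = "MKVLAQWDRHST", b2 = "GGHHSSTTNNDY"))
  ab <- find_bbh(ga, gb)
  ba <- find_bbh(gb, ga)
  expect_setequal(paste(ab$tag_a, ab$tag_b), paste(ba$tag_b, ba$tag_a))
})

test_that("ortholog groups collect partners and resolve paralog conflicts", {
  seed_p <- "MKVLAQWERHSTNDFPMKVLAQWERHSTNDFP"
  near <- "MKVLAQWERHSTNDFPMKVLAQWERHSTNDFA"
  far <- "MKVLAQWERHSTNDAAMKVLAQWERHSTAAAA"
  ga <- make_prot_genome("ga", c(s = seed_p))
  gb <- make_prot_genome("gb", c(p1 = near, p2 = far))
  gc_ <- make_prot_genome("gc", c(q = near))
  groups <- build_ortholog_groups(list(ga, gb, gc_),
                                  list(list(genome_id = "ga",
                                            locus_tag = "s")))
  m <- groups[[1]]$members
  expect_equal(nrow(m), 3L)               # one member per genome
  expect_equal(m$locus_tag[m$genome_id == "gb"], "p1")  # higher score to seed
  # a seed whose best hit is not reciprocated stays a singleton group:
  # gd's v matches ga's s far better than the seed u does
  gd <- make_prot_genome("gd", c(u = "WWWWCCCCYYYYWWWWCCCCYYYY",
                                 v = seed_p))
  ga1 <- make_prot_genome("ga", c(s = seed_p))
  g2 <- build_ortholog_groups(list(ga1, gd),
                              list(list(genome_id = "gd",
                                        locus_tag = "u")))
  expect_equal(nrow(g2[[1]]$members), 1L)
})

test_that("group membership is invariant to genome input order", {
  seed_p <- "MKVLAQWERHSTNDFPMKVLAQWERHSTNDFP"
  ga <- make_prot_genome("ga", c(s = seed_p))
  gb <- make_prot_genome("gb", c(p1 = sub("P$", "A", seed_p)))
  gc_ <- make_prot_genome("gc", c(q = sub("^M", "V", seed_p)))
  seed <- list(list(genome_id = "ga", locus_tag = "s"))
  m1 <- build_ortholog_groups(list(ga, gb, gc_), seed)[[1]]$members
  m2 <- build_ortholog_groups(list(gc_, ga, gb), seed)[[1]]$members
  expect_identical(m1[, c("genome_id", "locus_tag")],
                   m2[, c("genome_id", "locus_tag")])
})

test_that("neighbor-joining recovers additive distances", {
  # identical sequences: star tree with zero branch lengths
  star <- build_distance_tree(c(a = "MKVLA", b = "MKVLA", c = "MKVLA"))
  expect_s3_class(star, "phylo")
  expect_true(all(star$edge.length < 1e-12))
  # two sequences: one edge whose length is the corrected distance
  two <- build_distance_tree(c(a = "MKVLAMKVLA", b = "MKVLAMKVLT"))
  d <- -log(1 - 0.1)
  expect_equal(sum(two$edge.length), d, tolerance = 1e-9)
  # four-taxon case: the recovered split must match the four-point
  # condition computed independently from the corrected distances
  seqs <- c(a = "AAAAAAAAAAKKKKKKKKKK",
            b = "AAAAAAAAAAKKKKKKKKKR",
            c = "VVVVVVVVVVKKKKKKKKKK",
            d = "VVVVVVVVVVKKKKKKKKKR")
  tree <- build_distance_tree(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  D <- outer(seq_along(seqs), seq_along(seqs), Vectorize(function(i, j) {
    -log(1 - mean(chars[[i]] != chars[[j]]))
  }))
  dimnames(D) <- list(names(seqs), names(seqs))
  sums <- c(ab_cd = D["a", "b"] + D["c", "d"],
            ac_bd = D["a", "c"] + D["b", "d"],
            ad_bc = D["a", "d"] + D["b", "c"])
  expect_equal(names(which.min(sums)), "ab_cd")  # the four-point split
  expect_true(ape::is.monophyletic(ape::unroot(tree), c("a", "b")))
  expect_true(all(tree$edge.length >= 0))
  expect_error(build_distance_tree(c(a = "MK")), "at least 2")
})
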