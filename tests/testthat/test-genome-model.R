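# Genome data model: readers, validation, operon prediction, upstream
# extraction.

test_that("tabular dialect round-trips all fields bit-exactly", {
  contig <- random_seq(600)
  g <- toy_genome("gA", contig, list(
    list("gA_1", 10, 109, "+"), list("gA_2", 200, 350, "-"),
    list("gA_3", 400, 580, "+")))
  g$features$product <- c("kinase", "porin", "regulator")
  g$features$annotations <- c("category=x", "", "category=y;cond=glc")
  g <- regufoot:::fill_translations(g)
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  write_genome_fasta(g, fa)
  write_feature_table(g, tsv)
  g2 <- read_genome(fa, annotations = tsv, genome_id = "gA")
  expect_identical(g2$contigs, g$contigs)
  expect_identical(g2$features, g$features)
})

test_that("GenBank CDS features parse with strands and coordinates", {
  gb <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       ctg1                60 bp    DNA     linear",
    "FEATURES             Location/Qualifiers",
    "     CDS             3..11",
    '                     /locus_tag="g1"',
    '                     /product="alpha"',
    "     CDS             complement(20..31)",
    '                     /locus_tag="g2"',
    "     CDS             40..48",
    '                     /locus_tag="g3"',
    '                     /translation="MKL"',
    "ORIGIN",
    "        1 ccatgaaata accgccgcgt tacatgttta aaatgaaata acgcgcgcgc gcgcgcgcgc",
    "//"), gb)
  g <- read_genome(gb, genome_id = "toy")
  expect_equal(nrow(g$features), 3L)
  expect_equal(g$features$strand, c("+", "-", "+"))
  # GenBank 1-based inclusive converted to 0-based half-open
  expect_equal(g$features$start, c(2L, 19L, 39L))
  expect_equal(g$features$end, c(11L, 31L, 48L))
  expect_equal(g$features$product[1], "alpha")
  expect_equal(g$features$translation[3], "MKL")  # declared kept verbatim
})

test_that("translations derive from CDS coordinates, stop trimmed", {
  g <- toy_genome("gT", "ATGAAATAA", list(list("t1", 0, 9, "+")))
  g <- regufoot:::fill_translations(g)
  # hand translation: ATG=M, AAA=K, TAA=stop (trimmed)
  expect_equal(g$features$translation[1], "MK")
  # minus-strand copy of the same CDS
  g2 <- toy_genome("gT2", revcomp("ATGAAATAA"),
                   list(list("t1", 0, 9, "-")))
  g2 <- regufoot:::fill_translations(g2)
  expect_equal(g2$features$translation[1], "MK")
})

test_that("invariant violations are rejected with the offending feature", {
  contig <- random_seq(100)
  expect_error(toy_genome("g", contig, list(list("bad", 50, 50, "+"))),
               "bad")
  expect_error(toy_genome("g", contig, list(list("far", 10, 200, "+"))),
               "far")
  expect_error(toy_genome("g", contig, list(list("s", 10, 20, "*"))),
               "strand")
  expect_error(genome_record("g", c(c1 = "ACGTX"),
                             data.frame(locus_tag = character(0),
                                        contig_id = character(0),
                                        start = integer(0),
                                        end = integer(0),
                                        strand = character(0))),
               "A,C,G,T,N")
})

test_that("operon grouping matches a brute-force oracle", {
  oracle_group <- function(genes, max_gap) {
    # genes: data.frame sorted by start on one contig
    groups <- list(1L)
    for (i in seq_len(nrow(genes))[-1]) {
      gap <- genes$start[i] - genes$end[i - 1]
      if (genes$strand[i] == genes$strand[i - 1] && gap <= max_gap) {
        groups[[length(groups)]] <- c(groups[[length(groups)]], i)
      } else {
        groups[[length(groups) + 1L]] <- i
      }
    }
    groups
  }
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    starts <- cumsum(sample(c(20:80, 150:300), n))
    lens <- sample(30:90, n, replace = TRUE)
    genes <- data.frame(tag = sprintf("g%02d", seq_len(n)),
                        start = starts, end = starts + lens,
                        strand = sample(c("+", "-"), n, TRUE))
    contig <- random_seq(max(genes$end) + 10)
    g <- toy_genome("g", contig, lapply(seq_len(n), function(i) {
      list(genes$tag[i], genes$start[i], genes$end[i], genes$strand[i])
    }))
    ops <- predict_operons(g, max_gap = 100)
    expected <- oracle_group(genes, 100)
    expect_equal(length(ops), length(expected))
    got_sets <- lapply(ops, function(o) sort(o$gene_ids))
    want_sets <- lapply(expected, function(idx) sort(genes$tag[idx]))
    expect_setequal(got_sets, want_sets)
    # partition: every gene in exactly one operon
    all_genes <- unlist(lapply(ops, `[[`, "gene_ids"))
    expect_setequal(all_genes, genes$tag)
    expect_equal(anyDuplicated(all_genes), 0L)
  }
})

test_that("strand flips split operons and leaders follow transcription", {
  contig <- random_seq(700)
  g <- toy_genome("g", contig, list(
    list("a", 10, 100, "+"), list("b", 150, 240, "+"),
    list("c", 280, 380, "-"), list("d", 420, 520, "-")))
  ops <- predict_operons(g, max_gap = 100)
  expect_equal(length(ops), 2L)
  expect_equal(ops[[1]]$gene_ids, c("a", "b"))
  expect_equal(ops[[1]]$leader_gene, "a")
  # minus-strand operon reads right to left: leader is 3'-coordinate-most
  expect_equal(ops[[2]]$gene_ids, c("d", "c"))
  expect_equal(ops[[2]]$leader_gene, "d")
  single <- predict_operons(toy_genome("s", random_seq(100),
                                       list(list("only", 10, 70, "+"))))
  expect_equal(length(single), 1L)
  expect_equal(single[[1]]$gene_ids, "only")
})

test_that("upstream windows follow the -400..+50 rule with clamping", {
  contig <- random_seq(1500)
  g <- toy_genome("g", contig, list(list("mid", 1000, 1300, "+"),
                                    list("edge", 100, 300, "+")))
  r <- extract_upstream(g, "mid")
  expect_equal(c(r$start, r$end), c(600, 1050))
  expect_equal(nchar(r$sequence), 450L)
  expect_equal(r$sequence, substr(contig, 601, 1050))
  clamped <- extract_upstream(g, "edge")
  expect_equal(c(clamped$start, clamped$end), c(0, 150))
  expect_equal(nchar(clamped$sequence), 150L)
  expect_error(extract_upstream(g, "nope"), "not found")
})

test_that("minus-strand upstream extraction matches coordinate arithmetic", {
  contig <- random_seq(1300)
  g <- toy_genome("g", contig, list(list("neg", 500, 800, "-")))
  r <- extract_upstream(g, "neg")
  # window [end-50, end+400) = [750, 1200), reverse complemented
  expect_equal(c(r$start, r$end), c(750, 1200))
  expect_equal(r$sequence, revcomp(substr(contig, 751, 1200)))
})

test_that("strand-mirrored genes yield identical upstream sequences", {
  set.seed(7)
  for (rep in 1:5) {
    contig <- random_seq(1200)
    g_plus <- toy_genome("p", contig, list(list("x", 700, 1000, "+")))
    g_minus <- toy_genome("m", revcomp(contig),
                          list(list("x", 200, 500, "-")))
    expect_identical(extract_upstream(g_plus, "x")$sequence,
                     extract_upstream(g_minus, "x")$sequence)
  }
})

test_that("neighbor truncation shortens the literal window only when asked", {
  contig <- random_seq(1200)
  g <- toy_genome("g", contig, list(list("up", 100, 700, "+"),
                                    list("dn", 900, 1100, "+")))
  full <- extract_upstream(g, "dn")
  expect_equal(c(full$start, full$end), c(500, 950))
  cut <- extract_upstream(g, "dn", truncate_at_neighbor = TRUE)
  expect_equal(c(cut$start, cut$end), c(700, 950))
})

test_that("regions export as BED6 with locus tags and zero scores", {
  contig <- random_seq(1000)
  g <- toy_genome("g", contig, list(list("a", 500, 800, "+")))
  bed <- tempfile(fileext = ".bed")
  write_bed6(list(extract_upstream(g, "a")), bed)
  got <- read.delim(bed, header = FALSE)
  expect_equal(unlist(got, use.names = FALSE),
               c("c1", 100L, 550L, "a", 0L, "+"),
               ignore_attr = TRUE)
})
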