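# Phylogenetic footprinting: alignment, conservation islands, and
# candidate-site extraction.

test_that("identical regions align without gaps at full identity", {
  s <- random_seq(80)
  aln <- align_upstreams(c(r1 = s, r2 = s))
  expect_equal(aln$ncol, 80L)
  expect_false(any(grepl("-", unlist(aln$rows), fixed = TRUE)))
  isl <- find_islands(aln, window_len = 10, min_identity = 0.99)
  expect_equal(length(isl), 1L)
  expect_equal(c(isl[[1]]$start, isl[[1]]$end), c(1L, 80L))
  expect_equal(isl[[1]]$mean_identity, 1)
})

test_that("a single deletion is restored by one gap column", {
  aln <- align_upstreams(c(a = "ACGTACGT", b = "ACGACGT"))
  expect_equal(aln$ncol, 8L)
  expect_equal(sum(strsplit(aln$rows[["b"]], "")[[1]] == "-"), 1L)
  expect_equal(degap_row(aln, "a"), "ACGTACGT")
  expect_equal(degap_row(aln, "b"), "ACGACGT")
})

test_that("an insertion is confined to gap columns in the other rows", {
  set.seed(21)
  base <- random_seq(60)
  ins <- paste0(substr(base, 1, 30), "TTTTT", substr(base, 31, 60))
  aln <- align_upstreams(c(a = base, b = base, c = ins))
  expect_equal(aln$ncol, 65L)
  gaps_a <- which(strsplit(aln$rows[["a"]], "")[[1]] == "-")
  gaps_b <- which(strsplit(aln$rows[["b"]], "")[[1]] == "-")
  expect_equal(length(gaps_a), 5L)
  expect_equal(gaps_a, gaps_b)
  for (id in c("a", "b", "c")) {
    expect_equal(degap_row(aln, id),
                 c(a = base, b = base, c = ins)[[id]])
  }
})

test_that("degapping always reproduces the input regions", {
  set.seed(22)
  for (rep in 1:5) {
    seqs <- setNames(replicate(4, mutate_seq(random_seq(120), 0.2)),
                     paste0("r", 1:4))
    aln <- align_upstreams(seqs)
    for (id in names(seqs)) {
      expect_identical(degap_row(aln, id), unname(seqs[[id]]))
    }
  }
})

test_that("islands match an exhaustive sliding-window oracle", {
  island_oracle <- function(ident, win, thr) {
    covered <- rep(FALSE, length(ident))
    for (w in seq_len(length(ident) - win + 1)) {
      if (mean(ident[w:(w + win - 1)]) >= thr) {
        covered[w:(w + win - 1)] <- TRUE
      }
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    spans <- cbind(start = ends - r$lengths + 1,
                   end = ends)[r$values, , drop = FALSE]
    # boundary columns of a reported island are themselves conserved
    out <- NULL
    for (k in seq_len(nrow(spans))) {
      s <- spans[k, 1]; e <- spans[k, 2]
      while (s < e && ident[s] < thr) s <- s + 1
      while (e > s && ident[e] < thr) e <- e - 1
      if (e - s + 1 >= 2) out <- rbind(out, c(s, e))
    }
    if (is.null(out)) out <- matrix(0L, 0, 2)
    colnames(out) <- c("start", "end")
    out
  }
  set.seed(23)
  block <- random_seq(16)
  rows <- replicate(5, {
    left <- random_seq(40)
    right <- random_seq(44)
    paste0(left, block, right)
  })
  aln <- align_upstreams(setNames(rows, paste0("r", 1:5)))
  ident <- regufoot:::column_identity(aln)
  want <- island_oracle(ident, 10, 0.8)
  got <- find_islands(aln, 10, 0.8)
  expect_equal(length(got), nrow(want))
  for (k in seq_along(got)) {
    expect_equal(c(got[[k]]$start, got[[k]]$end),
                 unname(want[k, ]))
  }
  # the planted invariant block must lie inside some island
  expect_true(any(vapply(got, function(i) {
    all(grepl(block, i$rows$sequence, fixed = TRUE))
  }, logical(1))))
  # below-threshold alignments produce no islands
  noisy <- setNames(replicate(4, random_seq(60)), paste0("n", 1:4))
  expect_equal(length(find_islands(align_upstreams(noisy), 10, 0.9)), 0L)
})

test_that("island detection is invariant under row order", {
  set.seed(24)
  block <- random_seq(14)
  rows <- setNames(replicate(4, paste0(random_seq(30), block,
                                       random_seq(30))),
                   paste0("r", 1:4))
  spans <- function(seqs) {
    vapply(find_islands(align_upstreams(seqs), 10, 0.8),
           function(i) paste(i$start, i$end), character(1))
  }
  expect_setequal(spans(rows), spans(rev(rows)))
})

test_that("islands track planted boxes at realistic divergence", {
  # orthologous upstreams: random ancestor diverged per row, with only
  # the planted box inserted identically afterwards
  set.seed(25)
  hits <- 0L
  runs <- 20L
  for (r in seq_len(runs)) {
    anc <- random_seq(150)
    box <- random_seq(16)
    # 11 orthologous rows, matching a typical study-sized genome set
    rows <- replicate(11, {
      s <- mutate_seq(anc, 0.3)
      paste0(substr(s, 1, 60), box, substr(s, 77, 150))
    })
    # near-1 threshold because the planted box is exactly conserved;
    # a passing window then carries >= 9 conserved columns and the
    # trimmed island can overrun a box end by at most ~2 columns
    isl <- find_islands(align_upstreams(setNames(rows, paste0("r", 1:11))),
                        10, 0.95)
    # the box occupies region offsets [60, 76) in every row; judge the
    # island in per-row (ungapped) coordinates, robust to alignment gaps
    ok <- length(isl) >= 1L && any(vapply(isl, function(i) {
      all(abs(i$rows$from - 60) <= 2 & abs(i$rows$to - 76) <= 2)
    }, logical(1)))
    hits <- hits + ok
  }
  expect_gte(hits, 18L)   # >= 90% of runs
})

test_that("island pairs at the expected center distance form two-box sites", {
  set.seed(26)
  box <- random_seq(16)
  geom <- motif_geometry("direct_repeat", box_len = 16, spacer = 5)
  # two box islands whose per-row centers sit 21 bp apart
  rows <- setNames(replicate(4, {
    paste0(random_seq(30), box, random_seq(5), box, random_seq(30))
  }), paste0("r", 1:4))
  mk_island <- function(from, to) {
    structure(list(start = from + 1L, end = to,
                   mean_identity = 1,
                   rows = data.frame(region_id = names(rows),
                                     sequence = substr(rows, from + 1, to),
                                     from = from, to = to,
                                     stringsAsFactors = FALSE)),
              class = "conservation_island")
  }
  isl <- list(mk_island(30L, 46L), mk_island(51L, 67L))
  sites <- candidate_sites_from_islands(isl, geometry = geom,
                                        region_seqs = rows)
  expect_equal(length(sites), 4L)
  expect_true(all(nchar(sites) == 32L))
  expect_true(all(substr(sites, 1, 16) == box))
  expect_true(all(substr(sites, 17, 32) == box))
  # islands further apart than the tolerated center distance never pair
  far <- list(mk_island(10L, 26L), mk_island(51L, 67L))
  expect_equal(length(candidate_sites_from_islands(
    far, geometry = geom, region_seqs = rows)), 0L)
})

test_that("without a geometry island sequences are emitted verbatim", {
  set.seed(27)
  block <- random_seq(18)
  rows <- setNames(replicate(4, paste0(random_seq(25), block,
                                       random_seq(25))),
                   paste0("r", 1:4))
  isl <- find_islands(align_upstreams(rows), 10, 0.8)
  sites <- candidate_sites_from_islands(isl)
  expect_gt(length(sites), 0L)
  expect_true(all(vapply(sites, function(s) grepl(s, paste(rows, collapse = " "),
                                                  fixed = TRUE),
                         logical(1))))
  expect_error(candidate_sites_from_islands(list()), "non-empty")
})

test_that("SusR-type long-range island pairs are matched at 67 bp", {
  set.seed(28)
  box <- random_seq(12)
  geom <- motif_geometry("direct_repeat", box_len = 12, spacer = 55)
  expect_equal(geom$center_distance, 67L)
  rows <- setNames(replicate(4, {
    paste0(random_seq(20), box, random_seq(55), box, random_seq(20))
  }), paste0("r", 1:4))
  isl <- find_islands(align_upstreams(rows), 10, 0.8)
  sites <- candidate_sites_from_islands(isl, geometry = geom,
                                        region_seqs = rows)
  expect_gt(length(sites), 0L)
  expect_true(all(nchar(sites) == 24L))
})

test_that("aligned FASTA and island TSV writers round-trip content", {
  set.seed(29)
  rows <- setNames(replicate(3, random_seq(40)), paste0("r", 1:3))
  aln <- align_upstreams(rows)
  fa <- tempfile(fileext = ".afa")
  write_alignment_fasta(aln, fa)
  lines <- readLines(fa)
  expect_equal(lines[c(1, 3, 5)], paste0(">", names(rows)))
  expect_equal(gsub("-", "", lines[2]), unname(rows[1]))
})
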