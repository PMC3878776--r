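# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written as plainly as possible -
# brute force, enumeration, direct coordinate arithmetic - so the
# oracles share no code path with the implementations they check.

ORACLE_BASES <- c("A", "C", "G", "T")

random_seq <- function(n, bases = ORACLE_BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate) {
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (runif(1) < rate) {
      chars[i] <- sample(setdiff(ORACLE_BASES, chars[i]), 1)
    }
  }
  paste(chars, collapse = "")
}

# Smith-Waterman with affine gaps (a gap of length L costs
# open + L * extend), plain three-matrix dynamic program.
sw_oracle <- function(a, b, subst, open, extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  M <- matrix(0, n + 1, m + 1)       # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1)    # gap in b (consuming a)
  Y <- matrix(-Inf, n + 1, m + 1)    # gap in a (consuming b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- subst[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i - 1, j - 1] + s,
                     Y[i - 1, j - 1] + s)
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Brute-force word score: per-position PWM lookup, one base at a time.
score_word_oracle <- function(pwm, word) {
  chars <- strsplit(word, "")[[1]]
  total <- 0
  for (j in seq_along(chars)) {
    k <- match(chars[j], ORACLE_BASES)
    if (is.na(k)) return(-Inf)
    total <- total + pwm[k, j]
  }
  total
}

# Brute-force region scanner mirroring the documented scan contract:
# score every start on both strands, keep the better strand per
# position (forward wins ties), report scores >= threshold, and for
# direct repeats greedily collapse hits closer than one center
# distance (best score first, then smaller position).
scan_oracle <- function(model, region_seq, threshold) {
  g <- model$geometry
  tl <- g$total_len
  n <- nchar(region_seq)
  if (n < tl) return(data.frame(position = integer(0), score = numeric(0)))
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  word_of <- function(seq, p) {
    site <- substr(seq, p, p + tl - 1)
    if (g$kind == "direct_repeat") {
      paste0(substr(site, 1, g$box_len),
             substr(site, g$box_len + g$spacer + 1, tl))
    } else {
      site
    }
  }
  rev_seq <- rc(region_seq)
  np <- n - tl + 1
  pos <- integer(0)
  sco <- numeric(0)
  for (p in seq_len(np)) {
    sf <- score_word_oracle(model$pwm, word_of(region_seq, p))
    # reverse-read start that occupies the same forward window
    sr <- score_word_oracle(model$pwm, word_of(rev_seq, np - p + 1))
    s <- if (sr > sf) sr else sf
    if (s >= threshold) {
      pos <- c(pos, p)
      sco <- c(sco, s)
    }
  }
  if (g$kind == "direct_repeat" && length(pos) > 1) {
    ord <- order(-round(sco, 9), pos)
    keep <- integer(0)
    for (k in ord) {
      if (all(abs(pos[k] - pos[keep]) >= g$center_distance)) {
        keep <- c(keep, k)
      }
    }
    keep <- sort(keep)
    pos <- pos[keep]
    sco <- sco[keep]
  }
  data.frame(position = pos, score = sco)
}

# Build a one-contig genome record from explicit gene tuples:
# list(tag, start, end, strand).
toy_genome <- function(genome_id, contig, genes) {
  ft <- do.call(rbind, lapply(genes, function(g) {
    data.frame(locus_tag = g[[1]], contig_id = "c1",
               start = as.integer(g[[2]]), end = as.integer(g[[3]]),
               strand = g[[4]], product = "", translation = NA,
               stringsAsFactors = FALSE)
  }))
  genome_record(genome_id, c(c1 = contig), ft)
}

# Sequences with one planted direct repeat each: per-sequence noisy
# boxes around a random spacer, in random background.
planted_repeat_seqs <- function(n_seqs, box, spacer_len, bg_len,
                                noise = 0) {
  replicate(n_seqs, {
    bg <- random_seq(bg_len)
    site <- paste0(mutate_seq(box, noise), random_seq(spacer_len),
                   mutate_seq(box, noise))
    p <- sample(seq_len(bg_len - nchar(site) + 1), 1)
    paste0(substr(bg, 1, p - 1), site,
           substr(bg, p + nchar(site), bg_len))
  })
}
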