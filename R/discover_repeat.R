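# Direct-repeat (spaced dyad) motif discovery. The motif is two
# conserved boxes in the same orientation around a non-conserved spacer
# of fixed length. Discovery is a grid search over (box_len, spacer):
# for each geometry, greedy seeding from observed box-pair words
# followed by iterative refinement (pick the best-scoring occurrence in
# every sequence, rebuild the PWM) until the occupancy reaches a fixed
# point. Model selection across geometries maximises
# (total IC - ic_penalty * n_columns) * n_sequences_covered; the
# per-column penalty is an MDL-style correction that stops wider boxes
# from winning merely by absorbing weakly conserved spacer or flank
# columns.

#' Discover a spaced direct-repeat motif
#'
#' @param sequences DNA strings (>= 3) containing the repeat, e.g.
#'   footprint-selected upstream regions.
#' @param box_len_range candidate box lengths (default 10:18).
#' @param spacer_range candidate spacer lengths (default 3:12). With
#'   `susr_mode = TRUE` the grid instead covers center-to-center
#'   distances of 60-80 bp, the long-range geometry of SusR-type
#'   dimers.
#' @param n_seeds greedy seeds per geometry (default 8).
#' @param seed RNG seed; the search is deterministic given it.
#' @param background base frequencies; default estimated from the input
#'   sequences.
#' @param pseudocount PWM pseudocount (default 0.5).
#' @param ic_penalty per-column information penalty in bits used for
#'   geometry selection (default 0.5).
#' @param max_iter refinement iteration cap per seed (default 30).
#' @param n_refine number of top-ranked geometries (by dyad seed
#'   quality) carried into full refinement (default 12).
#' @param susr_mode search center distances 60-80 bp instead of
#'   `spacer_range` (default `FALSE`).
#' @return the best `motif_model`; its `geometry` reports the recovered
#'   box length, spacer and center distance, and attribute `occupancy`
#'   holds the chosen occurrence per sequence.
#' @export
discover_direct_repeat <- function(sequences,
                                   box_len_range = 10:18,
                                   spacer_range = 3:12,
                                   n_seeds = 8L, seed = 1L,
                                   background = NULL, pseudocount = 0.5,
                                   ic_penalty = 0.5, max_iter = 30L,
                                   n_refine = 12L, susr_mode = FALSE) {
  if (length(sequences) < 3L) stopf("need at least 3 sequences")
  if (length(box_len_range) == 0L || length(spacer_range) == 0L) {
    stopf("empty geometry range")
  }
  background <- check_background(background %||% base_frequencies(sequences))
  codes_fwd <- lapply(sequences, dna_codes)
  codes_rev <- lapply(revcomp(sequences), dna_codes)
  if (all(is.na(unlist(codes_fwd)))) stopf("motif discovery failed: all input bases are ambiguous")

  geometries <- list()
  for (b in sort(box_len_range)) {
    spacers <- if (susr_mode) (60:80) - b else sort(spacer_range)
    for (s in spacers[spacers >= 0L]) {
      geometries[[length(geometries) + 1L]] <- motif_geometry(
        "direct_repeat", box_len = b, spacer = s)
    }
  }

  withr::with_seed(seed, {
    # rank geometries by their strongest dyad seed (the box self-match
    # fraction); only the most promising ones are refined - geometries
    # whose spacing misses the true repeat have near-background seed
    # quality and cannot win the IC objective anyway
    quality <- vapply(geometries, function(g) {
      dyad_quality(g, codes_fwd, which(nchar(sequences) >= g$total_len))
    }, numeric(1))
    ord <- order(-quality,
                 vapply(geometries, `[[`, integer(1), "box_len"),
                 vapply(geometries, `[[`, integer(1), "spacer"))
    refine <- ord[seq_len(min(n_refine, length(ord)))]
    best <- NULL
    for (g in geometries[refine]) {
      fit <- fit_geometry(g, sequences, codes_fwd, codes_rev, background,
                          pseudocount, n_seeds, max_iter, ic_penalty)
      if (is.null(fit)) next
      if (is.null(best) || fit$objective > best$objective + 1e-9) best <- fit
    }
    if (is.null(best)) stopf("motif discovery failed: no geometry fits the sequences")
    model <- best$model
    attr(model, "occupancy") <- best$occupancy
    attr(model, "objective") <- best$objective
    model
  })
}

#' @noRd
fit_geometry <- function(g, sequences, codes_fwd, codes_rev, background,
                         pseudocount, n_seeds, max_iter, ic_penalty) {
  tl <- g$total_len
  usable <- which(nchar(sequences) >= tl)
  if (length(usable) < 3L) return(NULL)
  seeds <- dyad_seeds(g, sequences, codes_fwd, usable, n_seeds)
  if (length(seeds) == 0L) return(NULL)

  b <- g$box_len
  offsets <- c(0:(b - 1L), (b + g$spacer):(tl - 1L))
  L <- length(offsets)
  # all strands of all sequences concatenated (N-padded between
  # segments so no scoring window straddles a boundary); one flat PWM
  # gather then scores every placement in every sequence at once
  segs <- list()
  bounds <- matrix(0L, length(usable), 4L)  # fwd start/np, rev start/np
  at <- 0L
  for (k in seq_along(usable)) {
    i <- usable[k]
    for (strand in 1:2) {
      cc <- if (strand == 1L) codes_fwd[[i]] else codes_rev[[i]]
      cc[is.na(cc)] <- 5L
      bounds[k, 2L * strand - 1L] <- at + 1L
      bounds[k, 2L * strand] <- length(cc) - tl + 1L
      segs[[length(segs) + 1L]] <- c(cc, rep(5L, tl - 1L))
      at <- at + length(cc) + tl - 1L
    }
  }
  allcodes <- unlist(segs, use.names = FALSE)
  np_all <- length(allcodes) - tl + 1L
  idx <- rep(offsets, each = np_all) + seq_len(np_all)
  shift <- 5L * rep(seq_len(L) - 1L, each = np_all)
  flat <- allcodes[idx] + shift
  seq_rev <- revcomp(sequences[usable])

  best <- NULL
  for (k in seq_along(seeds)) {
    model <- build_pwm(seeds[k], background, pseudocount, geometry = g)
    occupancy <- NULL
    for (iter in seq_len(max_iter)) {
      new_occ <- best_occurrences(model, flat, np_all, L, bounds,
                                  sequences[usable], seq_rev, b,
                                  g$spacer, tl)
      if (!is.null(occupancy) &&
          identical(new_occ$position, occupancy$position) &&
          identical(new_occ$strand, occupancy$strand)) {
        break
      }
      occupancy <- new_occ
      model <- build_pwm(occupancy$site, background, pseudocount,
                         geometry = g)
    }
    objective <- (folded_ic(model) - ic_penalty * ncol(model$pwm)) *
      length(occupancy$position)
    if (is.null(best) || objective > best$objective + 1e-9) {
      best <- list(model = model,
                   occupancy = data.frame(
                     seq_index = usable,
                     position = occupancy$position,
                     strand = occupancy$strand,
                     site = occupancy$site,
                     stringsAsFactors = FALSE),
                   objective = objective)
    }
  }
  best
}

# Geometry-selection information content. A direct repeat is one box
# motif occurring twice, so the two box halves of the frequency matrix
# are folded (averaged) before the information content is computed:
# genuine box columns agree between the halves and keep their IC, while
# spuriously absorbed spacer/flank columns pair incoherent
# distributions and fold to near-background. This is what lets the grid
# search pin the exact box length instead of drifting wider.
#' @noRd
folded_ic <- function(model) {
  b <- model$geometry$box_len
  favg <- (model$freq[, 1:b, drop = FALSE] +
             model$freq[, (b + 1L):(2L * b), drop = FALSE]) / 2
  2 * sum(colSums(favg * log2(favg / model$background)))
}

# Best box self-match fraction over all sequences for one geometry -
# the cheap pre-score used to rank the grid.
#' @noRd
dyad_quality <- function(g, codes_fwd, usable) {
  b <- g$box_len
  d <- g$center_distance
  tl <- g$total_len
  best <- 0
  for (i in usable) {
    cc <- codes_fwd[[i]]
    n <- length(cc)
    np <- n - tl + 1L
    if (np < 1L) next
    eq <- !is.na(cc[1:(n - d)]) & !is.na(cc[(d + 1L):n]) &
      cc[1:(n - d)] == cc[(d + 1L):n]
    cs <- cumsum(c(0L, eq))
    w <- cs[(b + 1L):(np + b)] - cs[1:np]
    best <- max(best, max(w) / b)
  }
  best
}

# Seed box-pair words for one geometry: within a true dyad occurrence
# the two boxes are near-copies of the same consensus, so positions
# where the word at p closely matches the word at p + center_distance
# are strong seeds. The per-position box self-match count is a running
# sum, O(n) per sequence.
#' @noRd
dyad_seeds <- function(g, sequences, codes_fwd, usable, n_seeds) {
  b <- g$box_len
  d <- g$center_distance
  tl <- g$total_len
  cand_seq <- integer(0); cand_pos <- integer(0); cand_m <- integer(0)
  for (i in usable) {
    cc <- codes_fwd[[i]]
    n <- length(cc)
    np <- n - tl + 1L
    if (np < 1L) next
    eq <- !is.na(cc[1:(n - d)]) & !is.na(cc[(d + 1L):n]) &
      cc[1:(n - d)] == cc[(d + 1L):n]
    cs <- cumsum(c(0L, eq))
    w <- cs[(b + 1L):(np + b)] - cs[1:np]   # self-matches of box at p
    take <- order(-w, seq_along(w))[seq_len(min(3L, np))]
    cand_seq <- c(cand_seq, rep(i, length(take)))
    cand_pos <- c(cand_pos, take)
    cand_m <- c(cand_m, w[take])
  }
  if (length(cand_pos) == 0L) return(character(0))
  ord <- order(-cand_m, cand_seq, cand_pos)
  words <- character(0)
  for (k in utils::head(ord, 3L * n_seeds)) {
    i <- cand_seq[k]; p <- cand_pos[k]
    s <- sequences[[i]]
    word <- paste0(substr(s, p, p + b - 1L),
                   substr(s, p + d, p + tl - 1L))
    if (!grepl("N", word, fixed = TRUE)) words <- c(words, word)
    if (length(unique(words)) >= n_seeds) break
  }
  unique(words)
}

# Best occurrence (position and strand) of the model in each sequence.
# Ties prefer the forward strand, then the smallest position.
#' @noRd
best_occurrences <- function(model, flat, np_all, L, bounds, seq_fwd,
                             seq_rev, b, spacer, tl) {
  pwm5 <- rbind(model$pwm, -Inf)
  scores <- .rowSums(pwm5[flat], np_all, L)
  nuse <- nrow(bounds)
  position <- integer(nuse)
  strand <- character(nuse)
  site <- character(nuse)
  for (k in seq_len(nuse)) {
    sf <- scores[bounds[k, 1L] + seq_len(bounds[k, 2L]) - 1L]
    sr <- scores[bounds[k, 3L] + seq_len(bounds[k, 4L]) - 1L]
    bf <- which.max(sf)
    br <- which.max(sr)
    if (length(br) == 0L || (length(bf) > 0L && sf[bf] >= sr[br])) {
      pos <- bf; st <- "+"; s <- seq_fwd[k]
    } else {
      pos <- br; st <- "-"; s <- seq_rev[k]
    }
    position[k] <- pos
    strand[k] <- st
    site[k] <- paste0(substr(s, pos, pos + b - 1L),
                      substr(s, pos + b + spacer, pos + tl - 1L))
  }
  list(position = position, strand = strand, site = site)
}
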