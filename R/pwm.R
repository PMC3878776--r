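# Position weight matrices. The log-odds formula with an additive
# background-weighted pseudocount is stated explicitly so that every
# entry is exactly testable:
#   pwm[b, j] = log2( (count[b, j] + pc * bg[b]) / (n + pc) / bg[b] )
# Per-column information content uses the same pseudocounted
# frequencies:  IC_j = sum_b f[b, j] * log2(f[b, j] / bg[b]).
# For direct-repeat models only the two boxes are represented: the
# spacer is non-conserved and its columns are excluded from the matrix
# and from scoring; the boxes are scored at their fixed separation.

#' Motif geometry
#'
#' @param kind `"direct_repeat"`, `"palindrome"` or `"generic"`.
#' @param box_len box length in bp (direct repeats).
#' @param spacer spacer length in bp (direct repeats).
#' @param total_len motif length for palindrome/generic kinds.
#' @return a `motif_geometry` object with `total_len` and, for direct
#'   repeats, `center_distance = box_len + spacer` (which for two equal
#'   boxes equals the start-to-start distance of the repeats).
#' @export
motif_geometry <- function(kind = c("direct_repeat", "palindrome", "generic"),
                           box_len = NULL, spacer = NULL, total_len = NULL) {
  kind <- match.arg(kind)
  if (kind == "direct_repeat") {
    if (is.null(box_len) || is.null(spacer)) {
      stopf("direct_repeat geometry needs box_len and spacer")
    }
    box_len <- as.integer(box_len)
    spacer <- as.integer(spacer)
    g <- list(kind = kind, box_len = box_len, spacer = spacer,
              total_len = 2L * box_len + spacer,
              center_distance = box_len + spacer,
              scored_len = 2L * box_len)
  } else {
    if (is.null(total_len)) stopf("%s geometry needs total_len", kind)
    total_len <- as.integer(total_len)
    g <- list(kind = kind, box_len = NULL, spacer = NULL,
              total_len = total_len, center_distance = NULL,
              scored_len = total_len)
  }
  structure(g, class = "motif_geometry")
}

#' @export
print.motif_geometry <- function(x, ...) {
  if (x$kind == "direct_repeat") {
    cat(sprintf("<motif_geometry> direct repeat: 2 x %d bp boxes, %d bp spacer (center distance %d bp)\n",
                x$box_len, x$spacer, x$center_distance))
  } else {
    cat(sprintf("<motif_geometry> %s, %d bp\n", x$kind, x$total_len))
  }
  invisible(x)
}

#' Build a PWM motif model from aligned sites
#'
#' @param sites equal-length DNA site strings over `ACGT`. For direct
#'   repeats these are the concatenated boxes (length `2 * box_len`,
#'   spacer excluded).
#' @param background base frequencies (A, C, G, T); strictly positive.
#'   Default uniform.
#' @param pseudocount additive background-weighted pseudocount
#'   (default 0.5).
#' @param geometry a [motif_geometry()]; default generic of the site
#'   length.
#' @return object of class `motif_model` with `counts`, `freq`, `pwm`
#'   (log2 odds, bits), `ic` (per-column information content),
#'   `background`, `pseudocount`, `n_sites`, `training_sites` and
#'   `geometry`.
#' @export
build_pwm <- function(sites, background = rep(0.25, 4), pseudocount = 0.5,
                      geometry = NULL) {
  if (length(sites) < 1L) stopf("need at least one site")
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L) stopf("sites must have equal length")
  background <- check_background(background)
  if (pseudocount <= 0) stopf("pseudocount must be positive")
  code_list <- lapply(sites, dna_codes)
  if (anyNA(unlist(code_list))) stopf("sites must use the ACGT alphabet")
  L <- lens[1]
  geometry <- geometry %||% motif_geometry("generic", total_len = L)
  if (geometry$scored_len != L) {
    stopf("site length %d does not match geometry scored length %d",
          L, geometry$scored_len)
  }
  n <- length(sites)
  counts <- matrix(0L, 4L, L, dimnames = list(DNA_BASES4, NULL))
  for (codes in code_list) {
    counts[cbind(codes, seq_len(L))] <- counts[cbind(codes, seq_len(L))] + 1L
  }
  model_from_counts(counts, n, background, pseudocount, geometry, sites)
}

#' @noRd
model_from_counts <- function(counts, n, background, pseudocount,
                              geometry, training_sites) {
  freq <- (counts + pseudocount * background) / (n + pseudocount)
  pwm <- log2(freq / background)
  ic <- colSums(freq * log2(freq / background))
  structure(
    list(geometry = geometry, counts = counts, freq = freq, pwm = pwm,
         ic = ic, background = background, pseudocount = pseudocount,
         n_sites = n, training_sites = training_sites),
    class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s, %d scored columns, %d training sites, IC %.1f bits\n",
              x$geometry$kind, ncol(x$pwm), x$n_sites, sum(x$ic)))
  cat("consensus:", as.character(consensus(x)), "\n")
  invisible(x)
}

#' @method summary motif_model
#' @export
summary.motif_model <- function(object, ...) {
  print(object)
  cat("\nper-column information content (bits):\n")
  bars <- vapply(object$ic, function(v) {
    strrep("#", max(0L, round(pmax(v, 0) * 10)))
  }, character(1))
  cons <- strsplit(as.character(consensus(object)), "")[[1]]
  for (j in seq_along(object$ic)) {
    cat(sprintf("%3d %s %5.2f %s\n", j, cons[j], object$ic[j], bars[j]))
  }
  invisible(object)
}

#' Total information content of a motif model, in bits
#'
#' @param model a `motif_model`.
#' @return sum of the per-column information contents.
#' @export
information_content <- function(model) sum(model$ic)

#' Score one word under a motif model
#'
#' The word is the concatenation of the scored columns (both boxes for a
#' direct repeat, spacer excluded). Any ambiguity code makes the score
#' `-Inf`, so such sites can never pass a finite threshold.
#'
#' @param model a `motif_model`.
#' @param word DNA string of length `ncol(model$pwm)`.
#' @return score in bits.
#' @export
score_word <- function(model, word) {
  L <- ncol(model$pwm)
  if (nchar(word) != L) {
    stopf("word length %d does not match scoring length %d", nchar(word), L)
  }
  codes <- dna_codes(word)
  if (anyNA(codes)) return(-Inf)
  sum(model$pwm[cbind(codes, seq_len(L))])
}

# Score every placement of the model along an integer-coded sequence
# (one strand). Returns one score per start position of the full site
# (total_len including any spacer); NA codes propagate to -Inf.
#' @noRd
score_positions <- function(model, codes) {
  g <- model$geometry
  offsets <- if (g$kind == "direct_repeat") {
    c(0:(g$box_len - 1L), (g$box_len + g$spacer):(g$total_len - 1L))
  } else {
    0:(g$total_len - 1L)
  }
  np <- length(codes) - g$total_len + 1L
  if (np < 1L) return(numeric(0))
  L <- length(offsets)
  # flat lookup into the PWM extended by a 5th "-Inf" row for N codes
  codes5 <- codes
  codes5[is.na(codes5)] <- 5L
  pwm5 <- rbind(model$pwm, -Inf)
  idx <- rep(offsets, each = np) + seq_len(np)
  vals <- pwm5[codes5[idx] + 5L * rep(seq_len(L) - 1L, each = np)]
  .rowSums(vals, np, L)
}

#' IUPAC consensus of a motif model
#'
#' Per column: the single base if its frequency reaches `strong`; a
#' two-base IUPAC code (lowercase) if the top two frequencies sum to at
#' least `weak_pair`; `n` otherwise.
#'
#' @param model a `motif_model`.
#' @param strong single-base threshold (default 0.7).
#' @param weak_pair two-base threshold (default 0.8).
#' @return a `consensus_string` (character scalar with class attribute).
#' @export
consensus <- function(model, strong = 0.7, weak_pair = 0.8) {
  pair_codes <- c(AC = "m", AG = "r", AT = "w", CG = "s", CT = "y", GT = "k")
  letters_out <- apply(model$freq, 2L, function(f) {
    ord <- order(-f, DNA_BASES4)
    if (f[ord[1]] >= strong) return(DNA_BASES4[ord[1]])
    if (f[ord[1]] + f[ord[2]] >= weak_pair) {
      key <- paste(sort(DNA_BASES4[ord[1:2]]), collapse = "")
      return(pair_codes[[key]])
    }
    "n"
  })
  structure(paste(letters_out, collapse = ""), class = "consensus_string")
}

#' @export
print.consensus_string <- function(x, ...) {
  cat(unclass(x), "\n")
  invisible(x)
}

#' Is an IUPAC consensus palindromic?
#'
#' True iff the string equals its IUPAC reverse complement (`W` and `S`
#' are self-complementary, `R` pairs with `Y`, `K` with `M`, `N` with
#' `N`). Case-insensitive.
#'
#' @param c a `consensus_string` or plain IUPAC string.
#' @return logical.
#' @export
is_palindromic <- function(c) {
  s <- toupper(unclass(c))
  if (grepl("[^ACGTRYKMWSN]", s)) stopf("invalid IUPAC symbol in '%s'", s)
  identical(s, toupper(revcomp_iupac(s)))
}

#' Write a motif in MEME minimal format
#'
#' @param model a `motif_model`.
#' @param path output path.
#' @param name motif name.
#' @return `path`, invisibly.
#' @export
write_meme <- function(model, path, name = "motif1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               sprintf("Background letter frequencies"),
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       model$background[1], model$background[2],
                       model$background[3], model$background[4]), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(model$freq), model$n_sites)), con)
  for (j in seq_len(ncol(model$freq))) {
    writeLines(sprintf(" %.6f %.6f %.6f %.6f", model$freq[1, j],
                       model$freq[2, j], model$freq[3, j],
                       model$freq[4, j]), con)
  }
  invisible(path)
}

#' Write a motif count matrix in TRANSFAC style
#'
#' @param model a `motif_model`.
#' @param path output path.
#' @param name motif identifier.
#' @return `path`, invisibly.
#' @export
write_transfac <- function(model, path, name = "motif1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ID %s", name), sprintf("BF %s", name),
               "P0      A      C      G      T"), con)
  cons <- strsplit(toupper(as.character(consensus(model))), "")[[1]]
  for (j in seq_len(ncol(model$counts))) {
    writeLines(sprintf("%02d %6d %6d %6d %6d %s", j,
                       model$counts[1, j], model$counts[2, j],
                       model$counts[3, j], model$counts[4, j], cons[j]), con)
  }
  writeLines("XX\n//", con)
  invisible(path)
}
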