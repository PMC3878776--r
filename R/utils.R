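# Low-level sequence helpers shared across modules. DNA is handled as plain
# uppercase character strings; the integer encoding A=1 C=2 G=3 T=4 (N and
# other ambiguity codes -> NA) is what the scanners and PWMs operate on.

DNA_BASES4 <- c("A", "C", "G", "T")

#' @noRd
dna_codes <- function(x) {
  match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES4)
}

#' @noRd
codes_to_dna <- function(codes) {
  paste(ifelse(is.na(codes), "N", DNA_BASES4[codes]), collapse = "")
}

#' Reverse complement of plain DNA strings
#'
#' Vectorised over `x`; case is preserved and `N` maps to `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(flipped, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# IUPAC complement used by the palindrome test (W and S are self-
# complementary, R<->Y, K<->M).
IUPAC_FROM <- "ACGTRYKMWSNacgtrykmwsn"
IUPAC_TO   <- "TGCAYRMKWSNtgcayrmkwsn"

#' @noRd
revcomp_iupac <- function(x) {
  flipped <- chartr(IUPAC_FROM, IUPAC_TO, x)
  vapply(flipped, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

#' @noRd
base_frequencies <- function(sequences) {
  codes <- unlist(lapply(sequences, dna_codes), use.names = FALSE)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L) {
    return(setNames(rep(0.25, 4), DNA_BASES4))
  }
  counts <- tabulate(codes, nbins = 4L)
  # guard against degenerate inputs missing a base entirely
  counts <- counts + 1
  setNames(counts / sum(counts), DNA_BASES4)
}

#' @noRd
check_background <- function(background) {
  if (length(background) != 4L || any(!is.finite(background)) ||
      any(background <= 0)) {
    stop("background must be 4 strictly positive frequencies", call. = FALSE)
  }
  background <- background / sum(background)
  names(background) <- DNA_BASES4
  background
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
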