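#' Recombination signal sequence (RSS) consensus motifs
#'
#' The canonical heptamer and nonamer consensus used when scanning for
#' recombination signal sequences. Both can be overridden in [find_rss()].
#'
#' @name rss-consensus
#' @keywords internal
RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER <- "ACAAAAACC"

## spacer length (bp) for each RSS class
rss_spacer_length <- function(spacer_class) {
  switch(spacer_class, RSS12 = 12L, RSS23 = 23L,
         stop("spacer_class must be 'RSS12' or 'RSS23'", call. = FALSE))
}

## per-offset mismatch counts of `pattern` against every window of `sv`
## (a character vector of bases); N in the subject counts as a mismatch.
.window_mismatches <- function(sv, pattern) {
  k <- nchar(pattern)
  L <- length(sv)
  n_win <- L - k + 1L
  if (n_win < 1L) return(integer(0))
  pv <- s2c(pattern)
  m <- integer(n_win)
  for (j in seq_len(k)) {
    m <- m + (sv[j:(n_win + j - 1L)] != pv[j])
  }
  m
}

## scan one strand (sequence given 5'->3') for heptamer..spacer..nonamer
.scan_rss_strand <- function(sv, spacers, heptamer, nonamer,
                             heptamer_budget, nonamer_budget) {
  hm <- .window_mismatches(sv, heptamer)
  nm <- .window_mismatches(sv, nonamer)
  out <- list()
  for (sp in spacers) {
    ## heptamer window i (1-based), nonamer window i + 7 + sp
    off <- nchar(heptamer) + sp
    n_ok <- length(nm) - off
    if (n_ok < 1L) next
    i <- seq_len(n_ok)
    keep <- hm[i] <= heptamer_budget & nm[i + off] <= nonamer_budget
    if (any(keep)) {
      idx <- i[keep]
      out[[length(out) + 1L]] <- data.frame(
        start1 = idx, spacer_len = sp,
        heptamer_mismatches = hm[idx],
        nonamer_mismatches = nm[idx + off]
      )
    }
  }
  if (!length(out)) {
    return(data.frame(start1 = integer(0), spacer_len = integer(0),
                      heptamer_mismatches = integer(0),
                      nonamer_mismatches = integer(0)))
  }
  do.call(rbind, out)
}

#' Scan a genomic sequence for recombination signal sequences
#'
#' Finds every position, on both strands, where the RSS heptamer and nonamer
#' consensus occur separated by the spacer length of the requested class
#' (12 bp or 23 bp) within `spacer_tolerance`, allowing up to
#' `heptamer_budget` / `nonamer_budget` mismatches per motif. Comparison is
#' plain base-by-base against the consensus; an `N` in the genome counts as a
#' mismatch.
#'
#' Coordinates are 0-based offsets on the forward strand. For a minus-strand
#' match, `heptamer_start` is the forward-strand offset of the left-most
#' genomic base of the (reverse-complemented) heptamer, so the heptamer
#' occupies `[heptamer_start, heptamer_start + 7)` in genome coordinates on
#' either strand.
#'
#' @param genome a DNA string (character or `DNAString`) over A/C/G/T/N.
#' @param spacer_class `"RSS12"` or `"RSS23"`.
#' @param heptamer_budget,nonamer_budget maximum mismatches allowed in the
#'   heptamer and nonamer, respectively.
#' @param spacer_tolerance spacer length slack in bp (default 1, i.e. 12 +- 1
#'   or 23 +- 1).
#' @param heptamer,nonamer consensus motifs (defaults `CACAGTG`,
#'   `ACAAAAACC`).
#' @return a `data.frame` with columns `heptamer_start`, `spacer_len`,
#'   `spacer_class`, `strand`, `heptamer_mismatches`, `nonamer_mismatches`,
#'   sorted by `heptamer_start` then strand.
#' @examples
#' g <- paste0("CACAGTG", strrep("A", 23), "ACAAAAACC")
#' find_rss(g, "RSS23", 0, 0, 0)
#' @export
find_rss <- function(genome, spacer_class = c("RSS23", "RSS12"),
                     heptamer_budget = 1L, nonamer_budget = 2L,
                     spacer_tolerance = 1L,
                     heptamer = RSS_HEPTAMER, nonamer = RSS_NONAMER) {
  spacer_class <- match.arg(spacer_class)
  stopifnot(heptamer_budget >= 0, nonamer_budget >= 0, spacer_tolerance >= 0)
  g <- as_dna_string(genome)
  check_dna_alphabet(g)
  empty <- data.frame(heptamer_start = integer(0), spacer_len = integer(0),
                      spacer_class = character(0), strand = character(0),
                      heptamer_mismatches = integer(0),
                      nonamer_mismatches = integer(0),
                      stringsAsFactors = FALSE)
  L <- nchar(g)
  sp0 <- rss_spacer_length(spacer_class)
  spacers <- max(0L, sp0 - spacer_tolerance):(sp0 + spacer_tolerance)
  if (L < nchar(heptamer) + min(spacers) + nchar(nonamer)) return(empty)

  sv <- s2c(g)
  plus <- .scan_rss_strand(sv, spacers, heptamer, nonamer,
                           heptamer_budget, nonamer_budget)
  minus <- .scan_rss_strand(rev(complement_chr(sv)), spacers, heptamer,
                            nonamer, heptamer_budget, nonamer_budget)
  res <- list()
  if (nrow(plus)) {
    plus$heptamer_start <- plus$start1 - 1L
    plus$strand <- "+"
    res[[1L]] <- plus
  }
  if (nrow(minus)) {
    ## map reverse-complement offset back to forward coordinates of the
    ## heptamer's left-most base
    minus$heptamer_start <- L - (minus$start1 - 1L) - nchar(heptamer)
    minus$strand <- "-"
    res[[length(res) + 1L]] <- minus
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out$spacer_class <- spacer_class
  out <- out[, c("heptamer_start", "spacer_len", "spacer_class", "strand",
                 "heptamer_mismatches", "nonamer_mismatches")]
  out <- out[order(out$heptamer_start, out$strand, out$spacer_len), ]
  rownames(out) <- NULL
  out
}
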