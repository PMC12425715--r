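#' @import methods
#' @importFrom stats setNames rbinom runif
#' @importFrom utils head tail write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")

## IUPAC codes used by the AID hotspot motifs
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), K = c("G", "T"), M = c("A", "C"),
  N = c("A", "C", "G", "T")
)

## split a string into a character vector of single bases
s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

c2s <- function(x) paste(x, collapse = "")

#' Reverse complement of a DNA string
#'
#' Operates on plain character strings; `N` is preserved.
#'
#' @param x a single DNA string over A/C/G/T/N.
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  chartr("ACGTN", "TGCAN", paste(rev(s2c(x)), collapse = ""))
}

complement_chr <- function(x) chartr("ACGTN", "TGCAN", x)

## coerce DNAString/DNAStringSet/character to an upper-case character string
as_dna_string <- function(x) {
  if (methods::is(x, "DNAString") || methods::is(x, "DNAStringSet")) {
    x <- as.character(x)
  }
  toupper(x)
}

check_dna_alphabet <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!all(grepl(pat, x))) {
    stop("sequence contains characters outside the DNA alphabet ",
         if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}", call. = FALSE)
  }
  invisible(x)
}

## number of positions at which two equal-length base vectors differ
hamming <- function(a, b) sum(a != b)

## translate a DNA string starting at frame 0; incomplete terminal codon is
## dropped and any codon containing a non-ACGT base becomes "X"
translate_dna <- local({
  code <- NULL
  function(x) {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    n <- nchar(x) - nchar(x) %% 3L
    if (n < 3L) return("")
    codons <- substring(x, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
})

## Maximal-scoring contiguous subarray (used for gap-free local alignment
## trimming). Ties are broken toward the shortest, left-most interval so the
## result is deterministic. Returns c(start, end) 1-based inclusive, or
## c(0, -1) when all entries are negative.
max_subarray <- function(score) {
  best_sum <- 0
  best <- c(0L, -1L)
  cur_sum <- 0
  cur_start <- 1L
  for (i in seq_along(score)) {
    if (cur_sum <= 0) {
      cur_sum <- score[i]
      cur_start <- i
    } else {
      cur_sum <- cur_sum + score[i]
    }
    if (cur_sum > best_sum) {
      best_sum <- cur_sum
      best <- c(cur_start, i)
    }
  }
  best
}

## truncated geometric draw on 0:cap with success probability p
rgeom_trunc <- function(n, p, cap) {
  k <- 0:cap
  w <- (1 - p)^k * p
  sample(k, n, replace = TRUE, prob = w / sum(w))
}

## analytic mean of the truncated geometric law above
mean_geom_trunc <- function(p, cap) {
  k <- 0:cap
  w <- (1 - p)^k * p
  sum(k * w) / sum(w)
}

## longest exact common substring between two short strings.
## Returns list(len, a_start, b_start) with 1-based starts (len = 0 if none).
## Ties prefer the left-most position in `a`, then in `b`.
longest_common_substring <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  best <- list(len = 0L, a_start = 0L, b_start = 0L)
  if (la == 0L || lb == 0L) return(best)
  av <- s2c(a); bv <- s2c(b)
  ## slide b across a; shift = a_index - b_index
  for (shift in (-(lb - 1L)):(la - 1L)) {
    a0 <- max(1L, 1L + shift)
    b0 <- a0 - shift
    len <- min(la - a0, lb - b0) + 1L
    if (len < 1L) next
    eq <- av[a0:(a0 + len - 1L)] == bv[b0:(b0 + len - 1L)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    if (!length(hit)) next
    runlens <- r$lengths[hit]
    m <- max(runlens)
    if (m > best$len) {
      j <- hit[which.max(runlens)]
      best <- list(len = as.integer(m),
                   a_start = a0 + starts[j] - 1L,
                   b_start = b0 + starts[j] - 1L)
    }
  }
  best
}
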