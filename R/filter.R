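## Read-level quality gates applied before assignment: a read is kept when
## it reaches the minimum length and carries both amplification primers
## (forward primer near the 5' end, reverse-complemented reverse primer
## near the 3' end, Hamming match within a mismatch budget). Kept reads
## have their primers trimmed.

## first Hamming match of `primer` within the first `window` bp; returns
## 1-based start or NA
.find_primer_5p <- function(read, primer, max_mm, window) {
  lp <- nchar(primer)
  pv <- s2c(primer)
  last <- min(window - lp, nchar(read) - lp)
  if (last < 0L) return(NA_integer_)
  for (o in 0:last) {
    if (hamming(s2c(substr(read, o + 1L, o + lp)), pv) <= max_mm)
      return(o + 1L)
  }
  NA_integer_
}

## last Hamming match of `pattern` within the final `window` bp
.find_primer_3p <- function(read, pattern, max_mm, window) {
  lp <- nchar(pattern)
  pv <- s2c(pattern)
  L <- nchar(read)
  first <- max(1L, L - window + 1L)
  if (L - lp + 1L < first) return(NA_integer_)
  for (o in (L - lp + 1L):first) {
    if (hamming(s2c(substr(read, o, o + lp - 1L)), pv) <= max_mm)
      return(o)
  }
  NA_integer_
}

#' Filter amplicon reads by length and primer presence
#'
#' A read is kept iff (a) its length is at least `min_len` and (b) the
#' forward primer matches within `max_primer_mismatches` in the first
#' `window` bp and the reverse complement of the reverse primer matches in
#' the last `window` bp. Primer matching is ungapped (Hamming). Rejections
#' are partitioned by the first failing rule, in the order
#' `too_short`, `missing_fwd_primer`, `missing_rev_primer`. Kept reads are
#' returned with primers (and any bases outside them) trimmed.
#'
#' @param reads a named `DNAStringSet` or character vector.
#' @param forward_primer,reverse_primer primer sequences (the reverse
#'   primer as primer sequence, not reverse-complemented).
#' @param min_len minimum read length in bp (default 400; shorter reads
#'   cannot span a complete rearrangement).
#' @param max_primer_mismatches Hamming budget per primer (default 2).
#' @param window primer search window at each read end (default 60 bp).
#' @param barcode_len optional fixed-length barcode to trim before primer
#'   search (default 0).
#' @return a list: `kept` (trimmed `DNAStringSet`), `report` (named integer
#'   vector of rejection counts plus `kept`), `reasons` (per-read character
#'   vector, `NA` for kept reads).
#' @export
filter_reads <- function(reads, forward_primer, reverse_primer,
                         min_len = 400L, max_primer_mismatches = 2L,
                         window = 60L, barcode_len = 0L) {
  stopifnot(min_len >= 0L, nzchar(forward_primer), nzchar(reverse_primer))
  rd <- vapply(as.character(reads), as_dna_string, "")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(rd))
  fwd <- as_dna_string(forward_primer)
  rev3 <- revcomp(as_dna_string(reverse_primer))
  n <- length(rd)
  reasons <- rep(NA_character_, n)
  kept <- character(0)
  kept_ids <- character(0)
  for (i in seq_len(n)) {
    r <- rd[[i]]
    if (barcode_len > 0L) r <- substr(r, barcode_len + 1L, nchar(r))
    if (nchar(r) < min_len) {
      reasons[i] <- "too_short"
      next
    }
    s5 <- .find_primer_5p(r, fwd, max_primer_mismatches, window)
    if (is.na(s5)) {
      reasons[i] <- "missing_fwd_primer"
      next
    }
    s3 <- .find_primer_3p(r, rev3, max_primer_mismatches, window)
    if (is.na(s3)) {
      reasons[i] <- "missing_rev_primer"
      next
    }
    kept <- c(kept, substr(r, s5 + nchar(fwd), s3 - 1L))
    kept_ids <- c(kept_ids, ids[i])
  }
  report <- c(
    kept = length(kept),
    too_short = sum(reasons == "too_short", na.rm = TRUE),
    missing_fwd_primer = sum(reasons == "missing_fwd_primer", na.rm = TRUE),
    missing_rev_primer = sum(reasons == "missing_rev_primer", na.rm = TRUE)
  )
  list(kept = Biostrings::DNAStringSet(setNames(kept, kept_ids)),
       report = report, reasons = setNames(reasons, ids))
}
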