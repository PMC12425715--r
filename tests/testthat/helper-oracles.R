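## Independent oracles. Each is written as a direct, per-offset (or
## per-pair) computation so it shares no code path with the vectorised
## implementation it checks.

## brute-force RSS scan: test every offset, spacer length and strand
## independently, counting mismatches character by character
brute_rss <- function(genome, spacer_class, heptamer_budget, nonamer_budget,
                      spacer_tolerance,
                      heptamer = "CACAGTG", nonamer = "ACAAAAACC") {
  sp0 <- if (spacer_class == "RSS12") 12L else 23L
  spacers <- max(0L, sp0 - spacer_tolerance):(sp0 + spacer_tolerance)
  hv <- strsplit(heptamer, "")[[1L]]
  nv <- strsplit(nonamer, "")[[1L]]
  scan_one <- function(seq_chars, strand, L) {
    res <- list()
    for (i in seq_len(length(seq_chars))) {
      for (sp in spacers) {
        hep_end <- i + 6L
        non_start <- hep_end + sp + 1L
        non_end <- non_start + 8L
        if (non_end > length(seq_chars)) next
        hm <- sum(seq_chars[i:hep_end] != hv)
        nm <- sum(seq_chars[non_start:non_end] != nv)
        if (hm <= heptamer_budget && nm <= nonamer_budget) {
          start <- if (strand == "+") i - 1L else L - (i - 1L) - 7L
          res[[length(res) + 1L]] <- data.frame(
            heptamer_start = start, spacer_len = sp, strand = strand,
            heptamer_mismatches = hm, nonamer_mismatches = nm)
        }
      }
    }
    res
  }
  g <- strsplit(genome, "")[[1L]]
  L <- length(g)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  grc <- rev(unname(comp[g]))
  out <- c(scan_one(g, "+", L), scan_one(grc, "-", L))
  if (!length(out))
    return(data.frame(heptamer_start = integer(0), spacer_len = integer(0),
                      strand = character(0),
                      heptamer_mismatches = integer(0),
                      nonamer_mismatches = integer(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$heptamer_start, df$strand, df$spacer_len), ]
  rownames(df) <- NULL
  df
}

## exhaustive sliding-window identity oracle: best gap-free placement of a
## template in a genome, by direct per-offset comparison
sliding_identity_oracle <- function(genome, template) {
  g <- strsplit(genome, "")[[1L]]
  t <- strsplit(template, "")[[1L]]
  k <- length(t)
  best <- list(identity = -1, start = NA_integer_)
  for (o in 0:(length(g) - k)) {
    id <- sum(g[(o + 1L):(o + k)] == t) / k
    if (id > best$identity) best <- list(identity = id, start = o)
  }
  best
}

## connected components of the thresholded pairwise-identity graph,
## computed directly with pairwiseAlignment on every pair plus BFS
identity_components_oracle <- function(seqs, threshold) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(seqs[[j]]),
        type = "global")
      ok <- Biostrings::pid(pa, type = "PID1") / 100 >= threshold
      adj[i, j] <- adj[j, i] <- ok
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}
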