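## V(D)J assignment by seeded, gap-free alignment. Rearranged amplicon
## reads are substitution-dominated (merged high-quality reads, SHM and
## sequencing error are point events), so germline segments are anchored by
## short exact-ish seeds and evaluated base-by-base at the implied offset;
## region boundaries are then refined by exact-match extension. Ties are
## broken score -> identity -> name so calls are reproducible.

## collect seed votes: for each germline sequence, match seeds of length
## `seed_len` taken every `seed_step` bp against all reads; returns a
## data.frame (read_idx, gene_idx, offset) of implied germline-0 offsets
.seed_votes <- function(reads_set, gseqs, seed_len, seed_step, seed_mm) {
  ri_all <- gi_all <- off_all <- list()
  k <- 0L
  for (gi in seq_along(gseqs)) {
    g <- gseqs[[gi]]
    Lg <- nchar(g)
    if (Lg < seed_len) next
    offs <- unique(c(seq(0L, Lg - seed_len, by = seed_step), Lg - seed_len))
    for (so in offs) {
      seed <- substr(g, so + 1L, so + seed_len)
      m <- Biostrings::vmatchPattern(seed, reads_set, max.mismatch = seed_mm)
      st <- Biostrings::startIndex(m)
      lens <- lengths(st)
      if (!sum(lens)) next
      k <- k + 1L
      ri_all[[k]] <- rep.int(seq_along(st), lens)
      gi_all[[k]] <- rep.int(gi, sum(lens))
      off_all[[k]] <- unlist(st, use.names = FALSE) - 1L - so
    }
  }
  if (!k)
    return(data.frame(read_idx = integer(0), gene_idx = integer(0),
                      offset = integer(0)))
  out <- data.frame(read_idx = unlist(ri_all), gene_idx = unlist(gi_all),
                    offset = unlist(off_all))
  out[out$offset >= 0L, , drop = FALSE]
}

## evaluate a germline at a fixed offset. Score and identity come from the
## maximal-scoring (match +2 / mismatch -2) contiguous stretch, i.e. a
## gap-free local alignment. For V segments (`mutations_from_start`), the
## mutation-scoring interval instead runs from germline position 0 (the
## amplicons span the complete V) to the local-alignment 3' end, so
## substitutions near either end are not silently trimmed away.
.evaluate_gene <- function(read, gseq, offset, mutations_from_start = FALSE) {
  mv <- .match_vector(read, gseq, offset)
  if (!length(mv)) return(NULL)
  k <- max_subarray(ifelse(mv, 2L, -2L))
  if (k[2L] < k[1L]) return(NULL)
  gs <- k[1L] - 1L                     # 0-based germline start
  ge <- k[2L]                          # exclusive germline end
  span <- mv[(gs + 1L):ge]
  matches <- sum(span)
  len <- ge - gs
  mut_lo <- if (mutations_from_start) 0L else gs
  mspan <- mv[(mut_lo + 1L):ge]
  mut_pos <- mut_lo + which(!mspan) - 1L   # 0-based germline positions
  list(germ_start = gs, germ_end = ge, mut_start = mut_lo, mut_end = ge,
       score = 2L * matches - 2L * (len - matches),
       identity = matches / len, mut_pos = mut_pos, offset = offset)
}

#' Assign germline V and J segments to reads
#'
#' Anchors each germline segment on the read with short seeds, evaluates
#' candidate placements base-by-base, refines the aligned interval by
#' exact-match extension, and keeps the best-scoring V and (3' of it) J per
#' read. Reads whose best V or J identity falls below the thresholds, or
#' whose V/J ordering is inconsistent, are rejected with a reason. Reads
#' with no forward-strand V candidate are retried reverse-complemented.
#' D segments are called during [decompose_junctions()].
#'
#' @param reads a named `DNAStringSet` or character vector of reads
#'   (primers already trimmed).
#' @param ref a `germline_reference`; all V and J segments of `locus` are
#'   used.
#' @param locus locus to assign against; default the single locus in `ref`.
#' @param min_v_identity,min_j_identity identity thresholds below which the
#'   read is rejected (defaults 0.70 and 0.80; J is short).
#' @param sample_id sample label carried into all outputs.
#' @return an object of class `ig_repertoire`: a list with
#'   `rearrangements` (one row per assigned read), `mutations` (long table
#'   of V-region substitutions: `sequence_id`, `germline`, `pos`, `from`,
#'   `to`), and `rejected` (`sequence_id`, `reason`).
#' @export
assign_repertoire <- function(reads, ref, locus = NULL,
                              min_v_identity = 0.70, min_j_identity = 0.80,
                              sample_id = "sample1") {
  stopifnot(inherits(ref, "germline_reference"))
  if (is.null(locus)) {
    locus <- unique(ref$segments$locus)
    if (length(locus) != 1L)
      stop("reference covers several loci; pass `locus`", call. = FALSE)
  }
  vsegs <- ref_segments(ref, "V")
  jsegs <- ref_segments(ref, "J")
  vsegs <- vsegs[vsegs$locus == locus, , drop = FALSE]
  jsegs <- jsegs[jsegs$locus == locus, , drop = FALSE]
  if (!nrow(vsegs) || !nrow(jsegs))
    stop("reference lacks V or J segments for locus ", locus, call. = FALSE)

  rd <- vapply(as.character(reads), as_dna_string, "")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(rd))
  n <- length(rd)
  vseqs <- as.list(ref$sequences[vsegs$name])
  jseqs <- as.list(ref$sequences[jsegs$name])

  reads_set <- Biostrings::DNAStringSet(rd)
  vv <- .seed_votes(reads_set, vseqs, seed_len = 21L, seed_step = 30L,
                    seed_mm = 3L)
  ## reads without any forward V seed: retry reverse-complemented
  miss <- setdiff(seq_len(n), unique(vv$read_idx))
  flipped <- logical(n)
  if (length(miss)) {
    rc <- vapply(rd[miss], revcomp, "")
    vv_rc <- .seed_votes(Biostrings::DNAStringSet(rc), vseqs, 21L, 30L, 3L)
    if (nrow(vv_rc)) {
      fl <- miss[unique(vv_rc$read_idx)]
      flipped[fl] <- TRUE
      rd[fl] <- vapply(rd[fl], revcomp, "")
      vv_rc$read_idx <- miss[vv_rc$read_idx]
      vv <- rbind(vv, vv_rc)
    }
    reads_set <- Biostrings::DNAStringSet(rd)
  }
  jv <- .seed_votes(reads_set, jseqs, seed_len = 12L, seed_step = 6L,
                    seed_mm = 2L)

  v_by_read <- split(vv[, c("gene_idx", "offset")], vv$read_idx)
  j_by_read <- split(jv[, c("gene_idx", "offset")], jv$read_idx)

  rear <- vector("list", n)
  muts <- vector("list", n)
  rej <- vector("list", n)
  for (i in seq_len(n)) {
    read <- rd[[i]]
    cand <- v_by_read[[as.character(i)]]
    best_v <- NULL; best_v_name <- NA_character_
    if (!is.null(cand)) {
      for (gi in unique(cand$gene_idx)) {
        offs <- cand$offset[cand$gene_idx == gi]
        tab <- sort(table(offs), decreasing = TRUE)
        for (o in as.integer(names(tab))) {
          ev <- .evaluate_gene(read, vseqs[[gi]], o,
                               mutations_from_start = TRUE)
          if (is.null(ev)) next
          nm <- vsegs$name[gi]
          if (is.null(best_v) || ev$score > best_v$score ||
              (ev$score == best_v$score &&
               (ev$identity > best_v$identity ||
                (ev$identity == best_v$identity && nm < best_v_name)))) {
            best_v <- ev; best_v_name <- nm
          }
        }
      }
    }
    if (is.null(best_v) || best_v$identity < min_v_identity) {
      rej[[i]] <- data.frame(sequence_id = ids[i], reason = "no_v_match")
      next
    }
    v_read_start <- best_v$offset
    v_read_end <- v_read_start + best_v$germ_end

    cand <- j_by_read[[as.character(i)]]
    best_j <- NULL; best_j_name <- NA_character_
    if (!is.null(cand)) {
      for (gi in unique(cand$gene_idx)) {
        offs <- cand$offset[cand$gene_idx == gi]
        ## J must lie 3' of the V end (small slack for boundary ambiguity)
        offs <- offs[offs >= v_read_end - nchar(jseqs[[gi]]) &
                     offs >= v_read_start]
        for (o in unique(offs)) {
          ev <- .evaluate_gene(read, jseqs[[gi]], o)
          if (is.null(ev)) next
          if (ev$offset + ev$germ_start < v_read_end - 12L) next
          nm <- jsegs$name[gi]
          if (is.null(best_j) || ev$score > best_j$score ||
              (ev$score == best_j$score &&
               (ev$identity > best_j$identity ||
                (ev$identity == best_j$identity && nm < best_j_name)))) {
            best_j <- ev; best_j_name <- nm
          }
        }
      }
    }
    if (is.null(best_j) || best_j$identity < min_j_identity) {
      rej[[i]] <- data.frame(sequence_id = ids[i], reason = "no_j_match")
      next
    }
    if (best_j$offset + best_j$germ_start < v_read_start) {
      rej[[i]] <- data.frame(sequence_id = ids[i], reason = "vj_order")
      next
    }
    rear[[i]] <- data.frame(
      sequence_id = ids[i], sample_id = sample_id, locus = locus,
      sequence = read, rev_comp = flipped[i],
      v_call = best_v_name, j_call = best_j_name,
      v_identity = best_v$identity, j_identity = best_j$identity,
      v_score = best_v$score, j_score = best_j$score,
      v_read_start = v_read_start, v_germ_start = best_v$germ_start,
      v_germ_end = best_v$germ_end,
      v_mut_start = best_v$mut_start, v_mut_end = best_v$mut_end,
      j_read_off = best_j$offset, j_germ_start = best_j$germ_start,
      j_germ_end = best_j$germ_end,
      stringsAsFactors = FALSE
    )
    if (length(best_v$mut_pos)) {
      gp <- best_v$mut_pos
      muts[[i]] <- data.frame(
        sequence_id = ids[i], germline = best_v_name, pos = gp,
        from = substring(vseqs[[match(best_v_name, vsegs$name)]],
                         gp + 1L, gp + 1L),
        to = substring(read, v_read_start + gp + 1L, v_read_start + gp + 1L),
        stringsAsFactors = FALSE
      )
    }
  }
  empty_rej <- data.frame(sequence_id = character(0), reason = character(0))
  empty_mut <- data.frame(sequence_id = character(0), germline = character(0),
                          pos = integer(0), from = character(0),
                          to = character(0))
  out <- structure(list(
    rearrangements = if (any(!vapply(rear, is.null, TRUE)))
      do.call(rbind, rear) else NULL,
    mutations = if (any(!vapply(muts, is.null, TRUE)))
      do.call(rbind, muts) else empty_mut,
    rejected = if (any(!vapply(rej, is.null, TRUE)))
      do.call(rbind, rej) else empty_rej,
    sample_id = sample_id, locus = locus
  ), class = "ig_repertoire")
  if (is.null(out$rearrangements))
    out$rearrangements <- data.frame(sequence_id = character(0))
  rownames(out$rearrangements) <- NULL
  rownames(out$mutations) <- NULL
  rownames(out$rejected) <- NULL
  out
}

#' @export
print.ig_repertoire <- function(x, ...) {
  cat("ig_repertoire (", x$locus, "): ", nrow(x$rearrangements),
      " assigned, ", nrow(x$rejected), " rejected\n", sep = "")
  invisible(x)
}

#' Run assignment, junction decomposition, CDR3 extraction and
#' productivity in one step
#'
#' @inheritParams assign_repertoire
#' @param p_cap,min_d see [decompose_junctions()].
#' @return a fully annotated `ig_repertoire`.
#' @export
analyze_repertoire <- function(reads, ref, locus = NULL,
                               min_v_identity = 0.70, min_j_identity = 0.80,
                               sample_id = "sample1", p_cap = 4L,
                               min_d = 5L) {
  rep <- assign_repertoire(reads, ref, locus = locus,
                           min_v_identity = min_v_identity,
                           min_j_identity = min_j_identity,
                           sample_id = sample_id)
  if (!nrow(rep$rearrangements)) return(rep)
  rep <- decompose_junctions(rep, ref, p_cap = p_cap, min_d = min_d)
  rep <- extract_cdr3s(rep, ref)
  infer_productivity(rep, ref)
}
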