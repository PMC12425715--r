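## Germline locus annotation: template-guided segment search, RSS
## attachment under the 12/23 rule, IMGT-style functionality calls,
## subgroup clustering, and the germline reference container.

## RSS spacer class expected on each side of a segment, by locus.
## V segments carry one RSS 3' of the coding end, J segments one RSS 5',
## D segments (heavy chain only) a 12-spacer RSS on both sides.
rss_classes_for <- function(locus, seg_type) {
  tab <- list(
    IGH = list(V = c(rss3 = "RSS23"), D = c(rss5 = "RSS12", rss3 = "RSS12"),
               J = c(rss5 = "RSS23"), C = character(0)),
    IGK = list(V = c(rss3 = "RSS12"), J = c(rss5 = "RSS23"), C = character(0)),
    IGL = list(V = c(rss3 = "RSS23"), J = c(rss5 = "RSS12"), C = character(0))
  )
  cls <- tab[[locus]][[seg_type]]
  if (is.null(cls)) stop("segment type ", seg_type,
                         " is not defined for locus ", locus, call. = FALSE)
  cls
}

## ---------------------------------------------------------------------------
## segment location by template search
## ---------------------------------------------------------------------------

#' Locate gene segments in a genomic sequence by template search
#'
#' Scans the genome (both strands) for near-exact, gap-free occurrences of
#' each template at `min_identity` or better, suppresses hits overlapping a
#' higher-scoring hit, and attaches the flanking recombination signal
#' sequence(s) expected for the segment type when one lies within
#' `rss_gap` bp of the coding end.
#'
#' @param genome genome sequence (character or `DNAString`).
#' @param templates named character vector or `DNAStringSet` of template
#'   segment sequences.
#' @param locus `"IGH"`, `"IGK"` or `"IGL"`.
#' @param seg_type `"V"`, `"D"`, `"J"` or `"C"`.
#' @param min_identity minimum fraction identity of a hit (default 0.70,
#'   chosen for cross-species templates).
#' @param rss_gap maximum distance (bp) between the coding end and the RSS
#'   heptamer (default 40).
#' @param heptamer_budget,nonamer_budget,spacer_tolerance RSS scan settings
#'   passed to [find_rss()].
#' @param verbose if `TRUE`, log suppressed overlapping hits.
#' @return a `data.frame` of segments with 0-based half-open genomic
#'   coordinates, strand, identity, score, attached RSS coordinates and
#'   mismatch counts, and a `has_rss` flag.
#' @export
locate_segments <- function(genome, templates, locus, seg_type,
                            min_identity = 0.70, rss_gap = 40L,
                            heptamer_budget = 1L, nonamer_budget = 2L,
                            spacer_tolerance = 1L, verbose = FALSE) {
  stopifnot(min_identity > 0, min_identity <= 1)
  g <- as_dna_string(genome)
  check_dna_alphabet(g)
  tpl <- setNames(vapply(as.character(templates), as_dna_string, "",
                         USE.NAMES = FALSE), names(templates))
  if (is.null(names(tpl)) || any(!nzchar(names(tpl))))
    stop("templates must be named", call. = FALSE)
  gset <- Biostrings::DNAString(g)
  L <- nchar(g)

  hits <- list()
  for (nm in names(tpl)) {
    t_seq <- tpl[[nm]]
    k <- nchar(t_seq)
    mm_max <- floor((1 - min_identity) * k)
    for (str in c("+", "-")) {
      query <- if (str == "+") t_seq else revcomp(t_seq)
      m <- Biostrings::matchPattern(Biostrings::DNAString(query), gset,
                                    max.mismatch = mm_max)
      if (!length(m)) next
      st <- Biostrings::start(m)
      for (i in seq_along(st)) {
        sub <- substr(g, st[i], st[i] + k - 1L)
        mm <- hamming(s2c(sub), s2c(query))
        hits[[length(hits) + 1L]] <- data.frame(
          template = nm, start = st[i] - 1L, end = st[i] - 1L + k,
          strand = str, identity = (k - mm) / k,
          score = 2L * (k - mm) - 2L * mm,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  cols <- c("template", "start", "end", "strand", "identity", "score")
  if (!length(hits)) {
    out <- data.frame(template = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), score = numeric(0))
  } else {
    h <- do.call(rbind, hits)
    ## suppress hits overlapping a higher-scoring hit; ties broken by longer
    ## alignment, then lower start coordinate, then template name
    h <- h[order(-h$score, -(h$end - h$start), h$start, h$template), ]
    keep <- logical(nrow(h))
    occupied <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(h))) {
      ov <- nrow(occupied) > 0 &&
        any(h$start[i] < occupied[, 2] & h$end[i] > occupied[, 1])
      if (!ov) {
        keep[i] <- TRUE
        occupied <- rbind(occupied, c(h$start[i], h$end[i]))
      } else if (verbose) {
        message("suppressed overlapping hit: ", h$template[i], " at [",
                h$start[i], ",", h$end[i], ") score ", h$score[i])
      }
    }
    out <- h[keep, cols]
    out <- out[order(out$start), ]
  }
  rownames(out) <- NULL
  if (nrow(out)) {
    out$locus <- locus
    out$seg_type <- seg_type
    out <- .attach_rss(out, g, locus, seg_type, rss_gap,
                       heptamer_budget, nonamer_budget, spacer_tolerance)
  } else {
    out$locus <- character(0)
    out$seg_type <- character(0)
    for (cc in c("rss5_start", "rss5_spacer", "rss3_start", "rss3_spacer"))
      out[[cc]] <- integer(0)
    out$has_rss <- logical(0)
  }
  out
}

## attach the flanking RSS expected for this segment type, searching within
## `rss_gap` bp of each coding end in the correct orientation
.attach_rss <- function(segs, g, locus, seg_type, rss_gap,
                        heptamer_budget, nonamer_budget, spacer_tolerance) {
  cls <- rss_classes_for(locus, seg_type)
  segs$rss5_start <- NA_integer_; segs$rss5_spacer <- NA_integer_
  segs$rss3_start <- NA_integer_; segs$rss3_spacer <- NA_integer_
  if (!length(cls)) {
    segs$has_rss <- NA
    return(segs)
  }
  scans <- lapply(unique(cls), function(sc)
    find_rss(g, sc, heptamer_budget, nonamer_budget, spacer_tolerance))
  names(scans) <- unique(cls)
  hlen <- nchar(RSS_HEPTAMER)

  for (i in seq_len(nrow(segs))) {
    plus <- segs$strand[i] == "+"
    for (side in names(cls)) {
      rss <- scans[[cls[[side]]]]
      ## a "3' side" RSS reads heptamer-first away from the coding end; on
      ## the genome's forward strand that is a plus-strand motif after the
      ## segment (plus-strand segment) or a minus-strand motif before it
      ## (minus-strand segment). The "5' side" is the mirror image.
      downstream <- (side == "rss3") == plus
      if (downstream) {
        cand <- rss[rss$strand == (if (plus) "+" else "-") &
                    rss$heptamer_start >= segs$end[i] &
                    rss$heptamer_start <= segs$end[i] + rss_gap, , drop = FALSE]
        if (nrow(cand)) cand <- cand[which.min(cand$heptamer_start), ]
      } else {
        cand <- rss[rss$strand == (if (plus) "-" else "+") &
                    rss$heptamer_start + hlen <= segs$start[i] &
                    rss$heptamer_start + hlen >= segs$start[i] - rss_gap,
                    , drop = FALSE]
        if (nrow(cand)) cand <- cand[which.max(cand$heptamer_start), ]
      }
      if (nrow(cand) == 1L) {
        segs[[paste0(side, "_start")]][i] <- cand$heptamer_start
        segs[[paste0(side, "_spacer")]][i] <- cand$spacer_len
      }
    }
  }
  need <- names(cls)
  segs$has_rss <- apply(
    as.matrix(segs[, paste0(need, "_start"), drop = FALSE]), 1L,
    function(x) all(!is.na(x))
  )
  segs
}

#' Nominate D or J candidates purely from RSS pairing
#'
#' Implements the motif-scan route used when no template matches: a short
#' stretch flanked 5' and 3' by correctly oriented RSS motifs of the class
#' expected for the segment type is reported as a candidate segment.
#'
#' @inheritParams locate_segments
#' @param min_len,max_len candidate coding-region length bounds in bp.
#' @return a `data.frame` in the same shape as [locate_segments()] output.
#' @export
nominate_by_rss <- function(genome, locus, seg_type = c("D", "J"),
                            min_len = 8L, max_len = 60L,
                            heptamer_budget = 1L, nonamer_budget = 2L,
                            spacer_tolerance = 1L) {
  seg_type <- match.arg(seg_type)
  g <- as_dna_string(genome)
  cls <- rss_classes_for(locus, seg_type)
  hlen <- nchar(RSS_HEPTAMER)
  out <- list()
  if (seg_type == "D") {
    rss <- find_rss(g, cls[["rss5"]], heptamer_budget, nonamer_budget,
                    spacer_tolerance)
    ## plus-strand D: minus-strand RSS (heptamer abutting the start) then a
    ## plus-strand RSS (heptamer abutting the end)
    left <- rss[rss$strand == "-", , drop = FALSE]
    right <- rss[rss$strand == "+", , drop = FALSE]
    for (i in seq_len(nrow(left))) {
      s <- left$heptamer_start[i] + hlen
      cand <- right[right$heptamer_start >= s + min_len &
                    right$heptamer_start <= s + max_len, , drop = FALSE]
      for (j in seq_len(nrow(cand))) {
        e <- cand$heptamer_start[j]
        out[[length(out) + 1L]] <- data.frame(
          template = NA_character_, start = s, end = e, strand = "+",
          identity = NA_real_, score = NA_real_, locus = locus,
          seg_type = seg_type,
          rss5_start = left$heptamer_start[i], rss5_spacer = left$spacer_len[i],
          rss3_start = e, rss3_spacer = cand$spacer_len[j],
          has_rss = TRUE, stringsAsFactors = FALSE
        )
      }
    }
  } else {
    rss <- find_rss(g, cls[["rss5"]], heptamer_budget, nonamer_budget,
                    spacer_tolerance)
    left <- rss[rss$strand == "-", , drop = FALSE]
    for (i in seq_len(nrow(left))) {
      s <- left$heptamer_start[i] + hlen
      e <- min(nchar(g), s + max_len)
      if (e - s < min_len) next
      out[[length(out) + 1L]] <- data.frame(
        template = NA_character_, start = s, end = e, strand = "+",
        identity = NA_real_, score = NA_real_, locus = locus,
        seg_type = seg_type,
        rss5_start = left$heptamer_start[i], rss5_spacer = left$spacer_len[i],
        rss3_start = NA_integer_, rss3_spacer = NA_integer_,
        has_rss = TRUE, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(locate_segments(paste(rep("A", 0), collapse = ""),
                           c(x = "ACGT"), locus, seg_type)[0, ])
  res <- do.call(rbind, out)
  res[order(res$start), ]
}

## ---------------------------------------------------------------------------
## functionality classification (simplified IMGT decision tree)
## ---------------------------------------------------------------------------

#' Classify a gene segment as functional, ORF or pseudogene
#'
#' A simplified form of the IMGT functionality rules: a segment is a
#' pseudogene when its coding region contains an in-frame stop codon (or a
#' frameshift relative to the template length, when given); it is functional
#' when the frame is intact, the expected RSS is present, and the conserved
#' anchors are found (V: 1st-CYS and 2nd-CYS codons; J: a `[FW]-G-X-G`
#' motif); otherwise it is an ORF. Leader exons and splice sites are not
#' evaluated.
#'
#' @param sequence coding sequence (character), 5'->3'.
#' @param seg_type `"V"`, `"D"`, `"J"` or `"C"`.
#' @param has_rss whether the expected RSS(s) were found within budgets.
#' @param template_length optional template length (bp) used to detect
#'   frameshifts.
#' @return one of `"functional"`, `"ORF"`, `"pseudogene"`.
#' @export
classify_functionality <- function(sequence, seg_type, has_rss,
                                   template_length = NULL) {
  seq <- as_dna_string(sequence)
  if (seg_type == "C") return("functional")
  if (seg_type == "D") return(if (isTRUE(has_rss)) "functional" else "ORF")
  if (seg_type == "V") {
    if (!is.null(template_length) &&
        (nchar(seq) - template_length) %% 3L != 0L) return("pseudogene")
    aa <- translate_dna(seq)
    if (grepl("*", aa, fixed = TRUE)) return("pseudogene")
    n_cod <- nchar(aa)
    aav <- s2c(aa)
    cys1 <- any(aav[seq(15L, min(40L, n_cod))] == "C")
    cys2 <- n_cod >= 8L && any(aav[(n_cod - 7L):n_cod] == "C")
    if (cys1 && cys2 && isTRUE(has_rss)) return("functional")
    return("ORF")
  }
  ## J: examine all three frames; the anchor frame must be open through the
  ## [FW]GXG motif
  frames <- vapply(0:2, function(f) translate_dna(substr(seq, f + 1L,
                                                         nchar(seq))), "")
  anchored <- vapply(frames, function(aa) {
    m <- regexpr("[FW]G.G", aa)
    m > 0 && !grepl("*", substr(aa, 1L, m), fixed = TRUE)
  }, logical(1))
  all_stopped <- all(grepl("*", frames, fixed = TRUE))
  if (all_stopped && !any(anchored)) return("pseudogene")
  if (any(anchored) && isTRUE(has_rss)) return("functional")
  "ORF"
}

## locate the 2nd-CYS codon (V) or the [FW]GXG anchor codon (J).
## Returns the 0-based nucleotide offset of the codon start, or NA.
find_v_cys2 <- function(seq) {
  aa <- translate_dna(seq)
  n <- nchar(aa)
  if (n < 8L) return(NA_integer_)
  aav <- s2c(aa)
  idx <- which(aav == "C")
  idx <- idx[idx >= n - 7L]
  if (!length(idx)) return(NA_integer_)
  as.integer((max(idx) - 1L) * 3L)
}

find_j_anchor <- function(seq) {
  for (f in 0:2) {
    aa <- translate_dna(substr(seq, f + 1L, nchar(seq)))
    m <- regexpr("[FW]G.G", aa)
    if (m > 0) return(as.integer(f + (m - 1L) * 3L))
  }
  NA_integer_
}

## ---------------------------------------------------------------------------
## subgroup clustering
## ---------------------------------------------------------------------------

#' Assign V segments to subgroups by single-linkage identity clustering
#'
#' Two segments share a subgroup when connected by a chain of pairs with
#' global nucleotide identity at or above `identity_threshold` (default
#' 0.75, the conventional subgroup cutoff). Cluster labels are assigned by
#' descending cluster size, ties by the smallest value of `order_by`
#' (typically the genomic start coordinate).
#'
#' @param sequences named character vector (or `DNAStringSet`) of V
#'   sequences.
#' @param identity_threshold clustering threshold in (0, 1).
#' @param order_by optional numeric vector (parallel to `sequences`) used to
#'   break label ties; defaults to input order.
#' @return named integer vector of subgroup labels.
#' @export
assign_subgroups <- function(sequences, identity_threshold = 0.75,
                             order_by = NULL) {
  stopifnot(identity_threshold > 0, identity_threshold < 1)
  seqs <- setNames(vapply(as.character(sequences), as_dna_string, "",
                          USE.NAMES = FALSE), names(sequences))
  n <- length(seqs)
  stopifnot(n >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  if (is.null(order_by)) order_by <- seq_len(n)

  ## k-mer prefilter: pairs sharing almost no 8-mers cannot reach the
  ## identity threshold, so skip their alignment
  kmers <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < 8L) return(character(0))
    unique(substring(s, 1:(L - 7L), 8:L))
  })

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (find(i) == find(j)) next
        shared <- length(intersect(kmers[[i]], kmers[[j]])) /
          max(1L, min(length(kmers[[i]]), length(kmers[[j]])))
        if (shared < 0.03) next
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(seqs[[j]]),
          type = "global")
        if (Biostrings::pid(pa, type = "PID1") / 100 >= identity_threshold)
          union_(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  sizes <- lengths(comp)
  firsts <- vapply(comp, function(ix) min(order_by[ix]), numeric(1))
  ord <- order(-sizes, firsts)
  labels <- integer(n)
  for (k in seq_along(ord)) labels[comp[[ord[k]]]] <- k
  setNames(labels, names(seqs))
}

## ---------------------------------------------------------------------------
## germline reference container
## ---------------------------------------------------------------------------

#' Construct a germline reference
#'
#' Bundles annotated gene segments, their sequences (coding orientation;
#' minus-strand segments are stored reverse-complemented), and per-segment
#' metadata: the 2nd-CYS offset and FR/CDR delimitation for V segments and
#' the `[FW]GXG` anchor offset for J segments (0-based nucleotide offsets
#' within the stored sequence).
#'
#' @param segments `data.frame` with columns `name`, `locus`, `seg_type`,
#'   `start`, `end`, `strand`, `functionality`, `subgroup`, `rss5_spacer`,
#'   `rss3_spacer` (0-based half-open coordinates).
#' @param sequences named character vector or `DNAStringSet`, one per
#'   segment.
#' @param genome_id identifier of the source sequence.
#' @param meta named list of per-segment metadata lists (`cys2`, `anchor`,
#'   `regions`).
#' @return an object of class `germline_reference`.
#' @export
germline_reference <- function(segments, sequences, genome_id = "unknown",
                               meta = list()) {
  seq_names <- names(sequences)
  sequences <- setNames(vapply(as.character(sequences), as_dna_string, "",
                               USE.NAMES = FALSE), seq_names)
  stopifnot(is.data.frame(segments),
            all(c("name", "locus", "seg_type", "start", "end", "strand",
                  "functionality") %in% names(segments)))
  if (!all(segments$name %in% names(sequences)) ||
      anyDuplicated(segments$name))
    stop("every segment name must have exactly one sequence", call. = FALSE)
  sequences <- sequences[segments$name]
  if (any(nchar(sequences) != segments$end - segments$start))
    stop("sequence lengths do not match segment coordinates", call. = FALSE)
  if (!"subgroup" %in% names(segments)) segments$subgroup <- NA_integer_
  if (!"rss5_spacer" %in% names(segments)) segments$rss5_spacer <- NA_integer_
  if (!"rss3_spacer" %in% names(segments)) segments$rss3_spacer <- NA_integer_
  if (!"template" %in% names(segments)) segments$template <- NA_character_
  if (!"identity" %in% names(segments)) segments$identity <- NA_real_
  segments <- segments[, c("name", "locus", "seg_type", "start", "end",
                           "strand", "functionality", "subgroup",
                           "rss5_spacer", "rss3_spacer", "template",
                           "identity")]
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments$subgroup <- as.integer(segments$subgroup)
  segments$rss5_spacer <- as.integer(segments$rss5_spacer)
  segments$rss3_spacer <- as.integer(segments$rss3_spacer)
  structure(list(segments = segments, sequences = sequences,
                 genome_id = genome_id, meta = meta),
            class = "germline_reference")
}

#' @export
print.germline_reference <- function(x, ...) {
  tab <- table(x$segments$locus, x$segments$seg_type)
  cat("germline_reference on", x$genome_id, "with",
      nrow(x$segments), "segments\n")
  print(tab)
  invisible(x)
}

## convenience accessors
ref_segments <- function(ref, seg_type = NULL, functional_only = FALSE) {
  s <- ref$segments
  if (!is.null(seg_type)) s <- s[s$seg_type %in% seg_type, , drop = FALSE]
  if (functional_only)
    s <- s[s$functionality == "functional", , drop = FALSE]
  s
}

ref_seq <- function(ref, name) unname(ref$sequences[[name]])

## ---------------------------------------------------------------------------
## top-level annotation
## ---------------------------------------------------------------------------

#' Annotate an immunoglobulin locus
#'
#' Runs template search for every segment type present in `templates`
#' (headers must encode `locus|type|name`), attaches RSS motifs, classifies
#' functionality, optionally clusters V segments into subgroups, and returns
#' a [germline_reference()].
#'
#' @inheritParams locate_segments
#' @param templates named sequences with names of the form
#'   `"IGH|V|IGHV1-1"`.
#' @param genome_id identifier recorded in the reference and GFF3 output.
#' @param do_subgroups cluster V segments into subgroups (default `TRUE`).
#' @param identity_threshold subgroup clustering threshold.
#' @return a `germline_reference`.
#' @export
annotate_locus <- function(genome, templates, locus,
                           min_identity = 0.70, rss_gap = 40L,
                           heptamer_budget = 1L, nonamer_budget = 2L,
                           spacer_tolerance = 1L, genome_id = "genome",
                           do_subgroups = TRUE, identity_threshold = 0.75,
                           verbose = FALSE) {
  g <- as_dna_string(genome)
  tpl <- setNames(vapply(as.character(templates), as_dna_string, "",
                         USE.NAMES = FALSE), names(templates))
  info <- strsplit(names(tpl), "|", fixed = TRUE)
  if (any(lengths(info) != 3L))
    stop("template names must encode locus|type|name", call. = FALSE)
  t_locus <- vapply(info, `[`, "", 1L)
  t_type <- vapply(info, `[`, "", 2L)
  t_name <- vapply(info, `[`, "", 3L)
  if (!any(t_locus == locus))
    stop("no templates for locus ", locus, call. = FALSE)

  all_segs <- list()
  for (st in intersect(c("V", "D", "J", "C"), unique(t_type[t_locus == locus]))) {
    sel <- t_locus == locus & t_type == st
    tp <- setNames(tpl[sel], t_name[sel])
    segs <- locate_segments(g, tp, locus, st, min_identity = min_identity,
                            rss_gap = rss_gap,
                            heptamer_budget = heptamer_budget,
                            nonamer_budget = nonamer_budget,
                            spacer_tolerance = spacer_tolerance,
                            verbose = verbose)
    if (nrow(segs)) all_segs[[st]] <- segs
  }
  if (!length(all_segs)) stop("no segments located", call. = FALSE)
  segs <- do.call(rbind, all_segs)
  segs <- segs[order(segs$start), ]
  rownames(segs) <- NULL

  ## sequences in coding orientation
  seqs <- vapply(seq_len(nrow(segs)), function(i) {
    s <- substr(g, segs$start[i] + 1L, segs$end[i])
    if (segs$strand[i] == "-") revcomp(s) else s
  }, "")

  ## names: locus + type + ordinal in genomic order within type
  nm <- character(nrow(segs))
  for (st in unique(segs$seg_type)) {
    ix <- which(segs$seg_type == st)
    nm[ix] <- paste0(locus, st, seq_along(ix))
  }
  segs$name <- nm
  names(seqs) <- nm

  segs$functionality <- vapply(seq_len(nrow(segs)), function(i) {
    classify_functionality(seqs[i], segs$seg_type[i], segs$has_rss[i])
  }, "")

  segs$subgroup <- NA_integer_
  v_ix <- which(segs$seg_type == "V")
  if (do_subgroups && length(v_ix) >= 1L) {
    sg <- assign_subgroups(seqs[v_ix], identity_threshold,
                           order_by = segs$start[v_ix])
    segs$subgroup[v_ix] <- unname(sg)
  }

  meta <- list()
  for (i in seq_len(nrow(segs))) {
    m <- list(cys2 = NA_integer_, anchor = NA_integer_, regions = NULL)
    if (segs$seg_type[i] == "V") m$cys2 <- find_v_cys2(seqs[i])
    if (segs$seg_type[i] == "J") m$anchor <- find_j_anchor(seqs[i])
    meta[[segs$name[i]]] <- m
  }

  keep_cols <- c("name", "locus", "seg_type", "start", "end", "strand",
                 "functionality", "subgroup", "rss5_spacer", "rss3_spacer",
                 "template", "identity")
  germline_reference(segs[, keep_cols], seqs, genome_id = genome_id,
                     meta = meta)
}

## ---------------------------------------------------------------------------
## reference I/O: FASTA + GFF3
## ---------------------------------------------------------------------------

.encode_regions <- function(regions) {
  if (is.null(regions) || !nrow(regions)) return(NA_character_)
  paste(sprintf("%s:%d-%d", regions$region, regions$start, regions$end),
        collapse = ",")
}

.decode_regions <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1L]], "[:-]")
  data.frame(region = vapply(parts, `[`, "", 1L),
             start = as.integer(vapply(parts, `[`, "", 2L)),
             end = as.integer(vapply(parts, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Write a germline reference as FASTA + GFF3
#'
#' Writes `<prefix>.fasta` (one record per segment, coding orientation) and
#' `<prefix>.gff3` (feature types `V_gene_segment`, `D_gene_segment`,
#' `J_gene_segment`, `C_gene_segment`; 1-based inclusive coordinates).
#'
#' @param ref a `germline_reference`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_germline <- function(ref, prefix) {
  stopifnot(inherits(ref, "germline_reference"))
  fa <- paste0(prefix, ".fasta")
  gff <- paste0(prefix, ".gff3")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$sequences), fa)
  s <- ref$segments
  meta_chr <- function(field) vapply(s$name, function(nm) {
    v <- ref$meta[[nm]][[field]]
    if (is.null(v) || length(v) == 0L || is.na(v[1L])) NA_character_
    else as.character(v[1L])
  }, "")
  regions_chr <- vapply(s$name, function(nm)
    .encode_regions(ref$meta[[nm]]$regions), "")
  gr <- GenomicRanges::GRanges(
    seqnames = ref$genome_id,
    ranges = IRanges::IRanges(start = s$start + 1L, end = s$end),
    strand = s$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = paste0(s$seg_type, "_gene_segment"),
    ID = s$name, locus = s$locus,
    functionality = s$functionality,
    subgroup = ifelse(is.na(s$subgroup), NA_character_,
                      as.character(s$subgroup)),
    rss_spacer = ifelse(is.na(s$rss5_spacer) & is.na(s$rss3_spacer),
                        NA_character_,
                        paste(s$rss5_spacer, s$rss3_spacer, sep = "/")),
    cys2 = meta_chr("cys2"), anchor = meta_chr("anchor"),
    regions = regions_chr,
    template = s$template,
    identity = ifelse(is.na(s$identity), NA_character_,
                      sprintf("%.17g", s$identity))
  )
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fa, gff3 = gff))
}

#' Read a germline reference written by [write_germline()]
#'
#' @param prefix the path prefix used at write time.
#' @return a `germline_reference`.
#' @export
read_germline <- function(prefix) {
  fa <- paste0(prefix, ".fasta")
  gff <- paste0(prefix, ".gff3")
  seqs <- as.character(Biostrings::readDNAStringSet(fa))
  gr <- rtracklayer::import(gff, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  n <- length(gr)
  ## optional attribute columns are dropped by the writer when all-NA
  opt <- function(col) if (is.null(mc[[col]])) rep(NA_character_, n) else
    as.character(mc[[col]])
  spl <- strsplit(ifelse(is.na(opt("rss_spacer")), "NA/NA",
                         opt("rss_spacer")), "/", fixed = TRUE)
  segs <- data.frame(
    name = mc$ID, locus = opt("locus"),
    seg_type = sub("_gene_segment", "", as.character(mc$type)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    functionality = opt("functionality"),
    subgroup = suppressWarnings(as.integer(opt("subgroup"))),
    rss5_spacer = suppressWarnings(
      as.integer(vapply(spl, `[`, "", 1L))),
    rss3_spacer = suppressWarnings(
      as.integer(vapply(spl, `[`, "", 2L))),
    template = opt("template"),
    identity = suppressWarnings(as.numeric(opt("identity"))),
    stringsAsFactors = FALSE
  )
  cys2 <- opt("cys2"); anchor <- opt("anchor"); regions <- opt("regions")
  meta <- list()
  for (i in seq_len(nrow(segs))) {
    meta[[segs$name[i]]] <- list(
      cys2 = suppressWarnings(as.integer(cys2[i])),
      anchor = suppressWarnings(as.integer(anchor[i])),
      regions = if (!is.na(regions[i])) .decode_regions(regions[i]) else NULL
    )
  }
  germline_reference(segs, seqs,
                     genome_id = as.character(GenomicRanges::seqnames(gr))[1L],
                     meta = meta)
}
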