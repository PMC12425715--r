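## Synthetic V(D)J repertoire generation with full per-read ground truth.
## The generator is the inverse of the analysis: reads are assembled as
## leader + trimmed V + (P,N,P) + D remnant + (P,N,P) + trimmed J + partial
## C (+ primers), then point-mutated with hotspot-multiplied SHM rates and
## uniform sequencing error. A single seed governs all draws in a fixed
## per-read order, so outputs are reproducible byte-for-byte.

STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_pool <- function() {
  all <- as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                         DNA_BASES, paste0))
  setdiff(all, STOP_CODONS)
}

.random_codons <- function(n) {
  paste(sample(.codon_pool(), n, replace = TRUE), collapse = "")
}

.random_dna <- function(n, weights = NULL) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE, prob = weights), collapse = "")
}

.mutate_seq <- function(seq, rate) {
  s <- s2c(seq)
  hit <- which(runif(length(s)) < rate)
  for (i in hit) s[i] <- sample(setdiff(DNA_BASES, s[i]), 1L)
  c2s(s)
}

## ---------------------------------------------------------------------------
## toy segment builders (97 codons + a 10 bp CDR3 tail for V; J with a
## single [FW]GXG anchor; D segments include a (YG)n-motif element)
## ---------------------------------------------------------------------------

TOY_V_REGIONS <- data.frame(
  region = c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
  start = c(0L, 75L, 99L, 150L, 174L),
  end = c(75L, 99L, 150L, 174L, 291L)
)
TOY_V_CYS2 <- 288L   # 0-based start of the 2nd-CYS codon (codon 97)
TOY_J_ANCHOR <- 15L  # 0-based start of the [FW]GXG anchor codon

.toy_v_seq <- function() {
  v <- .random_codons(97L)
  substr(v, 64L, 66L) <- "TGC"    # 1st-CYS, codon 22
  substr(v, 289L, 291L) <- "TGT"  # 2nd-CYS, codon 97
  ## short germline CDR3 contribution, kept free of in-frame stops
  paste0(v, "GCGAGA", .random_codons(1L), .random_dna(1L))
}

.toy_j_seq <- function(locus) {
  ## only the [FW]-G-X-G anchor is conserved between J segments (as in the
  ## germline J repertoire, where the anchor and a short C-proximal motif
  ## are the conserved parts); everything else is segment-specific
  anchor_codon <- if (locus == "IGH") "TGG" else "TTT"
  gly <- c("GGT", "GGC", "GGA", "GGG")
  repeat {
    anchor_block <- paste0(anchor_codon, sample(gly, 1L),
                           .random_codons(1L), sample(gly, 1L),
                           .random_codons(7L))
    ## stop-free 5' region in the anchor frame, as in functional germline J
    j <- paste0(.random_codons(5L), anchor_block)
    ## require a unique [FW]GXG motif across all frames
    hits <- 0L
    for (f in 0:2) {
      aa <- translate_dna(substr(j, f + 1L, nchar(j)))
      g <- gregexpr("(?=[FW]G.G)", aa, perl = TRUE)[[1L]]
      hits <- hits + sum(g > 0)
    }
    if (hits == 1L && identical(find_j_anchor(j), TOY_J_ANCHOR)) return(j)
  }
}

.toy_d_seqs <- function(n) {
  ## the second D carries the (YG)n-style motif characteristic of bovid
  ## D segments (SYYSGYGYAYGY); the fourth (when present) a shorter one
  fixed <- list(NULL, "AGCTATTATAGCGGTTATGGCTATGCCTATGGTTAT", NULL,
                "AGCTATTATAGCGATTATGGATAT")
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (i <= length(fixed) && !is.null(fixed[[i]]))
      fixed[[i]] else .random_dna(sample(14:24, 1L))
  }
  out
}

## ---------------------------------------------------------------------------
## toy locus: genome + truth reference + templates
## ---------------------------------------------------------------------------

#' Build a synthetic immunoglobulin locus with a known answer
#'
#' Generates anchor-correct V (1st/2nd-CYS, FR/CDR delimitation),
#' D (RSS12 pair), J ([FW]GXG anchor) and C segments, assembles them into a
#' genomic sequence with correctly oriented RSS motifs and random spacers,
#' and returns the genome, the ground-truth reference, and a template set
#' (optionally diverged, emulating cross-species templates). V segments can
#' be planted as functional, ORF (RSS omitted) or pseudogene (in-frame stop
#' codon).
#'
#' @param seed RNG seed.
#' @param locus `"IGH"`, `"IGK"` or `"IGL"`.
#' @param n_v,n_d,n_j,n_c segment counts (`n_d` is ignored for light
#'   chains).
#' @param v_functionality optional character vector (length `n_v`) over
#'   `{"functional","ORF","pseudogene"}`; default all functional.
#' @param spacer intersegment spacer length in bp (default 300).
#' @param template_divergence per-base substitution rate applied to the
#'   templates relative to the planted segments (default 0).
#' @return a list with `genome` (character), `reference`
#'   (a [germline_reference()] of the planted truth), and `templates`
#'   (named character vector, `locus|type|name` headers).
#' @export
make_toy_locus <- function(seed, locus = c("IGH", "IGK", "IGL"),
                           n_v = 4L, n_d = 4L, n_j = 2L, n_c = 1L,
                           v_functionality = NULL, spacer = 300L,
                           template_divergence = 0) {
  locus <- match.arg(locus)
  set.seed(seed)
  if (locus != "IGH") n_d <- 0L
  if (is.null(v_functionality)) v_functionality <- rep("functional", n_v)
  stopifnot(length(v_functionality) == n_v)

  rss_block <- function(class) {
    sp <- rss_spacer_length(class)
    paste0(RSS_HEPTAMER, .random_dna(sp), RSS_NONAMER)
  }
  v_rss_class <- rss_classes_for(locus, "V")[["rss3"]]
  j_rss_class <- rss_classes_for(locus, "J")[["rss5"]]

  segs <- list()
  seqs <- character(0)
  meta <- list()
  genome <- .random_dna(spacer)
  add_segment <- function(name, seg_type, seq, functionality, block5 = "",
                          block3 = "", rss5_spacer = NA_integer_,
                          rss3_spacer = NA_integer_, m = NULL) {
    genome <<- paste0(genome, block5)
    start <- nchar(genome)
    genome <<- paste0(genome, seq, block3, .random_dna(spacer))
    segs[[length(segs) + 1L]] <<- data.frame(
      name = name, locus = locus, seg_type = seg_type,
      start = start, end = start + nchar(seq), strand = "+",
      functionality = functionality, subgroup = NA_integer_,
      rss5_spacer = rss5_spacer, rss3_spacer = rss3_spacer,
      stringsAsFactors = FALSE)
    seqs[name] <<- seq
    meta[[name]] <<- if (is.null(m))
      list(cys2 = NA_integer_, anchor = NA_integer_, regions = NULL) else m
  }

  for (i in seq_len(n_v)) {
    v <- .toy_v_seq()
    fun <- v_functionality[i]
    if (fun == "pseudogene") substr(v, 133L, 135L) <- "TAA"  # mid-FR2 stop
    has_rss <- fun != "ORF"
    add_segment(paste0(locus, "V1S", i), "V", v, fun,
                block3 = if (has_rss) rss_block(v_rss_class) else "",
                rss3_spacer = if (has_rss) rss_spacer_length(v_rss_class)
                  else NA_integer_,
                m = list(cys2 = TOY_V_CYS2, anchor = NA_integer_,
                         regions = TOY_V_REGIONS))
  }
  if (n_d > 0L) {
    dseqs <- .toy_d_seqs(n_d)
    for (i in seq_len(n_d)) {
      add_segment(paste0(locus, "D", i), "D", dseqs[i], "functional",
                  block5 = revcomp(rss_block("RSS12")),
                  block3 = rss_block("RSS12"),
                  rss5_spacer = 12L, rss3_spacer = 12L)
    }
  }
  for (i in seq_len(n_j)) {
    j <- .toy_j_seq(locus)
    add_segment(paste0(locus, "J", i), "J", j, "functional",
                block5 = revcomp(rss_block(j_rss_class)),
                rss5_spacer = rss_spacer_length(j_rss_class),
                m = list(cys2 = NA_integer_, anchor = TOY_J_ANCHOR,
                         regions = NULL))
  }
  for (i in seq_len(n_c)) {
    add_segment(paste0(locus, "C", i), "C", .random_codons(50L),
                "functional")
  }

  segdf <- do.call(rbind, segs)
  ref <- germline_reference(segdf, seqs,
                            genome_id = paste0("toy_", locus), meta = meta)
  tpl <- seqs
  if (template_divergence > 0)
    tpl <- vapply(tpl, .mutate_seq, "", rate = template_divergence)
  names(tpl) <- paste(locus, segdf$seg_type, segdf$name, sep = "|")
  list(genome = genome, reference = ref, templates = tpl)
}

#' Build a toy expressed germline reference
#'
#' Convenience wrapper around [make_toy_locus()] returning only the
#' reference, with all segments functional and anchor metadata attached --
#' the default counts (4 V, 4 D, 2 J for the heavy chain) mirror the
#' numbers of gene segments observed to participate in heavy-chain
#' rearrangement.
#'
#' @param seed RNG seed.
#' @param locus `"IGH"`, `"IGK"` or `"IGL"`.
#' @param counts named integer vector with elements `v`, `d`, `j`, `c`.
#' @return a `germline_reference`.
#' @export
make_toy_germline <- function(seed, locus = c("IGH", "IGK", "IGL"),
                              counts = NULL) {
  locus <- match.arg(locus)
  if (is.null(counts))
    counts <- if (locus == "IGH") c(v = 4L, d = 4L, j = 2L, c = 1L)
      else c(v = 5L, d = 0L, j = 3L, c = 1L)
  make_toy_locus(seed, locus, n_v = counts[["v"]],
                 n_d = if ("d" %in% names(counts)) counts[["d"]] else 0L,
                 n_j = counts[["j"]],
                 n_c = if ("c" %in% names(counts)) counts[["c"]] else 1L
                 )$reference
}

## ---------------------------------------------------------------------------
## simulation configuration
## ---------------------------------------------------------------------------

GSP_PRIMERS <- c(IGH = "ACACCAGGGGGAAGACTCTCGGG",
                 IGK = "GAAGAGGAAGACGGATGGCT",
                 IGL = "GTGACCGAGGGTGCGGACTTG")
UPM_PRIMER <- "AAGCAGTGGTATCAACGCAGAGT"

#' Simulation configuration
#'
#' Generative parameters of the synthetic repertoire. Defaults emulate the
#' measured structure of the sheep heavy-chain repertoire: strongly skewed
#' V/D/J usage, short geometric end deletions (3'V deletions mostly 0-4 bp,
#' 5'J deletions within 0-12 bp), short P tracts, transition-biased SHM
#' with A-to-G dominant and T-to-A rarest, and a five-fold AID hotspot rate
#' multiplier.
#'
#' @param seed integer seed governing every draw.
#' @param n_reads number of reads to generate.
#' @param locus target locus.
#' @param v_usage,d_usage,j_usage usage weights (recycled against the
#'   reference at simulation time; `NULL` selects locus-appropriate
#'   defaults when the segment counts match, otherwise uniform weights).
#' @param v3_del,d5_del,d3_del,j5_del lists `list(p=, max=)`: truncated
#'   geometric deletion laws per end.
#' @param p_prob probability that an undeleted end receives a P tract.
#' @param p_len_weights weights over P lengths 1-4 bp.
#' @param n_len list `list(p=, max=)`: truncated geometric N-length law.
#' @param n_base_weights N-nucleotide composition weights (A,C,G,T).
#' @param shm_rate per-base substitution probability on the V region.
#' @param shm_target_weights per-source-base target weights (12-type
#'   spectrum, conditional form).
#' @param hotspot_multiplier SHM rate multiplier at WRCY-C/RGYW-G
#'   positions.
#' @param seq_error_rate per-base sequencing error over the whole read.
#' @param fwd_primer,rev_primer amplification primers (`NULL` rev_primer
#'   selects the locus-specific constant-region primer).
#' @param fraction_missing_primer fraction of reads emitted without the
#'   forward primer.
#' @param leader_len_range min/max leader length in bp.
#' @param c_len length of the constant-region stub appended after J.
#' @param min_d_match,p_cap,min_anchor decomposition settings used when
#'   flagging ambiguous junctions (kept equal to the analysis defaults).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_reads = 1000L,
                              locus = c("IGH", "IGK", "IGL"),
                              v_usage = NULL, d_usage = NULL, j_usage = NULL,
                              v3_del = list(p = 0.35, max = 32L),
                              d5_del = list(p = 0.40, max = 10L),
                              d3_del = list(p = 0.40, max = 10L),
                              j5_del = list(p = 0.25, max = 12L),
                              p_prob = 0.35,
                              p_len_weights = c(0.55, 0.30, 0.10, 0.05),
                              n_len = list(p = 0.30, max = 34L),
                              n_base_weights = c(1, 1, 1, 1),
                              shm_rate = 0.02,
                              shm_target_weights = list(
                                A = c(C = 0.15, G = 0.60, T = 0.25),
                                C = c(A = 0.10, G = 0.25, T = 0.65),
                                G = c(A = 0.55, C = 0.20, T = 0.25),
                                T = c(A = 0.08, C = 0.52, G = 0.40)),
                              hotspot_multiplier = 5,
                              seq_error_rate = 0.001,
                              fwd_primer = UPM_PRIMER, rev_primer = NULL,
                              fraction_missing_primer = 0,
                              leader_len_range = c(40L, 60L),
                              c_len = 120L, min_d_match = 5L, p_cap = 4L,
                              min_anchor = 8L) {
  locus <- match.arg(locus)
  if (is.null(rev_primer)) rev_primer <- unname(GSP_PRIMERS[locus])
  cfg <- list(seed = as.integer(seed), n_reads = as.integer(n_reads),
              locus = locus, v_usage = v_usage, d_usage = d_usage,
              j_usage = j_usage, v3_del = v3_del, d5_del = d5_del,
              d3_del = d3_del, j5_del = j5_del, p_prob = p_prob,
              p_len_weights = p_len_weights, n_len = n_len,
              n_base_weights = n_base_weights, shm_rate = shm_rate,
              shm_target_weights = shm_target_weights,
              hotspot_multiplier = hotspot_multiplier,
              seq_error_rate = seq_error_rate, fwd_primer = fwd_primer,
              rev_primer = rev_primer,
              fraction_missing_primer = fraction_missing_primer,
              leader_len_range = as.integer(leader_len_range),
              c_len = as.integer(c_len), min_d_match = as.integer(min_d_match),
              p_cap = as.integer(p_cap), min_anchor = as.integer(min_anchor))
  probs <- c(cfg$p_prob, cfg$shm_rate, cfg$seq_error_rate,
             cfg$fraction_missing_primer, cfg$v3_del$p, cfg$j5_del$p,
             cfg$n_len$p)
  stopifnot(all(probs >= 0 & probs <= 1), cfg$n_reads >= 0,
            cfg$hotspot_multiplier > 0)
  structure(cfg, class = "simulation_config")
}

.default_usage <- function(locus, type, n) {
  tab <- list(
    IGH = list(V = c(0.581, 0.126, 0.292, 0.001),
               D = c(0.15, 0.55, 0.15, 0.15),
               J = c(0.883, 0.117)),
    IGK = list(V = c(0.545, 0.433, 0.015, 0.005, 0.002),
               J = c(0.621, 0.002, 0.377)),
    IGL = list(V = NULL, J = c(0.005, 0.995))
  )
  w <- tab[[locus]][[type]]
  if (is.null(w) || length(w) != n) w <- rep(1, n)
  w / sum(w)
}

## ---------------------------------------------------------------------------
## the generator
## ---------------------------------------------------------------------------

#' Simulate a rearranged-amplicon repertoire with ground truth
#'
#' Builds each read as forward primer (optionally omitted) + random leader
#' + trimmed V + junction inserts + D remnant (heavy chain) + trimmed J +
#' constant-region stub + reverse-complemented reverse primer; applies SHM
#' to the V region with hotspot-multiplied per-base rates, then uniform
#' sequencing error to the whole read. Every generative choice is recorded
#' in the truth table; a junction is flagged ambiguous when the exhaustive
#' minimal-N decomposer does not return the generated decomposition as its
#' unique optimum.
#'
#' @param config a [simulation_config()].
#' @param ref a `germline_reference` with at least one functional segment
#'   per required type (V/J, plus D and C for the heavy chain).
#' @return a list: `reads` (named `DNAStringSet`) and `truth`
#'   (`data.frame`, one row per read).
#' @export
simulate_repertoire <- function(config, ref) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(ref, "germline_reference"))
  locus <- config$locus
  vsegs <- ref_segments(ref, "V", functional_only = TRUE)
  jsegs <- ref_segments(ref, "J", functional_only = TRUE)
  vsegs <- vsegs[vsegs$locus == locus, ]
  jsegs <- jsegs[jsegs$locus == locus, ]
  heavy <- locus == "IGH"
  dsegs <- if (heavy) {
    d <- ref_segments(ref, "D", functional_only = TRUE)
    d[d$locus == locus, ]
  } else NULL
  csegs <- ref_segments(ref, "C")
  csegs <- csegs[csegs$locus == locus, ]
  stopifnot(nrow(vsegs) >= 1L, nrow(jsegs) >= 1L,
            !heavy || nrow(dsegs) >= 1L)
  c_stub <- if (nrow(csegs)) substr(ref_seq(ref, csegs$name[1L]), 1L,
                                    config$c_len) else ""

  vw <- config$v_usage
  if (is.null(vw)) vw <- .default_usage(locus, "V", nrow(vsegs))
  stopifnot(length(vw) == nrow(vsegs))
  jw <- config$j_usage
  if (is.null(jw)) jw <- .default_usage(locus, "J", nrow(jsegs))
  stopifnot(length(jw) == nrow(jsegs))
  if (heavy) {
    dw <- config$d_usage
    if (is.null(dw)) dw <- .default_usage(locus, "D", nrow(dsegs))
    stopifnot(length(dw) == nrow(dsegs))
  }
  nbw <- config$n_base_weights / sum(config$n_base_weights)

  ## hotspot-aware per-position SHM rate for each V, from its germline mask
  v_rates <- lapply(vsegs$name, function(nm) {
    mask <- hotspot_mask(ref_seq(ref, nm))
    r <- rep(config$shm_rate, length(mask))
    r[mask != "none"] <- pmin(0.9, r[mask != "none"] *
                                config$hotspot_multiplier)
    r
  })
  names(v_rates) <- vsegs$name
  v_masks <- lapply(vsegs$name, function(nm) hotspot_mask(ref_seq(ref, nm)))
  names(v_masks) <- vsegs$name
  dseq_list <- if (heavy) as.list(ref$sequences[dsegs$name]) else NULL

  set.seed(config$seed)
  n <- config$n_reads
  reads <- character(n)
  rows <- vector("list", n)
  draw_p <- function(end_seq, side) {
    if (runif(1L) >= config$p_prob) return("")
    k <- sample(seq_along(config$p_len_weights), 1L,
                prob = config$p_len_weights)
    k <- min(k, nchar(end_seq))
    if (side == "after")
      revcomp(substr(end_seq, nchar(end_seq) - k + 1L, nchar(end_seq)))
    else
      revcomp(substr(end_seq, 1L, k))
  }
  draw_n <- function() {
    k <- rgeom_trunc(1L, config$n_len$p, config$n_len$max)
    .random_dna(k, nbw)
  }

  for (i in seq_len(n)) {
    vi <- sample.int(nrow(vsegs), 1L, prob = vw)
    ji <- sample.int(nrow(jsegs), 1L, prob = jw)
    v_name <- vsegs$name[vi]; j_name <- jsegs$name[ji]
    vseq <- ref_seq(ref, v_name); jseq <- ref_seq(ref, j_name)
    Lv <- nchar(vseq); Lj <- nchar(jseq)

    v3 <- rgeom_trunc(1L, config$v3_del$p, min(config$v3_del$max, Lv - 60L))
    j5 <- rgeom_trunc(1L, config$j5_del$p, min(config$j5_del$max, Lj - 20L))
    v_ret <- substr(vseq, 1L, Lv - v3)
    j_ret <- substr(jseq, j5 + 1L, Lj)

    if (heavy) {
      di <- sample.int(nrow(dsegs), 1L, prob = dw)
      d_name <- dsegs$name[di]
      dseq <- ref_seq(ref, d_name); Ld <- nchar(dseq)
      d5 <- rgeom_trunc(1L, config$d5_del$p, min(config$d5_del$max, Ld - 1L))
      d3 <- rgeom_trunc(1L, config$d3_del$p,
                        min(config$d3_del$max, Ld - d5 - 1L))
      d_ret <- substr(dseq, d5 + 1L, Ld - d3)
      p1 <- if (v3 == 0L) draw_p(v_ret, "after") else ""
      p2 <- if (d5 == 0L) draw_p(d_ret, "before") else ""
      n1 <- draw_n()
      p3 <- if (d3 == 0L) draw_p(d_ret, "after") else ""
      p4 <- if (j5 == 0L) draw_p(j_ret, "before") else ""
      n2 <- draw_n()
      insert1 <- paste0(p1, n1, p2)
      insert2 <- paste0(p3, n2, p4)
      core <- paste0(v_ret, insert1, d_ret, insert2, j_ret)
    } else {
      d_name <- NA_character_; d5 <- d3 <- NA_integer_; d_ret <- ""
      p1 <- if (v3 == 0L) draw_p(v_ret, "after") else ""
      p2 <- if (j5 == 0L) draw_p(j_ret, "before") else ""
      n1 <- draw_n()
      p3 <- p4 <- n2 <- ""
      insert1 <- paste0(p1, n1, p2)
      insert2 <- ""
      core <- paste0(v_ret, insert1, j_ret)
    }

    has_fwd <- runif(1L) >= config$fraction_missing_primer
    leader_len <- sample(config$leader_len_range[1L]:
                           config$leader_len_range[2L], 1L)
    leader <- .random_dna(leader_len)
    prefix <- paste0(if (has_fwd) config$fwd_primer else "", leader)
    clean_read <- paste0(prefix, core, c_stub, revcomp(config$rev_primer))
    v_read_start <- nchar(prefix)
    j_read_off <- v_read_start + nchar(v_ret) + nchar(insert1) +
      nchar(d_ret) + nchar(insert2) - j5

    ## SHM on the retained V region (hotspot-multiplied per-position rates)
    rates <- v_rates[[v_name]][seq_len(nchar(v_ret))]
    u <- runif(length(rates))
    mut_pos <- which(u < rates)   # 1-based germline positions
    mut_from <- if (length(mut_pos)) substring(vseq, mut_pos, mut_pos)
      else character(0)
    mut_to <- vapply(mut_from, function(b) {
      w <- config$shm_target_weights[[b]]
      sample(names(w), 1L, prob = w)
    }, "")
    read <- clean_read
    if (length(mut_pos)) {
      rp <- v_read_start + mut_pos  # 1-based read positions
      sv <- s2c(read)
      sv[rp] <- mut_to
      read <- c2s(sv)
    }
    mut_hot <- v_masks[[v_name]][mut_pos] != "none"

    ## uniform sequencing error across the read
    sv <- s2c(read)
    err_pos <- which(runif(length(sv)) < config$seq_error_rate)
    err_from <- sv[err_pos]
    err_to <- vapply(err_from, function(b)
      sample(setdiff(DNA_BASES, b), 1L), "")
    if (length(err_pos)) {
      sv[err_pos] <- err_to
      read <- c2s(sv)
    }

    ## truth productivity/CDR3 from the final read via the true coordinates
    cys2 <- ref$meta[[v_name]]$cys2
    anchor <- ref$meta[[j_name]]$anchor
    anc_read <- j_read_off + anchor
    cys_read <- v_read_start + cys2
    cdr3_len <- NA_integer_
    productive <- FALSE
    if (!is.na(cys2) && !is.na(anchor) && nchar(v_ret) >= cys2 + 3L &&
        j5 <= anchor) {
      cys_aa <- translate_dna(substr(read, cys_read + 1L, cys_read + 3L))
      anc_aa <- translate_dna(substr(read, anc_read + 1L, anc_read + 3L))
      if (cys_aa == "C" && anc_aa %in% c("F", "W"))
        cdr3_len <- anc_read - cys_read - 3L
    }
    if (!is.na(anchor) && (anc_read - v_read_start) %% 3L == 0L) {
      aa <- translate_dna(substr(read, v_read_start + 1L, anc_read + 3L))
      productive <- !grepl("*", aa, fixed = TRUE)
    }

    ## ambiguity: the exhaustive minimal-N decomposer must return exactly
    ## the generated decomposition (checked on the pre-mutation read)
    cls <- enumerate_decompositions(
      clean_read, vseq, v_read_start, jseq, j_read_off,
      dseqs = if (heavy) dseq_list else NULL,
      min_anchor = config$min_anchor, p_cap = config$p_cap,
      min_d = config$min_d_match)
    truth_matches <- function(dec) {
      ok <- dec$v3_del == v3 && dec$j5_del == j5 &&
        nchar(dec$p1) == nchar(p1) && nchar(dec$n1) == nchar(n1)
      if (!ok) return(FALSE)
      if (heavy) {
        identical(dec$d_call, d_name) &&
          !is.na(dec$d5_del) && dec$d5_del == d5 && dec$d3_del == d3 &&
          nchar(dec$p2) == nchar(p2) && nchar(dec$p3) == nchar(p3) &&
          nchar(dec$n2) == nchar(n2) && nchar(dec$p4) == nchar(p4)
      } else {
        nchar(dec$p2) == nchar(p2)
      }
    }
    ambiguous <- !(length(cls) == 1L && truth_matches(cls[[1L]]))

    id <- sprintf("sim_%s_%05d", locus, i)
    reads[i] <- read
    names(reads)[i] <- id
    rows[[i]] <- data.frame(
      read_id = id, locus = locus, v_call = v_name, d_call = d_name,
      j_call = j_name, v3_del = v3, d5_del = d5, d3_del = d3, j5_del = j5,
      p1 = p1, n1 = n1, p2 = p2, p3 = p3, n2 = n2, p4 = p4,
      np1_length = nchar(insert1),
      np2_length = if (heavy) nchar(insert2) else NA_integer_,
      d_length = if (heavy) nchar(d_ret) else NA_integer_,
      leader = leader, has_fwd_primer = has_fwd,
      v_read_start = v_read_start, j_read_off = j_read_off,
      mutations = paste(sprintf("%d:%s>%s", mut_pos - 1L, mut_from, mut_to),
                        collapse = "|"),
      n_mutations = length(mut_pos),
      n_hotspot_mutations = sum(mut_hot),
      seq_errors = paste(sprintf("%d:%s>%s", err_pos - 1L, err_from, err_to),
                         collapse = "|"),
      n_seq_errors = length(err_pos),
      productive = productive, cdr3_length = cdr3_len,
      ambiguous_junction = ambiguous,
      read_length = nchar(read),
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, rows)
  list(reads = Biostrings::DNAStringSet(reads), truth = truth)
}

#' Rebuild a simulated read from its truth record
#'
#' Reconstructs the emitted read byte-for-byte from the germline reference,
#' the recorded deletions, P/N tracts, leader, mutation list and sequencing
#' errors -- the generator's defining invariant.
#'
#' @param truth_row one row of the truth table.
#' @param ref the `germline_reference` used for simulation.
#' @param config the `simulation_config` used.
#' @return the read as a character string.
#' @export
reconstruct_read <- function(truth_row, ref, config) {
  tr <- as.list(truth_row)
  vseq <- ref_seq(ref, tr$v_call)
  jseq <- ref_seq(ref, tr$j_call)
  v_ret <- substr(vseq, 1L, nchar(vseq) - tr$v3_del)
  j_ret <- substr(jseq, tr$j5_del + 1L, nchar(jseq))
  heavy <- tr$locus == "IGH"
  d_ret <- if (heavy && !is.na(tr$d_call)) {
    dseq <- ref_seq(ref, tr$d_call)
    substr(dseq, tr$d5_del + 1L, nchar(dseq) - tr$d3_del)
  } else ""
  ## apply SHM to the retained V
  if (nzchar(tr$mutations)) {
    sv <- s2c(v_ret)
    for (m in strsplit(tr$mutations, "|", fixed = TRUE)[[1L]]) {
      parts <- strsplit(m, "[:>]")[[1L]]
      sv[as.integer(parts[1L]) + 1L] <- parts[3L]
    }
    v_ret <- c2s(sv)
  }
  core <- paste0(v_ret, tr$p1, tr$n1, tr$p2, d_ret, tr$p3, tr$n2, tr$p4,
                 j_ret)
  csegs <- ref_segments(ref, "C")
  csegs <- csegs[csegs$locus == tr$locus, ]
  c_stub <- if (nrow(csegs)) substr(ref_seq(ref, csegs$name[1L]), 1L,
                                    config$c_len) else ""
  read <- paste0(if (tr$has_fwd_primer) config$fwd_primer else "",
                 tr$leader, core, c_stub, revcomp(config$rev_primer))
  if (nzchar(tr$seq_errors)) {
    sv <- s2c(read)
    for (m in strsplit(tr$seq_errors, "|", fixed = TRUE)[[1L]]) {
      parts <- strsplit(m, "[:>]")[[1L]]
      sv[as.integer(parts[1L]) + 1L] <- parts[3L]
    }
    read <- c2s(sv)
  }
  read
}
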