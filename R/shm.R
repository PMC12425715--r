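## Somatic hypermutation analysis against the germline V: overall
## frequency, the 12-type substitution spectrum, per-position maps with
## FR/CDR labels, and mutation counts inside the AID hotspot motifs
## WRCY (targeting the C) and RGYW (its reverse complement, targeting
## the G). Only substitutions are counted; the aligned V interval defines
## the denominator.

SUBSTITUTION_TYPES <- {
  x <- expand.grid(to = DNA_BASES, from = DNA_BASES,
                   stringsAsFactors = FALSE)
  x <- x[x$from != x$to, c("from", "to")]
  paste0(x$from, ">", x$to)
}

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' AID hotspot mask of a germline sequence
#'
#' Flags every C that sits at position 3 of a WRCY motif and every G at
#' position 2 of an RGYW motif (W = A/T, R = A/G, Y = C/T). A base matching
#' both contexts is flagged `"both"`.
#'
#' @param seq germline DNA (character).
#' @return character vector (one entry per position) over
#'   `{"WRCY", "RGYW", "both", "none"}`.
#' @examples
#' hotspot_mask("AGCT")  # C is a WRCY hotspot, G an RGYW hotspot
#' @export
hotspot_mask <- function(seq) {
  s <- s2c(as_dna_string(seq))
  L <- length(s)
  in_set <- function(i, code) i >= 1L && i <= L && s[i] %in% IUPAC_SETS[[code]]
  mask <- rep("none", L)
  for (i in seq_len(L)) {
    wrcy <- s[i] == "C" && in_set(i - 2L, "W") && in_set(i - 1L, "R") &&
      in_set(i + 1L, "Y")
    rgyw <- s[i] == "G" && in_set(i - 1L, "R") && in_set(i + 1L, "Y") &&
      in_set(i + 2L, "W")
    if (wrcy && rgyw) mask[i] <- "both"
    else if (wrcy) mask[i] <- "WRCY"
    else if (rgyw) mask[i] <- "RGYW"
  }
  mask
}

#' Somatic hypermutation frequency
#'
#' The mutation frequency as a percentage:
#' `100 * mutated_bases / total_bases`.
#'
#' @param mutated_bases number of mutated bases.
#' @param total_bases total sequenced (aligned) bases; must be positive.
#' @return percentage.
#' @export
shm_frequency <- function(mutated_bases, total_bases) {
  stopifnot(mutated_bases >= 0, mutated_bases <= total_bases)
  if (total_bases <= 0)
    stop("total_bases must be positive", call. = FALSE)
  100 * mutated_bases / total_bases
}

#' Build per-germline mutation profiles from an assigned repertoire
#'
#' Tallies, for every germline V, the per-position substitution counts by
#' type, the per-position aligned-read coverage, the FR/CDR region label
#' (when the reference carries a delimitation), and the AID hotspot mask.
#'
#' @param rep an `ig_repertoire` (after [assign_repertoire()]).
#' @param ref the `germline_reference`.
#' @param collapse_identical_junctions optionally deduplicate reads by
#'   identical junction before tallying (default `FALSE`; the repertoire
#'   frequencies in this package are computed without duplicate removal).
#' @return a list of class `mutation_profile_list`; each element has
#'   `germline`, `length`, `counts` (12 x L matrix), `coverage`,
#'   `regions`, `hotspot`.
#' @export
mutation_profiles <- function(rep, ref, collapse_identical_junctions = FALSE) {
  stopifnot(inherits(rep, "ig_repertoire"))
  rr <- rep$rearrangements
  muts <- rep$mutations
  if (collapse_identical_junctions && "junction" %in% names(rr)) {
    keep <- !duplicated(paste(rr$v_call, rr$j_call, rr$junction))
    rr <- rr[keep, , drop = FALSE]
    muts <- muts[muts$sequence_id %in% rr$sequence_id, , drop = FALSE]
  }
  profiles <- list()
  for (vname in sort(unique(rr$v_call[!is.na(rr$v_call)]))) {
    vseq <- ref_seq(ref, vname)
    L <- nchar(vseq)
    counts <- matrix(0L, nrow = length(SUBSTITUTION_TYPES), ncol = L,
                     dimnames = list(SUBSTITUTION_TYPES, NULL))
    coverage <- integer(L)
    sel <- which(rr$v_call == vname)
    for (i in sel) {
      ## the mutation-scoring interval recorded at assignment time defines
      ## both the numerator and the denominator
      gs <- if (!is.null(rr$v_mut_start)) rr$v_mut_start[i] else
        rr$v_germ_start[i]
      ge <- if (!is.null(rr$v_mut_end)) rr$v_mut_end[i] else
        rr$v_germ_end[i]
      ge <- min(ge, L)
      if (ge > gs) coverage[(gs + 1L):ge] <- coverage[(gs + 1L):ge] + 1L
    }
    m <- muts[muts$germline == vname &
                muts$sequence_id %in% rr$sequence_id[sel], , drop = FALSE]
    if (nrow(m)) {
      keys <- paste0(m$from, ">", m$to)
      ok <- keys %in% SUBSTITUTION_TYPES & m$pos < L
      for (j in which(ok)) {
        counts[keys[j], m$pos[j] + 1L] <- counts[keys[j], m$pos[j] + 1L] + 1L
      }
    }
    meta <- ref$meta[[vname]]
    regions <- rep(NA_character_, L)
    if (!is.null(meta$regions) && nrow(meta$regions)) {
      for (k in seq_len(nrow(meta$regions))) {
        a <- meta$regions$start[k] + 1L
        b <- min(meta$regions$end[k], L)
        if (b >= a) regions[a:b] <- meta$regions$region[k]
      }
    }
    profiles[[vname]] <- list(germline = vname, length = L, counts = counts,
                              coverage = coverage, regions = regions,
                              hotspot = hotspot_mask(vseq))
  }
  structure(profiles, class = "mutation_profile_list")
}

## pool counts/coverage across a profile list
.pool_profiles <- function(profiles) {
  if (inherits(profiles, "mutation_profile_list") ||
      (is.list(profiles) && !is.null(profiles[[1L]]$counts)))
    profiles else list(profiles)
}

#' Overall SHM frequency of a profile set
#'
#' Total mutated bases over total aligned bases, as a percentage.
#'
#' @param profiles a `mutation_profile_list` (or single profile).
#' @return percentage.
#' @export
shm_frequency_of <- function(profiles) {
  ps <- .pool_profiles(profiles)
  mutated <- sum(vapply(ps, function(p) sum(p$counts), 0))
  total <- sum(vapply(ps, function(p) sum(p$coverage), 0))
  shm_frequency(mutated, total)
}

#' 12-type substitution spectrum
#'
#' The fraction of all observed mutations attributable to each ordered
#' substitution type, with transition/transversion aggregation.
#'
#' @param profiles a `mutation_profile_list` (or single profile).
#' @return a `data.frame` (`from`, `to`, `type`, `count`, `fraction`,
#'   `class`), sorted by descending fraction; attribute
#'   `transition_fraction` holds the aggregate transition share. Zero
#'   mutations yields an empty, flagged table.
#' @export
substitution_spectrum <- function(profiles) {
  ps <- .pool_profiles(profiles)
  totals <- Reduce(`+`, lapply(ps, function(p) rowSums(p$counts)))
  total <- sum(totals)
  df <- data.frame(
    type = names(totals),
    from = substr(names(totals), 1L, 1L),
    to = substr(names(totals), 3L, 3L),
    count = as.integer(totals),
    fraction = if (total > 0) as.numeric(totals) / total else
      rep(NA_real_, length(totals)),
    class = ifelse(names(totals) %in% TRANSITIONS, "transition",
                   "transversion"),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$count, df$type), ]
  rownames(df) <- NULL
  attr(df, "transition_fraction") <- if (total > 0)
    sum(df$count[df$class == "transition"]) / total else NA_real_
  attr(df, "total_mutations") <- total
  if (total == 0) attr(df, "empty") <- TRUE
  df
}

#' Mutations inside AID hotspot motifs
#'
#' Tallies mutations of germline C inside WRCY and germline G inside RGYW
#' (a position matching both contexts is counted once), reports the
#' per-type counts (C to T/G/A and G to A/C/T), the fraction of all
#' mutations falling in hotspots, and the hotspot versus background
#' per-base mutation rate ratio.
#'
#' @param profiles a `mutation_profile_list` (or single profile).
#' @return a list: `wrcy` and `rgyw` named count vectors, `n_mutations`,
#'   `hotspot_mutations`, `hotspot_fraction`, `hotspot_rate`,
#'   `background_rate`, `rate_ratio`.
#' @export
hotspot_mutations <- function(profiles) {
  ps <- .pool_profiles(profiles)
  wrcy <- c(T = 0L, G = 0L, A = 0L)
  rgyw <- c(A = 0L, C = 0L, T = 0L)
  hot_mut <- bg_mut <- 0
  hot_cov <- bg_cov <- 0
  total_mut <- 0
  for (p in ps) {
    hot <- p$hotspot != "none"
    pos_mut <- colSums(p$counts)
    total_mut <- total_mut + sum(pos_mut)
    hot_mut <- hot_mut + sum(pos_mut[hot])
    bg_mut <- bg_mut + sum(pos_mut[!hot])
    hot_cov <- hot_cov + sum(p$coverage[hot])
    bg_cov <- bg_cov + sum(p$coverage[!hot])
    for (tb in names(wrcy)) {
      sel <- p$hotspot %in% c("WRCY", "both")
      wrcy[tb] <- wrcy[tb] + sum(p$counts[paste0("C>", tb), sel])
    }
    for (tb in names(rgyw)) {
      sel <- p$hotspot %in% c("RGYW", "both")
      rgyw[tb] <- rgyw[tb] + sum(p$counts[paste0("G>", tb), sel])
    }
  }
  hot_rate <- if (hot_cov > 0) hot_mut / hot_cov else NA_real_
  bg_rate <- if (bg_cov > 0) bg_mut / bg_cov else NA_real_
  list(wrcy = wrcy, rgyw = rgyw, n_mutations = total_mut,
       hotspot_mutations = hot_mut,
       hotspot_fraction = if (total_mut > 0) hot_mut / total_mut else
         NA_real_,
       hotspot_rate = hot_rate, background_rate = bg_rate,
       rate_ratio = if (!is.na(bg_rate) && bg_rate > 0)
         hot_rate / bg_rate else NA_real_)
}

#' Per-position mutation map
#'
#' One row per germline position: coverage, total mutation count, count per
#' substitution type, FR/CDR region label and hotspot flag.
#'
#' @param profiles a `mutation_profile_list` (or single profile).
#' @return a `data.frame` in long-by-position form.
#' @export
position_map <- function(profiles) {
  ps <- .pool_profiles(profiles)
  out <- lapply(ps, function(p) {
    df <- data.frame(
      germline = p$germline, pos = seq_len(p$length) - 1L,
      coverage = p$coverage, mutations = colSums(p$counts),
      region = p$regions, hotspot = p$hotspot,
      stringsAsFactors = FALSE
    )
    tp <- as.data.frame(t(p$counts))
    names(tp) <- sub(">", "_", names(tp))
    cbind(df, tp)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
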