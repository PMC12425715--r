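## Per-sample repertoire statistics: segment usage frequencies,
## recombination-type tables, and cross-read summaries. Frequencies are
## computed without duplicate removal, as fractions of total assigned
## reads; output ordering is deterministic (descending fraction, ties by
## name).

#' Segment (or subgroup) usage frequencies
#'
#' Fraction of assigned reads using each germline segment, per segment
#' type. Segments present in the reference but unused are reported with
#' frequency 0. With `by = "subgroup"`, V usage is aggregated over the
#' reference's subgroup labels.
#'
#' @param rep an `ig_repertoire`.
#' @param ref the `germline_reference` (supplies the segment universe and
#'   subgroup labels).
#' @param by `"segment"` or `"subgroup"`.
#' @return a named list of `data.frame`s (`v`, `d`, `j` as available), each
#'   with `name`, `count`, `fraction`.
#' @export
usage_frequencies <- function(rep, ref, by = c("segment", "subgroup")) {
  by <- match.arg(by)
  stopifnot(inherits(rep, "ig_repertoire"))
  rr <- rep$rearrangements
  out <- list()
  for (st in c("V", "D", "J")) {
    col <- paste0(tolower(st), "_call")
    if (!col %in% names(rr)) next
    segs <- ref_segments(ref, st)
    segs <- segs[segs$locus == rep$locus, , drop = FALSE]
    if (!nrow(segs)) next
    calls <- rr[[col]][!is.na(rr[[col]])]
    if (by == "subgroup" && st == "V") {
      lab <- setNames(segs$subgroup, segs$name)
      calls <- as.character(lab[calls])
      universe <- sort(unique(as.character(segs$subgroup)))
    } else {
      universe <- segs$name
    }
    counts <- table(factor(calls, levels = universe))
    total <- sum(counts)
    df <- data.frame(name = universe, count = as.integer(counts),
                     fraction = if (total > 0) as.integer(counts) / total
                       else rep(0, length(universe)),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$fraction, df$name), ]
    rownames(df) <- NULL
    out[[tolower(st)]] <- df
  }
  out
}

#' Recombination-type table
#'
#' Distinct (V, D, J) -- or (V, J) for light chains -- combinations among
#' assigned reads, with counts and fractions sorted by descending fraction
#' (ties by name), plus the number of types below a reporting threshold.
#'
#' @param rep an `ig_repertoire`.
#' @param rare_threshold fraction below which a type is counted as rare
#'   (default 0.01).
#' @return a `data.frame` of types with attributes `n_types` and
#'   `n_rare_types`.
#' @export
recombination_types <- function(rep, rare_threshold = 0.01) {
  stopifnot(inherits(rep, "ig_repertoire"))
  rr <- rep$rearrangements
  rr <- rr[!is.na(rr$v_call) & !is.na(rr$j_call), , drop = FALSE]
  heavy <- rep$locus == "IGH" && "d_call" %in% names(rr)
  key <- if (heavy)
    paste(rr$v_call, ifelse(is.na(rr$d_call), "-", rr$d_call), rr$j_call,
          sep = "|")
  else paste(rr$v_call, rr$j_call, sep = "|")
  tab <- table(key)
  total <- sum(tab)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  df <- data.frame(
    v_call = vapply(parts, `[`, "", 1L),
    d_call = if (heavy) vapply(parts, `[`, "", 2L) else NA_character_,
    j_call = vapply(parts, `[`, "", if (heavy) 3L else 2L),
    count = as.integer(tab),
    fraction = as.integer(tab) / total,
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$fraction, df$v_call, df$d_call, df$j_call), ]
  rownames(df) <- NULL
  attr(df, "n_types") <- nrow(df)
  attr(df, "n_rare_types") <- sum(df$fraction < rare_threshold)
  df
}

#' Sankey-ready recombination flows
#'
#' Three-column (source, target, weight) edge lists for the V-to-D and
#' D-to-J flows (V-to-J for light chains).
#'
#' @param rep an `ig_repertoire`.
#' @return a `data.frame` with `source`, `target`, `weight`.
#' @export
sankey_flows <- function(rep) {
  rr <- rep$rearrangements
  rr <- rr[!is.na(rr$v_call) & !is.na(rr$j_call), , drop = FALSE]
  heavy <- rep$locus == "IGH" && "d_call" %in% names(rr) &&
    any(!is.na(rr$d_call))
  agg <- function(a, b) {
    t <- table(paste(a, b, sep = "|"))
    parts <- strsplit(names(t), "|", fixed = TRUE)
    data.frame(source = vapply(parts, `[`, "", 1L),
               target = vapply(parts, `[`, "", 2L),
               weight = as.integer(t), stringsAsFactors = FALSE)
  }
  if (heavy) {
    d <- ifelse(is.na(rr$d_call), "(no D)", rr$d_call)
    out <- rbind(agg(rr$v_call, d), agg(d, rr$j_call))
  } else {
    out <- agg(rr$v_call, rr$j_call)
  }
  out[order(out$source, out$target), ]
}

#' Per-sample repertoire summary
#'
#' @param rep a fully annotated `ig_repertoire`.
#' @param ref the `germline_reference`.
#' @return a list: `sample_id`, `n_reads`, `usage`, `recomb_types`,
#'   `cdr3_stats` (mean, sd, max of CDR3 length), `productive_fraction`.
#' @export
repertoire_summary <- function(rep, ref) {
  rr <- rep$rearrangements
  cl <- rr$cdr3_length[!is.na(rr$cdr3_length)]
  list(
    sample_id = rep$sample_id,
    n_reads = nrow(rr),
    usage = usage_frequencies(rep, ref),
    recomb_types = recombination_types(rep),
    cdr3_stats = c(mean = if (length(cl)) mean(cl) else NA_real_,
                   sd = if (length(cl) > 1) stats::sd(cl) else NA_real_,
                   max = if (length(cl)) max(cl) else NA_real_),
    productive_fraction = if ("productive" %in% names(rr) && nrow(rr))
      mean(rr$productive, na.rm = TRUE) else NA_real_
  )
}
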