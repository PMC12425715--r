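## Format adapters and the end-to-end pipeline driver. All randomness lives
## in the simulator; given fixed inputs every stage is deterministic, so
## rerunning a pipeline reproduces its outputs byte-for-byte.

#' Read amplicon reads from FASTA or FASTQ
#'
#' Format is chosen by extension (`.fq`/`.fastq`, optionally `.gz`);
#' anything else is parsed as FASTA.
#'
#' @param path input file.
#' @return a named `DNAStringSet`.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  reads <- withCallingHandlers(
    Biostrings::readDNAStringSet(path, format = fmt),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("malformed record in ", path, ": ", conditionMessage(w),
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  reads
}

#' Write reads as FASTA
#'
#' @param reads a `DNAStringSet` or named character vector.
#' @param path output file.
#' @export
write_reads <- function(reads, path) {
  if (!methods::is(reads, "DNAStringSet"))
    reads <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(reads, path)
  invisible(path)
}

## AIRR-style column order for the rearrangement table
AIRR_COLUMNS <- c(
  "sequence_id", "sample_id", "locus", "sequence", "rev_comp",
  "v_call", "d_call", "j_call", "junction", "cdr3", "cdr3_length",
  "productive", "v_identity", "j_identity", "np1_length", "np2_length",
  "d_sequence", "v_3p_del", "j_5p_del", "d_5p_del", "d_3p_del",
  "p1", "n1", "p2", "p3", "n2", "p4", "cdr3_missing_reason"
)

#' Write a rearrangement table as AIRR-style TSV
#'
#' Shared fields follow the AIRR Rearrangement naming
#' (`sequence_id`, `v_call`, `d_call`, `j_call`, `junction`, `cdr3`,
#' `productive`, `np1_length`, `np2_length`, ...); junction-decomposition
#' fields are appended after them.
#'
#' @param rep an `ig_repertoire` or a rearrangement `data.frame`.
#' @param path output TSV path.
#' @export
write_airr <- function(rep, path) {
  rr <- if (inherits(rep, "ig_repertoire")) rep$rearrangements else rep
  cols <- c(intersect(AIRR_COLUMNS, names(rr)),
            setdiff(names(rr), AIRR_COLUMNS))
  write.table(rr[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read an AIRR-style TSV written by [write_airr()]
#'
#' @param path TSV path.
#' @return a `data.frame`.
#' @export
read_airr <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             na.strings = c("NA", ""))
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Pipeline configuration
#'
#' Validated, fail-fast configuration for [run_pipeline()].
#'
#' @param reads input reads: a path (FASTA/FASTQ) or a `DNAStringSet`.
#' @param germline germline reference: a path prefix (as written by
#'   [write_germline()]) or a `germline_reference`.
#' @param out_dir output directory (created if absent).
#' @param sample_id sample label.
#' @param locus locus; default taken from the reference.
#' @param forward_primer,reverse_primer,min_len,max_primer_mismatches
#'   filter-stage settings (see [filter_reads()]); `do_filter = FALSE`
#'   skips the stage.
#' @param do_filter,do_shm stage toggles.
#' @param min_v_identity,min_j_identity,p_cap,min_d assignment and junction
#'   settings.
#' @param collapse_identical_junctions SHM deduplication flag (see
#'   [mutation_profiles()]).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(reads, germline, out_dir,
                            sample_id = "sample1", locus = NULL,
                            forward_primer = UPM_PRIMER,
                            reverse_primer = NULL, min_len = 400L,
                            max_primer_mismatches = 2L, do_filter = TRUE,
                            do_shm = TRUE, min_v_identity = 0.70,
                            min_j_identity = 0.80, p_cap = 4L, min_d = 5L,
                            collapse_identical_junctions = FALSE) {
  if (is.character(reads) && !file.exists(reads))
    stop("reads file does not exist: ", reads, call. = FALSE)
  if (is.character(germline) &&
      !file.exists(paste0(germline, ".fasta")))
    stop("germline reference not found at prefix: ", germline,
         call. = FALSE)
  stopifnot(min_len >= 0L, min_v_identity > 0, min_v_identity <= 1,
            min_j_identity > 0, min_j_identity <= 1)
  structure(list(reads = reads, germline = germline, out_dir = out_dir,
                 sample_id = sample_id, locus = locus,
                 forward_primer = forward_primer,
                 reverse_primer = reverse_primer, min_len = min_len,
                 max_primer_mismatches = max_primer_mismatches,
                 do_filter = do_filter, do_shm = do_shm,
                 min_v_identity = min_v_identity,
                 min_j_identity = min_j_identity, p_cap = p_cap,
                 min_d = min_d,
                 collapse_identical_junctions = collapse_identical_junctions),
            class = "pipeline_config")
}

#' Run the full repertoire pipeline
#'
#' Stages run in order filter -> assign -> junction -> SHM -> summarise;
#' each stage's outputs are written before the next starts and a manifest
#' of every produced file (with row counts) is written last.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `manifest` (`data.frame` of file, rows),
#'   `repertoire` (the annotated `ig_repertoire`) and `filter_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list()
  note <- function(path, rows) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = basename(path), rows = rows, stringsAsFactors = FALSE)
  }

  ref <- if (inherits(config$germline, "germline_reference"))
    config$germline else read_germline(config$germline)
  locus <- config$locus
  if (is.null(locus)) {
    locus <- unique(ref$segments$locus)
    if (length(locus) != 1L)
      stop("reference covers several loci; set `locus`", call. = FALSE)
  }
  reads <- if (is.character(config$reads)) read_reads(config$reads) else
    config$reads

  ## -- filter ---------------------------------------------------------------
  filter_report <- NULL
  if (config$do_filter) {
    rev_primer <- config$reverse_primer
    if (is.null(rev_primer)) rev_primer <- unname(GSP_PRIMERS[locus])
    fl <- filter_reads(reads, config$forward_primer, rev_primer,
                       min_len = config$min_len,
                       max_primer_mismatches = config$max_primer_mismatches)
    filter_report <- fl$report
    write_reads(fl$kept, out("kept.fasta"))
    note(out("kept.fasta"), length(fl$kept))
    rej <- data.frame(read_id = names(fl$reasons), reason = fl$reasons,
                      row.names = NULL, stringsAsFactors = FALSE)
    rej <- rej[!is.na(rej$reason), , drop = FALSE]
    write.table(rej, out("rejected_reads.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    note(out("rejected_reads.tsv"), nrow(rej))
    reads <- fl$kept
  }

  ## -- assign + junction ----------------------------------------------------
  rep <- analyze_repertoire(reads, ref, locus = locus,
                            min_v_identity = config$min_v_identity,
                            min_j_identity = config$min_j_identity,
                            sample_id = config$sample_id,
                            p_cap = config$p_cap, min_d = config$min_d)
  write_airr(rep, out("rearrangements.tsv"))
  note(out("rearrangements.tsv"), nrow(rep$rearrangements))
  if (nrow(rep$rejected)) {
    write.table(rep$rejected, out("unassigned_reads.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note(out("unassigned_reads.tsv"), nrow(rep$rejected))
  }

  if (nrow(rep$rearrangements)) {
    hists <- junction_histograms(rep$rearrangements)
    for (nm in c("v3_del", "np1", "d_length", "np2", "j5_del",
                 "cdr3_length")) {
      p <- .write_csv(hists[[nm]], out(paste0("hist_", nm, ".csv")))
      note(p, nrow(hists[[nm]]))
    }
    p <- .write_csv(hists$summary, out("junction_summary.csv"))
    note(p, nrow(hists$summary))
  }

  ## -- SHM ------------------------------------------------------------------
  if (config$do_shm && nrow(rep$rearrangements)) {
    profiles <- mutation_profiles(
      rep, ref,
      collapse_identical_junctions = config$collapse_identical_junctions)
    spec <- substitution_spectrum(profiles)
    p <- .write_csv(spec, out("shm_spectrum.csv")); note(p, nrow(spec))
    hs <- hotspot_mutations(profiles)
    hs_df <- data.frame(
      motif = c(rep("WRCY", 3L), rep("RGYW", 3L), "summary", "summary",
                "summary"),
      key = c(paste0("C>", names(hs$wrcy)), paste0("G>", names(hs$rgyw)),
              "hotspot_fraction", "hotspot_rate", "rate_ratio"),
      value = c(as.numeric(hs$wrcy), as.numeric(hs$rgyw),
                hs$hotspot_fraction, hs$hotspot_rate, hs$rate_ratio),
      stringsAsFactors = FALSE
    )
    p <- .write_csv(hs_df, out("shm_hotspots.csv")); note(p, nrow(hs_df))
    pm <- position_map(profiles)
    p <- .write_csv(pm, out("shm_position_map.csv")); note(p, nrow(pm))
  }

  ## -- summarise ------------------------------------------------------------
  if (nrow(rep$rearrangements)) {
    usage <- usage_frequencies(rep, ref)
    for (nm in names(usage)) {
      p <- .write_csv(usage[[nm]], out(paste0("usage_", nm, ".csv")))
      note(p, nrow(usage[[nm]]))
    }
    rt <- recombination_types(rep)
    p <- .write_csv(rt, out("recombination_types.csv")); note(p, nrow(rt))
    fl <- sankey_flows(rep)
    p <- .write_csv(fl, out("recombination_flows.csv")); note(p, nrow(fl))
  }

  man <- do.call(rbind, manifest)
  write.table(man, out("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(manifest = man, repertoire = rep,
                 filter_report = filter_report))
}
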