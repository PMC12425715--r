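## Shared fixtures, built once per test session. All fixtures are generated
## in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## expressed heavy-chain reference used by most repertoire tests
fx_ref_igh <- function() fixture("ref_igh", function() {
  make_toy_germline(7, "IGH")
})

fx_ref_igk <- function() fixture("ref_igk", function() {
  make_toy_germline(13, "IGK")
})

## a clean (no SHM, no sequencing error) simulated heavy-chain run with
## its analysis, shared across junction/stats tests
fx_clean_run <- function() fixture("clean_run", function() {
  ref <- fx_ref_igh()
  cfg <- simulation_config(seed = 101, n_reads = 400, shm_rate = 0,
                           seq_error_rate = 0)
  sim <- simulate_repertoire(cfg, ref)
  rep <- analyze_repertoire(sim$reads, ref)
  tr <- sim$truth[match(rep$rearrangements$sequence_id, sim$truth$read_id), ]
  list(ref = ref, cfg = cfg, sim = sim, rep = rep, truth = tr)
})

## a mutated run (2% SHM, hotspot multiplier 5) for SHM tests
fx_shm_run <- function() fixture("shm_run", function() {
  ref <- fx_ref_igh()
  cfg <- simulation_config(seed = 202, n_reads = 400, shm_rate = 0.02,
                           seq_error_rate = 0)
  sim <- simulate_repertoire(cfg, ref)
  rep <- analyze_repertoire(sim$reads, ref)
  tr <- sim$truth[match(rep$rearrangements$sequence_id, sim$truth$read_id), ]
  list(ref = ref, cfg = cfg, sim = sim, rep = rep, truth = tr)
})

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## expand the truth mutation strings into per-read keys "id pos:F>T"
truth_mutation_keys <- function(truth) {
  idx <- which(truth$n_mutations > 0)
  if (!length(idx)) return(character(0))
  unlist(lapply(idx, function(i) {
    paste(truth$read_id[i],
          strsplit(truth$mutations[i], "|", fixed = TRUE)[[1L]])
  }))
}

called_mutation_keys <- function(rep) {
  m <- rep$mutations
  if (!nrow(m)) return(character(0))
  paste(m$sequence_id, sprintf("%d:%s>%s", m$pos, m$from, m$to))
}

## compare one rearrangement row against its truth row on the junction
## decomposition tuple
junction_matches_truth <- function(rr_row, tr_row) {
  heavy <- tr_row$locus == "IGH"
  ok <- rr_row$v_3p_del == tr_row$v3_del &&
    rr_row$j_5p_del == tr_row$j5_del &&
    nchar(rr_row$p1) == nchar(tr_row$p1) &&
    nchar(rr_row$n1) == nchar(tr_row$n1) &&
    nchar(rr_row$p2) == nchar(tr_row$p2)
  if (!ok || !heavy) return(ok)
  identical(rr_row$d_call, tr_row$d_call) &&
    rr_row$d_5p_del == tr_row$d5_del &&
    rr_row$d_3p_del == tr_row$d3_del &&
    nchar(rr_row$p3) == nchar(tr_row$p3) &&
    nchar(rr_row$n2) == nchar(tr_row$n2) &&
    nchar(rr_row$p4) == nchar(tr_row$p4)
}
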