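test_that("an exact germline V+D+J concatenation is called perfectly with
           abutting intervals and no mutations", {
  ref <- fx_ref_igh()
  s <- ref$segments
  v <- s$name[s$seg_type == "V"][2]
  d <- s$name[s$seg_type == "D"][2]
  j <- s$name[s$seg_type == "J"][1]
  set.seed(51)
  lead <- random_dna(45)
  read <- paste0(lead, ovIgSeq:::ref_seq(ref, v), ovIgSeq:::ref_seq(ref, d),
                 ovIgSeq:::ref_seq(ref, j),
                 substr(ovIgSeq:::ref_seq(ref, s$name[s$seg_type == "C"][1]),
                        1, 100))
  rep <- analyze_repertoire(c(r1 = read), ref)
  rr <- rep$rearrangements
  expect_identical(nrow(rr), 1L)
  expect_identical(rr$v_call, v)
  expect_identical(rr$d_call, d)
  expect_identical(rr$j_call, j)
  expect_identical(nrow(rep$mutations), 0L)
  expect_identical(rr$v_read_start, nchar(lead))
  ## zero deletions, zero insertions: intervals abut exactly
  expect_identical(rr$v_3p_del, 0L)
  expect_identical(rr$j_5p_del, 0L)
  expect_identical(rr$d_5p_del, 0L)
  expect_identical(rr$d_3p_del, 0L)
  expect_identical(rr$np1_length, 0L)
  expect_identical(rr$np2_length, 0L)
})

test_that("simulated substitutions are recovered as the exact truth
           mutation list", {
  run <- fx_shm_run()
  expect_identical(run$rep$rearrangements$v_call, run$truth$v_call)
  cm <- called_mutation_keys(run$rep)
  tk <- truth_mutation_keys(run$truth)
  expect_gte(mean(cm %in% tk), 0.99)
  expect_gte(mean(tk %in% cm), 0.99)
})

test_that("V and J calls are fully accurate on clean reads and accuracy is
           monotone non-increasing in the SHM rate", {
  run <- fx_clean_run()
  expect_identical(run$rep$rearrangements$v_call, run$truth$v_call)
  expect_identical(run$rep$rearrangements$j_call, run$truth$j_call)
  ref <- run$ref
  acc <- vapply(c(0, 0.02, 0.05, 0.10), function(r) {
    cfg <- simulation_config(seed = 73, n_reads = 120, shm_rate = r,
                             seq_error_rate = 0)
    sim <- simulate_repertoire(cfg, ref)
    rep <- analyze_repertoire(sim$reads, ref)
    tr <- sim$truth[match(rep$rearrangements$sequence_id,
                          sim$truth$read_id), ]
    sum(rep$rearrangements$v_call == tr$v_call) / nrow(sim$truth)
  }, 0)
  expect_true(all(diff(acc) <= 1e-9 + 0))
  expect_identical(acc[1], 1)
})

test_that("assignment is deterministic and ties break toward the
           lexicographically smaller name", {
  ref <- fx_ref_igh()
  s <- ref$segments
  vname <- s$name[s$seg_type == "V"][1]
  ## duplicate the first V under a larger and a smaller name
  segs2 <- rbind(s, transform(s[s$name == vname, ],
                              name = "IGHV1S9"),
                 transform(s[s$name == vname, ], name = "IGHV1S0"))
  seqs2 <- c(ref$sequences,
             setNames(ref$sequences[vname], "IGHV1S9"),
             setNames(ref$sequences[vname], "IGHV1S0"))
  meta2 <- c(ref$meta, setNames(ref$meta[vname], "IGHV1S9"),
             setNames(ref$meta[vname], "IGHV1S0"))
  ref2 <- germline_reference(segs2, seqs2, ref$genome_id, meta2)
  cfg <- simulation_config(seed = 81, n_reads = 10, shm_rate = 0,
                           seq_error_rate = 0,
                           v_usage = c(1, 0, 0, 0), j_usage = NULL)
  sim <- simulate_repertoire(cfg, ref)
  rep1 <- assign_repertoire(sim$reads, ref2)
  rep2 <- assign_repertoire(sim$reads, ref2)
  expect_identical(rep1$rearrangements, rep2$rearrangements)
  expect_true(all(rep1$rearrangements$v_call == "IGHV1S0"))
})

test_that("unassignable reads are rejected with a reason", {
  ref <- fx_ref_igh()
  set.seed(91)
  junk <- setNames(vapply(1:5, function(i) random_dna(450), ""),
                   paste0("junk", 1:5))
  rep <- assign_repertoire(junk, ref)
  expect_identical(nrow(rep$rearrangements), 0L)
  expect_identical(nrow(rep$rejected), 5L)
  expect_true(all(rep$rejected$reason == "no_v_match"))
})
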