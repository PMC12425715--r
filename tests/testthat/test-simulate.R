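test_that("the degenerate configuration emits exact germline
           concatenations with an all-zero truth table", {
  ref <- fx_ref_igh()
  cfg <- simulation_config(seed = 71, n_reads = 25, shm_rate = 0,
                           seq_error_rate = 0, p_prob = 0,
                           v3_del = list(p = 1, max = 0),
                           d5_del = list(p = 1, max = 0),
                           d3_del = list(p = 1, max = 0),
                           j5_del = list(p = 1, max = 0),
                           n_len = list(p = 1, max = 0))
  sim <- simulate_repertoire(cfg, ref)
  tr <- sim$truth
  expect_true(all(tr$v3_del == 0 & tr$j5_del == 0 & tr$d5_del == 0 &
                    tr$d3_del == 0 & tr$np1_length == 0 &
                    tr$np2_length == 0 & tr$n_mutations == 0))
  ## every read contains the exact germline V+D+J concatenation
  for (i in seq_len(5)) {
    core <- paste0(ovIgSeq:::ref_seq(ref, tr$v_call[i]),
                   ovIgSeq:::ref_seq(ref, tr$d_call[i]),
                   ovIgSeq:::ref_seq(ref, tr$j_call[i]))
    expect_true(grepl(core, as.character(sim$reads[[i]]), fixed = TRUE))
  }
})

test_that("identical seeds give byte-identical outputs", {
  ref <- fx_ref_igh()
  cfg <- simulation_config(seed = 72, n_reads = 30, shm_rate = 0.02)
  s1 <- simulate_repertoire(cfg, ref)
  s2 <- simulate_repertoire(cfg, ref)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_repertoire(simulation_config(seed = 73, n_reads = 30,
                                              shm_rate = 0.02), ref)
  expect_false(identical(as.character(s1$reads), as.character(s3$reads)))
})

test_that("every read reconstructs byte-for-byte from its truth record", {
  ref <- fx_ref_igh()
  cfg <- simulation_config(seed = 74, n_reads = 60, shm_rate = 0.03,
                           seq_error_rate = 0.002,
                           fraction_missing_primer = 0.2)
  sim <- simulate_repertoire(cfg, ref)
  rebuilt <- vapply(seq_len(nrow(sim$truth)), function(i)
    reconstruct_read(sim$truth[i, ], ref, cfg), "")
  expect_identical(rebuilt, unname(as.character(sim$reads)))
})

test_that("zeroing one diversity channel zeroes the corresponding
           measured histogram (channel isolation)", {
  ref <- fx_ref_igh()
  base <- list(seed = 75, n_reads = 80, shm_rate = 0, seq_error_rate = 0)
  ## no N and no P: all np lengths zero
  cfg <- do.call(simulation_config,
                 c(base, list(p_prob = 0, n_len = list(p = 1, max = 0))))
  sim <- simulate_repertoire(cfg, ref)
  rep <- analyze_repertoire(sim$reads, ref)
  h <- junction_histograms(rep$rearrangements)
  expect_identical(h$np1$value, 0L)
  ## no deletions at the V end
  cfg2 <- do.call(simulation_config,
                  c(base, list(v3_del = list(p = 1, max = 0))))
  sim2 <- simulate_repertoire(cfg2, ref)
  expect_true(all(sim2$truth$v3_del == 0))
})

test_that("the toy germline is anchor-correct with the expressed segment
           counts used for the heavy chain", {
  ref <- make_toy_germline(99, "IGH")
  s <- ref$segments
  expect_identical(as.integer(table(s$seg_type)[c("V", "D", "J")]),
                   c(4L, 4L, 2L))
  for (v in s$name[s$seg_type == "V"]) {
    aa <- ovIgSeq:::translate_dna(ovIgSeq:::ref_seq(ref, v))
    expect_false(grepl("*", substr(aa, 1, 97), fixed = TRUE))
    expect_identical(substr(aa, 97, 97), "C")          # 2nd-CYS
    expect_identical(substr(aa, 22, 22), "C")          # 1st-CYS
  }
  for (j in s$name[s$seg_type == "J"]) {
    jseq <- ovIgSeq:::ref_seq(ref, j)
    hits <- 0
    for (f in 0:2) {
      aa <- ovIgSeq:::translate_dna(substr(jseq, f + 1, nchar(jseq)))
      g <- gregexpr("(?=[FW]G.G)", aa, perl = TRUE)[[1]]
      hits <- hits + sum(g > 0)
    }
    expect_identical(hits, 1)   # exactly one [FW]GXG motif
  }
  ## the (YG)n-motif D segment is present
  d2 <- ovIgSeq:::ref_seq(ref, "IGHD2")
  expect_identical(ovIgSeq:::translate_dna(d2), "SYYSGYGYAYGY")
})

test_that("simulated deletion lengths follow the configured truncated
           geometric law (Kolmogorov-Smirnov at depth)", {
  ref <- fx_ref_igh()
  cfg <- simulation_config(seed = 76, n_reads = 1200, shm_rate = 0,
                           seq_error_rate = 0)
  sim <- simulate_repertoire(cfg, ref)
  x <- sim$truth$v3_del
  k <- 0:cfg$v3_del$max
  p <- (1 - cfg$v3_del$p)^k * cfg$v3_del$p
  p <- p / sum(p)
  ## one-sample KS distance against the discrete generating CDF
  emp <- ecdf(x)(k)
  ks <- max(abs(emp - cumsum(p)))
  expect_lt(ks, 1.63 / sqrt(length(x)))  # ~1% critical value
})

test_that("generator preconditions are validated", {
  expect_error(simulation_config(shm_rate = 1.5))
  ref <- fx_ref_igh()
  expect_error(simulate_repertoire(
    simulation_config(v_usage = c(1, 1)), ref))
})
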