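test_that("the identity junction (no deletions, no insertions) decomposes
           to all-zero fields", {
  run <- fx_clean_run()
  rr <- run$rep$rearrangements
  tr <- run$truth
  idx <- which(tr$v3_del == 0 & tr$j5_del == 0 & tr$d5_del == 0 &
                 tr$d3_del == 0 & tr$np1_length == 0 & tr$np2_length == 0)
  if (length(idx)) {
    expect_true(all(rr$v_3p_del[idx] == 0 & rr$j_5p_del[idx] == 0 &
                      rr$np1_length[idx] == 0 & rr$np2_length[idx] == 0))
  }
  ## a hand-built identity read
  ref <- run$ref
  s <- ref$segments
  read <- paste0(strrep("T", 30),
                 ovIgSeq:::ref_seq(ref, s$name[s$seg_type == "V"][1]),
                 ovIgSeq:::ref_seq(ref, s$name[s$seg_type == "D"][1]),
                 ovIgSeq:::ref_seq(ref, s$name[s$seg_type == "J"][1]))
  rep <- analyze_repertoire(c(x = read), ref)
  rr1 <- rep$rearrangements
  expect_identical(rr1$v_3p_del + rr1$j_5p_del + rr1$d_5p_del +
                     rr1$d_3p_del + rr1$np1_length + rr1$np2_length, 0L)
})

test_that("P nucleotides are the inward-read reverse complement of the
           undeleted germline end", {
  ## germline V ending ...CA, undeleted, gap starting TG -> p1 == "TG"
  p <- ovIgSeq:::.p_after("TGAA", "GGGCA", 4L)
  expect_identical(p, 2L)
  ## deletion > 0 forbids a P tract by definition (enforced upstream);
  ## the J-side mirror reads the first germline bases inward
  p4 <- ovIgSeq:::.p_before("GGTC", "GATT", 4L)
  expect_identical(p4, 2L)  # "TC" = revcomp of "GA"
})

test_that("clean junctions: exact truth recovery when unambiguous,
           optimal-class membership always, concatenation invariant
           everywhere", {
  run <- fx_clean_run()
  rr <- run$rep$rearrangements
  tr <- run$truth
  ref <- run$ref
  expect_identical(nrow(rr), nrow(tr))

  ## concatenation invariant: junction fields rebuild the read between the
  ## trimmed V end and trimmed J start
  rebuilt <- paste0(rr$p1, rr$n1, rr$p2,
                    ifelse(is.na(rr$d_sequence), "", rr$d_sequence),
                    rr$p3, rr$n2, rr$p4)
  observed <- substr(rr$sequence, rr$v_read_end_trim + 1,
                     rr$j_read_start_trim)
  expect_identical(rebuilt, observed)

  un <- which(!tr$ambiguous_junction)
  expect_gt(length(un), 50)
  exact <- vapply(un, function(i)
    junction_matches_truth(rr[i, ], tr[i, ]), TRUE)
  expect_true(all(exact))

  ## ambiguous junctions still land inside the enumerator's optimal class
  dsegs <- ovIgSeq:::ref_segments(ref, "D")
  dseqs <- as.list(ref$sequences[dsegs$name])
  amb <- which(tr$ambiguous_junction)
  in_class <- vapply(amb, function(i) {
    cls <- enumerate_decompositions(
      rr$sequence[i], ovIgSeq:::ref_seq(ref, rr$v_call[i]),
      rr$v_read_start[i], ovIgSeq:::ref_seq(ref, rr$j_call[i]),
      rr$j_read_off[i], dseqs)
    any(vapply(cls, function(d) {
      isTRUE(d$v3_del == rr$v_3p_del[i] && d$j5_del == rr$j_5p_del[i] &&
        identical(is.na(d$d_call), is.na(rr$d_call[i])) &&
        (is.na(d$d_call) || d$d_call == rr$d_call[i]) &&
        nchar(d$n1) == nchar(rr$n1[i]) && nchar(d$n2) == nchar(rr$n2[i]))
    }, TRUE))
  }, TRUE)
  expect_true(all(in_class))
})

test_that("P fields are empty whenever the adjacent end is deleted", {
  run <- fx_clean_run()
  rr <- run$rep$rearrangements
  expect_true(all(nchar(rr$p1[rr$v_3p_del > 0]) == 0))
  expect_true(all(nchar(rr$p4[rr$j_5p_del > 0]) == 0))
  with_d <- !is.na(rr$d_call)
  expect_true(all(nchar(rr$p2[with_d & rr$d_5p_del > 0]) == 0))
  expect_true(all(nchar(rr$p3[with_d & rr$d_3p_del > 0]) == 0))
})

test_that("CDR3 runs between the 2nd-CYS and the J anchor, both excluded", {
  run <- fx_clean_run()
  ref <- run$ref
  rr <- run$rep$rearrangements
  tr <- run$truth
  ok <- !is.na(rr$cdr3_length) | !is.na(tr$cdr3_length)
  expect_identical(rr$cdr3_length[ok], tr$cdr3_length[ok])
  ## for in-frame junctions the translation starts with C and ends with
  ## the anchor W/F (out-of-frame junctions are not codon-aligned)
  with_j <- which(!is.na(rr$junction) & rr$productive)
  aa <- vapply(rr$junction[with_j], ovIgSeq:::translate_dna, "")
  expect_true(all(substr(aa, 1, 1) == "C"))
  expect_true(all(substr(aa, nchar(aa), nchar(aa)) %in% c("W", "F")))
  ## CDR3 is contained in the junction with exactly one codon margin
  expect_true(all(nchar(rr$junction[with_j]) ==
                    rr$cdr3_length[with_j] + 6L))
})

test_that("a mutated 2nd-CYS codon makes CDR3 undefined with a logged
           reason", {
  ref <- fx_ref_igh()
  s <- ref$segments
  v <- ovIgSeq:::ref_seq(ref, s$name[s$seg_type == "V"][1])
  cys <- ref$meta[[s$name[s$seg_type == "V"][1]]]$cys2
  substr(v, cys + 1, cys + 3) <- "TGA"  # 2nd-CYS -> stop
  read <- paste0(strrep("A", 30), v,
                 ovIgSeq:::ref_seq(ref, s$name[s$seg_type == "D"][1]),
                 ovIgSeq:::ref_seq(ref, s$name[s$seg_type == "J"][1]))
  rep <- analyze_repertoire(c(x = read), ref)
  expect_true(is.na(rep$rearrangements$cdr3))
  expect_identical(rep$rearrangements$cdr3_missing_reason, "missing_anchor")
})

test_that("productive rearrangements always have CDR3 lengths divisible by
           three; a forced frameshift is judged unproductive", {
  run <- fx_clean_run()
  rr <- run$rep$rearrangements
  prod <- rr$productive & !is.na(rr$cdr3_length)
  expect_gt(sum(prod), 0)
  expect_true(all(rr$cdr3_length[prod] %% 3 == 0))
  expect_identical(rr$productive, run$truth$productive)

  ## deleting one junction base flips the frame
  i <- which(rr$productive & rr$np1_length > 0)[1]
  read <- rr$sequence[i]
  cut <- rr$v_read_end_trim[i] + 1
  shifted <- paste0(substr(read, 1, cut - 1),
                    substr(read, cut + 1, nchar(read)))
  rep2 <- analyze_repertoire(setNames(shifted, "fs"), run$ref)
  expect_false(rep2$rearrangements$productive[1])
})

test_that("the deletion-law estimator inverts the coincidental-extension
           channel simulated directly", {
  ## independent channel simulation: X truncated-geometric, G geometric
  ## with match probability q, M = max(X - G, 0)
  set.seed(88)
  p <- 0.35; cap <- 32L; q <- 0.25; n <- 40000
  k <- 0:cap
  w <- (1 - p)^k * p
  x <- sample(k, n, replace = TRUE, prob = w / sum(w))
  g <- rgeom(n, 1 - q)
  m <- pmax(x - g, 0L)
  est <- estimate_deletion_distribution(m, match_prob = q)
  expect_lt(abs(est$mean - mean(x)) / mean(x), 0.03)
  ## raw measured mean is visibly biased low, the corrected one is not
  expect_gt(mean(x) - mean(m), 0.15)
})

test_that("junction histograms match direct arithmetic", {
  rr <- data.frame(cdr3_length = c(27L, 27L, 30L),
                   v_3p_del = c(0L, 1L, 1L),
                   np1_length = c(0L, 0L, 2L),
                   np2_length = c(NA, NA, NA),
                   j_5p_del = c(0L, 0L, 0L),
                   d_sequence = c(NA, NA, NA))
  h <- junction_histograms(rr)
  expect_identical(h$cdr3_length$value, c(27L, 30L))
  expect_equal(h$cdr3_length$fraction, c(2 / 3, 1 / 3))
  expect_equal(h$summary$value[h$summary$statistic == "cdr3_length_mean"],
               28)
  ## mean/sd equal a direct recomputation from the record stream
  run <- fx_clean_run()
  h2 <- junction_histograms(run$rep$rearrangements)
  cl <- run$rep$rearrangements$cdr3_length
  cl <- cl[!is.na(cl)]
  expect_equal(h2$summary$value[h2$summary$statistic == "cdr3_length_mean"],
               mean(cl))
  expect_equal(h2$summary$value[h2$summary$statistic == "cdr3_length_sd"],
               sd(cl))
})
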