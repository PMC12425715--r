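mini_rep <- function(v, j, d = NULL, locus = "IGH") {
  rr <- data.frame(sequence_id = paste0("r", seq_along(v)), v_call = v,
                   j_call = j, stringsAsFactors = FALSE)
  if (!is.null(d)) rr$d_call <- d
  structure(list(rearrangements = rr,
                 mutations = data.frame(), rejected = data.frame(),
                 sample_id = "s1", locus = locus),
            class = "ig_repertoire")
}

test_that("usage fractions follow the counts, report unused segments as
           zero, and are order-invariant", {
  ref <- fx_ref_igh()
  vnames <- ref$segments$name[ref$segments$seg_type == "V"]
  rep <- mini_rep(v = c(rep(vnames[1], 3), vnames[2]),
                  j = rep(ref$segments$name[ref$segments$seg_type == "J"][1],
                          4))
  u <- usage_frequencies(rep, ref)
  expect_equal(u$v$fraction[u$v$name == vnames[1]], 0.75)
  expect_equal(u$v$fraction[u$v$name == vnames[2]], 0.25)
  expect_true(all(u$v$fraction[u$v$name %in% vnames[3:4]] == 0))
  expect_equal(sum(u$v$fraction), 1)
  perm <- sample(4)
  rep2 <- rep
  rep2$rearrangements <- rep$rearrangements[perm, ]
  expect_identical(usage_frequencies(rep2, ref), u)
})

test_that("subgroup usage aggregates over the reference labels", {
  ref <- fx_ref_igh()
  ref$segments$subgroup[ref$segments$seg_type == "V"] <- c(1L, 1L, 2L, 2L)
  vnames <- ref$segments$name[ref$segments$seg_type == "V"]
  rep <- mini_rep(v = vnames[c(1, 2, 3)], j = rep("IGHJ1", 3))
  u <- usage_frequencies(rep, ref, by = "subgroup")
  expect_equal(u$v$fraction[u$v$name == "1"], 2 / 3)
})

test_that("recombination types are enumerated with normalised fractions
           and a rare-type count", {
  rep <- mini_rep(v = c("A", "A", "A", "B"), j = c("J1", "J1", "J1", "J1"),
                  d = c("D1", "D2", "D1", "D1"))
  rt <- recombination_types(rep)
  expect_identical(attr(rt, "n_types"), 3L)
  expect_equal(sum(rt$fraction), 1)
  expect_identical(rt$count[1], 2L)
  rt2 <- recombination_types(rep, rare_threshold = 0.3)
  expect_identical(attr(rt2, "n_rare_types"), 2L)
})

test_that("all configured recombination types appear at depth under
           uniform usage (coupon collection at fixed seed)", {
  ref <- fx_ref_igh()
  cfg <- simulation_config(seed = 55, n_reads = 1500, shm_rate = 0,
                           seq_error_rate = 0,
                           v_usage = rep(0.25, 4), d_usage = rep(0.25, 4),
                           j_usage = c(0.5, 0.5))
  sim <- simulate_repertoire(cfg, ref)
  rep <- analyze_repertoire(sim$reads, ref)
  rt <- recombination_types(rep)
  ## 4 V x 4 D x 2 J = 32 types, all observed at this depth; D-less calls
  ## (remnant below the match floor) appear as additional "-" types
  with_d <- rt[rt$d_call != "-", ]
  expect_identical(nrow(with_d), 32L)
  expect_identical(sum(rt$count), nrow(rep$rearrangements))
})

test_that("cross-module consistency: summary counts equal the AIRR rows
           with resolved calls", {
  run <- fx_clean_run()
  sm <- repertoire_summary(run$rep, run$ref)
  expect_identical(sm$n_reads, nrow(run$rep$rearrangements))
  expect_identical(sum(sm$recomb_types$count),
                   sum(!is.na(run$rep$rearrangements$v_call) &
                         !is.na(run$rep$rearrangements$j_call)))
  fl <- sankey_flows(run$rep)
  expect_identical(sum(fl$weight), 2L * sum(sm$recomb_types$count))
})
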