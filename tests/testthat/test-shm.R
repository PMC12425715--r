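test_that("the printed SHM frequency formula is applied verbatim", {
  expect_identical(shm_frequency(0, 1000), 0)
  expect_identical(shm_frequency(2, 200), 1)
  expect_error(shm_frequency(1, 0))
})

test_that("the hotspot mask follows the IUPAC expansion of WRCY/RGYW and
           its reverse-complement duality", {
  ## in AGCT: C at index 3 sits in a WRCY context (A=W, G=R, C, T=Y) and
  ## G at index 2 in an RGYW context
  m <- hotspot_mask("AGCT")
  expect_identical(m, c("none", "RGYW", "WRCY", "none"))
  ## duality: the mask of the reverse complement equals the reversed mask
  ## with WRCY and RGYW swapped
  set.seed(33)
  for (i in 1:5) {
    s <- random_dna(200)
    m1 <- hotspot_mask(s)
    m2 <- hotspot_mask(revcomp(s))
    swapped <- rev(ifelse(m1 == "WRCY", "RGYW",
                          ifelse(m1 == "RGYW", "WRCY", m1)))
    expect_identical(m2, swapped)
  }
})

test_that("mutation profiles conserve counts across spectrum, position map
           and the mutation stream", {
  run <- fx_shm_run()
  prof <- mutation_profiles(run$rep, run$ref)
  total <- nrow(run$rep$mutations)
  spec <- substitution_spectrum(prof)
  expect_identical(sum(spec$count), total)
  expect_equal(sum(spec$fraction), 1)
  pm <- position_map(prof)
  expect_equal(sum(pm$mutations), total)
  ## per-position mutation count never exceeds coverage
  expect_true(all(pm$mutations <= pm$coverage))
  ## region labels present for every position of the toy V
  expect_true(all(!is.na(pm$region[pm$pos < 291])))
})

test_that("a single-type input yields a degenerate spectrum and zero
           mutations an empty flagged table", {
  prof <- list(list(germline = "g", length = 4L,
                    counts = matrix(0L, 12, 4,
                                    dimnames = list(ovIgSeq:::SUBSTITUTION_TYPES,
                                                    NULL)),
                    coverage = rep(10L, 4),
                    regions = rep(NA_character_, 4),
                    hotspot = rep("none", 4)))
  prof[[1]]$counts["A>G", 2] <- 5L
  spec <- substitution_spectrum(prof)
  expect_identical(spec$fraction[spec$type == "A>G"], 1)
  expect_identical(attr(spec, "transition_fraction"), 1)
  prof[[1]]$counts["A>G", 2] <- 0L
  empty <- substitution_spectrum(prof)
  expect_true(isTRUE(attr(empty, "empty")))
})

test_that("hotspot mutations are tallied once per event with per-type
           counts, and the simulated five-fold enrichment is recovered", {
  ## one C>T at a flagged WRCY C
  prof <- list(list(germline = "g", length = 4L,
                    counts = matrix(0L, 12, 4,
                                    dimnames = list(ovIgSeq:::SUBSTITUTION_TYPES,
                                                    NULL)),
                    coverage = rep(100L, 4),
                    regions = rep(NA_character_, 4),
                    hotspot = hotspot_mask("AGCT")))
  prof[[1]]$counts["C>T", 3] <- 1L
  hs <- hotspot_mutations(prof)
  expect_identical(unname(hs$wrcy["T"]), 1L)
  expect_identical(hs$hotspot_mutations, 1)
  expect_identical(hs$hotspot_fraction, 1)

  ## enrichment recovery on the simulated run (multiplier 5)
  run <- fx_shm_run()
  hs2 <- hotspot_mutations(mutation_profiles(run$rep, run$ref))
  ## 3-SE band for the rate ratio via the delta method on log scale
  se_log <- sqrt(1 / hs2$hotspot_mutations + 1 / (hs2$n_mutations -
                                                    hs2$hotspot_mutations))
  expect_lt(abs(log(hs2$rate_ratio / 5)), 3 * se_log)
})

test_that("SHM frequency is invariant to read order and batch splits", {
  run <- fx_shm_run()
  rep <- run$rep
  prof <- mutation_profiles(rep, run$ref)
  f_all <- shm_frequency_of(prof)
  ## split the read set in two and recombine the tallies
  ids <- rep$rearrangements$sequence_id
  half <- seq_len(length(ids) %/% 2)
  sub_rep <- function(keep_ids) {
    structure(list(
      rearrangements = rep$rearrangements[ids %in% keep_ids, ],
      mutations = rep$mutations[rep$mutations$sequence_id %in% keep_ids, ],
      rejected = rep$rejected, sample_id = rep$sample_id,
      locus = rep$locus), class = "ig_repertoire")
  }
  p1 <- mutation_profiles(sub_rep(ids[half]), run$ref)
  p2 <- mutation_profiles(sub_rep(ids[-half]), run$ref)
  mutated <- sum(vapply(c(p1, p2), function(p) sum(p$counts), 0))
  total <- sum(vapply(c(p1, p2), function(p) sum(p$coverage), 0))
  expect_equal(shm_frequency(mutated, total), f_all)
})

test_that("mutation calling reaches 0.99 precision and recall on
           simulations without sequencing error", {
  run <- fx_shm_run()
  cm <- called_mutation_keys(run$rep)
  tk <- truth_mutation_keys(run$truth)
  expect_gte(mean(cm %in% tk), 0.99)
  expect_gte(mean(tk %in% cm), 0.99)
})

test_that("mutations concentrated in CDR1 by construction show up in the
           CDR1 rows of the position map", {
  ref <- fx_ref_igh()
  ## hand-build a profile-like repertoire: mutate only CDR1 positions
  s <- ref$segments
  vname <- s$name[s$seg_type == "V"][1]
  v <- ovIgSeq:::ref_seq(ref, vname)
  reads <- character(20)
  set.seed(44)
  for (i in 1:20) {
    vv <- v
    pos <- sample(76:99, 2)  # CDR1 nt range (0-based 75..98)
    for (p in pos) substr(vv, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                      substr(vv, p, p)), 1)
    reads[i] <- paste0(strrep("G", 25), vv,
                       ovIgSeq:::ref_seq(ref, s$name[s$seg_type == "D"][1]),
                       ovIgSeq:::ref_seq(ref, s$name[s$seg_type == "J"][1]))
  }
  rep <- analyze_repertoire(setNames(reads, paste0("r", 1:20)), ref)
  pm <- position_map(mutation_profiles(rep, ref))
  pm_v <- pm[pm$germline == vname, ]
  frac_cdr1 <- sum(pm_v$mutations[pm_v$region %in% "CDR1"]) /
    sum(pm_v$mutations)
  expect_gte(frac_cdr1, 0.99)
})
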