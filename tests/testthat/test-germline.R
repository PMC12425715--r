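test_that("a planted template with its RSS is located exactly", {
  set.seed(11)
  v <- random_dna(300)
  g <- paste0(random_dna(400), v, "CACAGTG", random_dna(23), "ACAAAAACC",
              random_dna(400))
  segs <- locate_segments(g, c(tplV = v), "IGH", "V")
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$start, 400L)
  expect_identical(segs$end, 700L)
  expect_identical(segs$identity, 1)
  expect_identical(segs$rss3_spacer, 23L)
  expect_true(segs$has_rss)
})

test_that("duplicated templates give distinct non-overlapping segments", {
  set.seed(12)
  v <- random_dna(250)
  g <- paste0(random_dna(300), v, random_dna(5000), v, random_dna(300))
  segs <- locate_segments(g, c(tplV = v), "IGH", "V")
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$start, c(300L, 300L + 250L + 5000L))
  expect_true(all(segs$end[-nrow(segs)] <= segs$start[-1]))
})

test_that("a diverged template is recovered near the planting site,
           matching the sliding-window identity oracle", {
  set.seed(13)
  tpl <- random_dna(300)
  planted <- tpl
  idx <- sample(300, 30)  # 10% substitutions
  for (i in idx) {
    substr(planted, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(planted, i, i)), 1)
  }
  g <- paste0(random_dna(700), planted, random_dna(700))
  segs <- locate_segments(g, c(tplV = tpl), "IGH", "V",
                          min_identity = 0.85)
  expect_identical(nrow(segs), 1L)
  expect_true(segs$identity >= 0.85 && segs$identity <= 1)
  expect_lte(abs(segs$start - 700L), 3L)
  oracle <- sliding_identity_oracle(g, tpl)
  expect_identical(segs$start, oracle$start)
  expect_equal(segs$identity, oracle$identity)
})

test_that("overlapping hits are suppressed in favour of the better score", {
  set.seed(14)
  v <- random_dna(200)
  v_sub <- substr(v, 21, 180)  # contained, shorter, lower score
  g <- paste0(random_dna(100), v, random_dna(100))
  segs <- locate_segments(g, c(long = v, short = v_sub), "IGH", "V")
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$template, "long")
})

test_that("functionality classification applies the stated rules", {
  ref <- fx_ref_igh()
  v <- ovIgSeq:::ref_seq(ref, ref$segments$name[ref$segments$seg_type == "V"][1])
  expect_identical(classify_functionality(v, "V", has_rss = TRUE),
                   "functional")
  expect_identical(classify_functionality(v, "V", has_rss = FALSE), "ORF")
  stopped <- v
  substr(stopped, 133, 135) <- "TAA"
  expect_identical(classify_functionality(stopped, "V", has_rss = TRUE),
                   "pseudogene")
  ## frameshift relative to the template length
  expect_identical(
    classify_functionality(substr(v, 1, nchar(v) - 1), "V", TRUE,
                           template_length = nchar(v)),
    "pseudogene")
  j <- ovIgSeq:::ref_seq(ref, ref$segments$name[ref$segments$seg_type == "J"][1])
  expect_identical(classify_functionality(j, "J", has_rss = TRUE),
                   "functional")
})

test_that("subgroup clustering equals the thresholded-identity graph
           components computed by the all-pairs oracle", {
  set.seed(15)
  ## three families of mutated copies plus one singleton
  proto <- replicate(3, random_dna(240))
  mutate <- function(s, k) {
    for (i in sample(nchar(s), k))
      substr(s, i, i) <- sample(c("A", "C", "G", "T"), 1)
    s
  }
  seqs <- c(vapply(rep(1:3, each = 3), function(f)
    mutate(proto[f], 20), ""), random_dna(240))
  names(seqs) <- paste0("s", seq_along(seqs))
  got <- assign_subgroups(seqs, 0.75)
  want <- identity_components_oracle(seqs, 0.75)
  ## same partition (labels may differ)
  expect_identical(length(unique(got)), length(unique(want)))
  expect_true(all(table(got, want) %in%
                    c(0L, as.vector(table(want)))))
  ## trivial cases
  expect_identical(unname(assign_subgroups(c(a = seqs[[1]], b = seqs[[1]]))),
                   c(1L, 1L))
  two <- c(x = random_dna(200), y = random_dna(200))
  expect_identical(length(unique(assign_subgroups(two))), 2L)
})

test_that("annotating a toy locus reproduces the planted segments and a
           GFF3 round trip preserves the reference", {
  tl <- make_toy_locus(42, "IGH", template_divergence = 0.05)
  ref <- annotate_locus(tl$genome, tl$templates, "IGH",
                        min_identity = 0.8, genome_id = "toy_IGH")
  truth <- tl$reference$segments
  expect_identical(ref$segments$start, truth$start)
  expect_identical(ref$segments$end, truth$end)
  expect_identical(ref$segments$seg_type, truth$seg_type)
  expect_identical(ref$segments$functionality, truth$functionality)
  ## intervals are pairwise non-overlapping within each segment type
  for (st in unique(ref$segments$seg_type)) {
    s <- ref$segments[ref$segments$seg_type == st, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$end[-nrow(s)] <= s$start[-1]))
  }
  pfx <- tempfile()
  write_germline(ref, pfx)
  back <- read_germline(pfx)
  expect_identical(back$segments, ref$segments)
  expect_identical(back$sequences, ref$sequences)
  expect_identical(back$meta, ref$meta)
})

test_that("RSS-pairing nomination proposes a D candidate without templates", {
  set.seed(16)
  d <- random_dna(20)
  rss12 <- function() paste0("CACAGTG", random_dna(12), "ACAAAAACC")
  g <- paste0(random_dna(300), revcomp(rss12()), d, rss12(),
              random_dna(300))
  cand <- nominate_by_rss(g, "IGH", "D", min_len = 8, max_len = 40)
  expect_true(any(cand$start == 300 + 28 & cand$end == 300 + 28 + 20))
})
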