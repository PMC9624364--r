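test_that("length boundaries split reads into fragment, gap and precursor", {
  # one read of every length 15-36 nt mapped to a 70-nt precursor
  lens <- 15:36
  a <- mk_assignments("p1", "tRNA", 0, lens, 70)
  fr <- call_fragments(a, min_reads = 1)
  roles <- setNames(fr$reads$role, fr$reads$insert_length)
  expect_true(all(roles[as.character(15:27)] == "fragment"))
  expect_equal(unname(roles["28"]), "gap")
  expect_true(all(roles[as.character(29:36)] == "precursor"))
  expect_equal(max(fr$reads$insert_length[fr$reads$role == "fragment"]), 27L)
  expect_equal(min(fr$reads$insert_length[fr$reads$role == "precursor"]), 29L)
  # bucket membership changes exactly at the documented boundaries
  for (l in 26:29) {
    one <- call_fragments(mk_assignments("p1", "tRNA", 0, l, 70),
                          min_reads = 1)
    expect_equal(one$reads$role,
                 if (l <= 27) "fragment" else if (l == 28) "gap"
                 else "precursor")
  }
})

test_that("the inclusion filter drops precursors below the read threshold", {
  a <- do.call(rbind, lapply(1:10, function(k) {
    mk_assignments(sprintf("p%02d", k), "tRNA", 0, rep(20, k), 70)
  }))
  a$read_id <- sprintf("r%03d", seq_len(nrow(a)))
  fr <- call_fragments(a)  # default min_reads = 5
  expect_setequal(fr$precursors$precursor_id, sprintf("p%02d", 5:10))
  expect_equal(min(fr$precursors$n_total), 5L)
  expect_false("p04" %in% fr$precursors$precursor_id)
  expect_false(any(fr$reads$precursor_id == "p04"))
})

test_that("end categories follow the tolerance window with 5' precedence", {
  a <- rbind(
    mk_assignments("p1", "rRNA", 0, 20, 70),    # start 0 -> 5'
    mk_assignments("p1", "rRNA", 2, 20, 70),    # start at tolerance -> 5'
    mk_assignments("p1", "rRNA", 50, 20, 70),   # ends at 70 -> 3'
    mk_assignments("p1", "rRNA", 48, 20, 70),   # ends at 68, within 2 -> 3'
    mk_assignments("p1", "rRNA", 20, 20, 70),   # interior -> internal
    mk_assignments("p2", "tRNA", 0, rep(30, 5), 30))  # whole precursor
  a$read_id <- sprintf("r%03d", seq_len(nrow(a)))
  fr <- call_fragments(a)
  r1 <- fr$reads[fr$reads$precursor_id == "p1", ]
  expect_equal(r1$end_category[order(r1$start)],
               c("5prime", "5prime", "internal", "3prime", "3prime"))
  # length-30 reads on a 30-nt precursor are full-length, no end category
  r2 <- fr$reads[fr$reads$precursor_id == "p2", ]
  expect_true(all(r2$role == "precursor"))
  expect_true(all(is.na(r2$end_category)))
  expect_error(call_fragments(a, end_tolerance = -1), "non-negative")
})

test_that("fragment end counts partition the fragment total", {
  p <- tiny_params(seed = 19, n_reads = 3000, internal_rate = 0.1)
  ref <- make_reference(p)
  s <- simulate_sample(p, ref)
  a <- classify_reads(s$reads, ref, p$adaptor)
  fr <- call_fragments(a)
  with(fr$precursors, {
    expect_equal(n_5prime + n_3prime + n_internal, n_fragment)
    expect_equal(n_fragment + n_gap + n_precursor, n_total)
  })
  expect_true(all(fr$precursors$n_total >= 5L))
})

test_that("bin distributions have ten bins summing to one", {
  # degenerate: all fragments 5'-anchored -> all mass in bin 1
  a <- mk_assignments("p1", "snoRNA", 0, rep(20, 10), 70)
  a$read_id <- sprintf("r%03d", seq_len(nrow(a)))
  bd <- bin_distribution(call_fragments(a))
  expect_equal(nrow(bd), 10L)
  expect_equal(bd$bin, 1:10)
  expect_equal(bd$proportion[1], 1)
  expect_equal(sum(bd$proportion), 1)

  # class without fragments: flagged empty, all-zero, not an error
  a2 <- mk_assignments("p2", "rRNA", 0, rep(30, 6), 120)
  a2$read_id <- sprintf("q%03d", seq_len(nrow(a2)))
  bd2 <- bin_distribution(call_fragments(a2))
  expect_true(all(bd2$empty))
  expect_equal(sum(bd2$proportion), 0)
})

test_that("uniform fragment starts spread evenly over the bins", {
  withr::with_seed(55, {
    L <- 1000L
    starts <- sample(0:(L - 15L), 10000, replace = TRUE)
    a <- mk_assignments("p1", "tRNA", starts, 15, L)
    a$read_id <- sprintf("r%05d", seq_len(nrow(a)))
    bd <- bin_distribution(call_fragments(a))
    # multinomial expectation: bin b holds the fraction of the uniform
    # support 0..L-15 that falls inside it
    support <- L - 15L + 1L
    expected <- vapply(1:10, function(b) {
      lo <- floor((b - 1) * L / 10); hi <- floor(b * L / 10)
      (min(hi, support) - lo) / support
    }, numeric(1))
    expect_true(all(abs(bd$proportion - expected) <= 0.02))
    expect_equal(sum(bd$proportion), 1, tolerance = 1e-12)
  })
})

test_that("enrichment ratios follow the fragment/precursor definition", {
  a <- rbind(mk_assignments("p1", "tRNA", 0, rep(20, 10), 70),
             mk_assignments("p1", "tRNA", 0, rep(29, 10), 70))
  a$read_id <- sprintf("r%03d", seq_len(nrow(a)))
  en <- enrichment(call_fragments(a))
  expect_equal(names(en), c("precursor_id", "class", "n_fragment",
                            "n_precursor", "ratio", "defined"))
  expect_equal(en$ratio, 1)

  # zero numerator
  a0 <- mk_assignments("p1", "tRNA", 0, rep(29, 5), 70)
  a0$read_id <- sprintf("r%03d", seq_len(nrow(a0)))
  expect_equal(enrichment(call_fragments(a0))$ratio, 0)

  # zero denominator: missing value, row retained and flagged
  af <- mk_assignments("p1", "tRNA", 0, rep(20, 7), 70)
  af$read_id <- sprintf("r%03d", seq_len(nrow(af)))
  enf <- enrichment(call_fragments(af))
  expect_equal(nrow(enf), 1L)
  expect_true(is.na(enf$ratio))
  expect_false(enf$defined)
})

test_that("family aggregation sums counts before dividing", {
  a <- rbind(
    mk_assignments("t1", "tRNA", 0, rep(20, 6), 70, family = "GlyGCC"),
    mk_assignments("t1", "tRNA", 0, rep(29, 2), 70, family = "GlyGCC"),
    mk_assignments("t2", "tRNA", 0, rep(20, 2), 70, family = "GlyGCC"),
    mk_assignments("t2", "tRNA", 0, rep(29, 6), 70, family = "GlyGCC"))
  a$read_id <- sprintf("r%03d", seq_len(nrow(a)))
  fam <- enrichment(call_fragments(a), by = "family")
  expect_equal(nrow(fam), 1L)
  expect_equal(fam$family, "GlyGCC")
  # (6+2)/(2+6), not mean(6/2, 2/6)
  expect_equal(fam$ratio, 1)
})

test_that("prorating rescales pools to the reference library size", {
  counts <- data.frame(pool = c("FC_SR_M", "CER_Ct_F"),
                       count = c(100, 100))
  totals <- c(FC_SR_M = 2e6, CER_Ct_F = 1e6)
  out <- prorate(counts, totals, "FC_SR_M")
  expect_equal(out$count_prorated, c(100, 200))  # half-depth pool doubled
  expect_equal(unname(attr(out, "factors")["FC_SR_M"]), 1)
  # prorating each pool's total equals the reference total (algebraic
  # identity checked numerically)
  tot_df <- data.frame(pool = names(totals), count = unname(totals))
  tot_out <- prorate(tot_df, totals, "FC_SR_M")
  expect_equal(tot_out$count_prorated, rep(2e6, 2))
  expect_error(prorate(counts, c(FC_SR_M = 2e6, CER_Ct_F = 0), "FC_SR_M"),
               "zero assigned")
  expect_error(prorate(counts, totals, "nope"), "reference pool")
})

test_that("end-bias summaries recover degenerate and biased mixtures", {
  a <- rbind(
    mk_assignments("t1", "tRNA", 0, rep(20, 10), 70),        # all 5'
    mk_assignments("s1", "snoRNA", 50, rep(20, 4), 70),      # 3'
    mk_assignments("s1", "snoRNA", 0, rep(20, 6), 70),       # 5'
    mk_assignments("r1", "rRNA", 25, rep(20, 5), 70))        # internal only
  a$read_id <- sprintf("r%03d", seq_len(nrow(a)))
  efs <- end_fraction_summary(call_fragments(a))
  cls <- efs$classes
  expect_equal(cls$frac_5prime[cls$class == "tRNA"], 1)
  expect_equal(cls$frac_5prime[cls$class == "snoRNA"], 0.6)
  expect_false(cls$informative[cls$class == "rRNA"])
  expect_true(is.na(cls$frac_5prime[cls$class == "rRNA"]))
})

test_that("simulated end bias is recovered within binomial error", {
  p <- simulation_params(seed = 23, n_reads = 4000,
                         class_weights = c("tRNA" = 1),
                         end_bias = c("tRNA" = 0.7),
                         n_precursors_per_class = 3)
  ref <- make_reference(p)
  s <- simulate_sample(p, ref)
  a <- classify_reads(s$reads, ref, p$adaptor)
  efs <- end_fraction_summary(call_fragments(a))
  f5 <- efs$classes$frac_5prime[efs$classes$class == "tRNA"]
  expect_gt(f5, 0.65)
  expect_lt(f5, 0.75)
})
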