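test_that("obs_exp_ratio follows N_CpG * N / (N_C * N_G) with zero-denominator convention", {
  expect_equal(obs_exp_ratio("CGCGCGCG"), 2)
  expect_equal(obs_exp_ratio("AAAA"), 0)
  expect_equal(obs_exp_ratio("CCCC"), 0) # no G
  expect_equal(obs_exp_ratio("ACGT"), 1 * 4 / (1 * 1))
  expect_error(obs_exp_ratio(""), "non-empty")
  # ambiguity characters count as neither C nor G and never form a CpG
  expect_equal(obs_exp_ratio("CNGA"), 0 * 4 / (1 * 1))

  set.seed(21)
  for (i in 1:25) {
    s <- random_seq(sample(5:200, 1))
    expect_equal(obs_exp_ratio(s), brute_obs_exp(s))
  }
})

test_that("window_profile emits one window per shifted start with direct statistics", {
  g <- genome_record(strrep("A", 100))
  prof <- window_profile(g, scan_params(window = 100))
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$pct_cg, 0)
  expect_equal(prof$obs_exp, 0)

  g <- genome_record(random_seq(300))
  prof <- window_profile(g, scan_params(window = 100, shift = 1))
  expect_equal(nrow(prof), 201L)
  expect_equal(prof$window_start, 1:201)
  # spot-check a few windows against direct recomputation
  for (st in c(1, 57, 201)) {
    win <- substr(g$sequence, st, st + 99)
    expect_equal(prof$obs_exp[st], brute_obs_exp(win))
    expect_equal(
      prof$pct_cg[st],
      100 * (count_char(win, "C") + count_char(win, "G")) / 100
    )
  }
  expect_error(
    window_profile(genome_record("ACGT"), scan_params(window = 100)),
    "shorter than window"
  )
})

test_that("per-window statistics are invariant under reverse complement", {
  # pct_cg and obs_exp of a window equal those of its reverse complement, so
  # the profile of the H strand is the value-wise mirror of the L strand
  set.seed(22)
  p <- scan_params(window = 40, shift = 1, min_length = 40)
  for (i in 1:10) {
    g <- genome_record(random_seq(250))
    rc <- reverse_complement(g)
    pf <- window_profile(g, p)
    pr <- window_profile(rc, p)
    expect_equal(pf$pct_cg, rev(pr$pct_cg))
    expect_equal(pf$obs_exp, rev(pr$obs_exp))
  }
})

test_that("call_islands recovers a planted CpG block and nothing else", {
  set.seed(23)
  for (i in 1:5) {
    at <- sample(300:1500, 1)
    s <- planted_block_seq(n = 2000, at = at, block = 250)
    isl <- call_islands(genome_record(s))
    expect_equal(nrow(isl), 1L)
    expect_lte(abs(isl$start - at), 100)
    expect_lte(abs(isl$end - (at + 249)), 100)
    # aggregate statistics recomputed from the subsequence match exactly
    sub <- substr(s, isl$start, isl$end)
    expect_equal(isl$length, nchar(sub))
    expect_equal(isl$cg_sum, count_char(sub, "C") + count_char(sub, "G"))
    expect_equal(isl$pct_cg, 100 * isl$cg_sum / isl$length)
    expect_equal(isl$obs_exp, brute_obs_exp(sub))
  }
  expect_equal(nrow(call_islands(genome_record(strrep("A", 2000)))), 0L)
})

test_that("every emitted island satisfies the three criteria, disjoint and sorted", {
  set.seed(24)
  p <- scan_params(window = 30, shift = 1, min_length = 60, min_obs_exp = 0.6,
                   min_pct_cg = 50)
  n_with_islands <- 0L
  for (i in 1:40) {
    g <- genome_record(random_seq(sample(200:800, 1), p_cg = runif(1, 0.45, 0.75)))
    isl <- call_islands(g, p)
    if (nrow(isl) == 0) next
    n_with_islands <- n_with_islands + 1L
    expect_true(all(isl$length >= p$min_length))
    expect_true(all(isl$pct_cg >= p$min_pct_cg))
    expect_true(all(isl$obs_exp >= p$min_obs_exp))
    expect_true(all(diff(isl$start) > 0))
    if (nrow(isl) > 1) {
      expect_true(all(isl$start[-1] > isl$end[-nrow(isl)] + 1))
    }
  }
  expect_gt(n_with_islands, 5L) # the generator actually exercised the caller
})

test_that("call_islands agrees with the per-base brute-force oracle", {
  set.seed(25)
  for (attribution in c("cover", "midpoint")) {
    for (i in 1:15) {
      p <- scan_params(
        window = sample(c(20, 30, 50), 1), shift = sample(c(1, 3), 1),
        min_length = 60, min_obs_exp = runif(1, 0.4, 0.8),
        min_pct_cg = runif(1, 40, 60)
      )
      g <- genome_record(random_seq(sample(150:600, 1), p_cg = runif(1, 0.4, 0.7)))
      got <- call_islands(g, p, attribution = attribution)
      want <- brute_islands(g$sequence, p, attribution = attribution)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("island_report labels islands with overlapped features and rounds half-up", {
  s <- planted_block_seq(n = 1200, at = 500, block = 260)
  g <- genome_record(s)
  ft <- feature_table(
    name = c("ND1", "ND2"), start = c(1, 601), end = c(600, 1200),
    genome_length = 1200
  )
  isl <- call_islands(g)
  rep <- island_report(isl, ft, genome_length = g$length)
  expect_equal(nrow(rep), 1L)
  expect_match(rep$region, "ND1")
  expect_equal(rep$pct_cg, round(floor(isl$pct_cg * 100 + 0.5) / 100, 10))
  expect_equal(
    nrow(island_report(call_islands(genome_record(strrep("A", 300))))),
    0L
  )
})

test_that("circular scanning finds an island spanning the sequence origin", {
  # half the CG block at each end of the linearized circle; each half plus
  # its window-rule extension stays below min_length, the joined block does
  # not
  s <- paste0(
    strrep("CG", 55), strrep("AT", 425), strrep("CG", 55)
  )
  g <- genome_record(s, topology = "circular")
  linear <- call_islands(g)
  expect_equal(nrow(linear), 0L) # each half is below min_length
  circ <- call_islands(g, circular = TRUE)
  expect_equal(nrow(circ), 1L)
  expect_gt(circ$start, circ$end) # reported as an origin-wrapping interval
})
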