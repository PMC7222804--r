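test_that("the background generator is deterministic and leaves the caller's RNG alone", {
  spec <- synth_spec(length = 3000, islands = NULL, seed = 42)
  g1 <- generate_background(spec)
  g2 <- generate_background(spec)
  expect_identical(g1$sequence, g2$sequence)
  expect_false(identical(
    g1$sequence,
    generate_background(synth_spec(length = 3000, islands = NULL, seed = 43))$sequence
  ))
  set.seed(99)
  before <- .Random.seed
  invisible(generate_background(spec))
  expect_identical(.Random.seed, before)
})

test_that("background composition matches the requested GC and obs/exp", {
  spec <- synth_spec(
    length = 16500, background_gc = 0.4, background_obs_exp = 0.25,
    islands = NULL, seed = 1
  )
  g <- generate_background(spec)
  gc <- (count_char(g$sequence, "C") + count_char(g$sequence, "G")) / g$length
  expect_lt(abs(gc - 0.40), 0.02)
  expect_lt(abs(brute_obs_exp(g$sequence) - 0.25), 0.05)
})

test_that("mean composition over many seeds is unbiased", {
  gcs <- numeric(0)
  oes <- numeric(0)
  for (seed in 1:50) {
    spec <- synth_spec(
      length = 4000, background_gc = 0.42, background_obs_exp = 0.30,
      islands = NULL, seed = seed
    )
    g <- generate_background(spec)
    gcs <- c(gcs, (count_char(g$sequence, "C") + count_char(g$sequence, "G")) / g$length)
    oes <- c(oes, brute_obs_exp(g$sequence))
  }
  expect_lt(abs(mean(gcs) - 0.42), 0.01)
  expect_lt(abs(mean(oes) - 0.30), 0.03)
})

test_that("obs/exp of zero forbids CG dinucleotides entirely", {
  spec <- synth_spec(
    length = 5000, background_obs_exp = 0, islands = NULL, seed = 7
  )
  g <- generate_background(spec)
  expect_equal(count_char(g$sequence, "CG"), 0L)
})

test_that("infeasible composition requests are rejected", {
  expect_error(
    generate_background(
      synth_spec(background_gc = 0.9, background_obs_exp = 3, islands = NULL)
    ),
    "infeasible"
  )
  expect_error(
    synth_spec(islands = data.frame(
      position = c(100, 200), length = c(300, 300), gc = 0.55, obs_exp = 1.2
    )),
    "overlap"
  )
  expect_error(
    synth_spec(
      length = 1000,
      islands = data.frame(position = 900, length = 300, gc = 0.55, obs_exp = 1.2)
    ),
    "outside"
  )
})

test_that("planted islands carry their own composition and a faithful truth table", {
  spec <- synth_spec(seed = 5)
  out <- generate_mito_genome(spec)
  expect_equal(out$genome$length, spec$length)
  expect_equal(nrow(out$truth), 2L)
  expect_equal(out$truth$start, spec$islands$position)
  for (i in seq_len(nrow(out$truth))) {
    sub <- substr(out$genome$sequence, out$truth$start[i], out$truth$end[i])
    gc <- (count_char(sub, "C") + count_char(sub, "G")) / nchar(sub)
    expect_lt(abs(gc - out$truth$gc[i]), 0.08)
    expect_gt(brute_obs_exp(sub), 0.8)
  }
  # regeneration with the same spec is byte-identical
  out2 <- generate_mito_genome(spec)
  expect_identical(out$genome$sequence, out2$genome$sequence)
  expect_identical(out$truth, out2$truth)
})

test_that("the caller recovers planted islands and ignores sub-threshold ones", {
  spec <- synth_spec(seed = 11)
  out <- generate_mito_genome(spec)
  isl <- call_islands(out$genome)
  expect_equal(nrow(isl), nrow(out$truth))
  for (i in seq_len(nrow(out$truth))) {
    expect_lte(abs(isl$start[i] - out$truth$start[i]), 100)
    expect_lte(abs(isl$end[i] - out$truth$end[i]), 100)
  }
  # an island at the background's own composition is not required and a
  # zero-island spec yields no calls
  quiet <- generate_mito_genome(synth_spec(islands = NULL, seed = 11))
  expect_equal(nrow(call_islands(quiet$genome)), 0L)
})

test_that("the canonical feature layout tiles the genome without overlap", {
  ft <- generate_feature_layout(16500)
  expect_s3_class(ft, "feature_table")
  expect_equal(nrow(ft), 39L) # 37 genes + rep_origin + D-loop
  expect_true(all(c("TRNF", "12s rRNA", "CYTB", "D-LOOP", "rep_origin") %in% ft$name))
  o <- order(ft$start)
  expect_true(all(ft$start[o][-1] > ft$end[o][-nrow(ft)]))
  expect_equal(ft$start[o][1], 1L)
  expect_equal(max(ft$end), 16500L)
  expect_error(generate_feature_layout(800), "too short")
  # compact invertebrate-like genomes scale the same gene complement down
  compact <- generate_feature_layout(14000)
  expect_equal(nrow(compact), 39L)
  o <- order(compact$start)
  expect_true(all(compact$start[o][-1] > compact$end[o][-nrow(compact)]))
  expect_lte(max(compact$end), 14000L)
})

test_that("an origin-wrapping D-loop splits into spans totalling its length", {
  ft <- generate_feature_layout(16500, dloop_wraps = TRUE)
  dl <- ft[ft$name == "D-LOOP", ]
  expect_true(dl$wraps_origin)
  expect_gt(dl$start, dl$end)
  spans <- mitocpg:::feature_spans(ft, 16500)
  dsp <- spans[spans$name == "D-LOOP", ]
  expect_equal(nrow(dsp), 2L)
  expect_equal(
    sum(dsp$end - dsp$start + 1),
    mitocpg:::feature_length(ft, 16500)[ft$name == "D-LOOP"]
  )
})

test_that("a planted island inside ND5 is classified as single_feature(ND5)", {
  ft <- generate_feature_layout(16500)
  nd5 <- ft[ft$name == "ND5", ]
  spec <- synth_spec(
    islands = data.frame(
      position = nd5$start + 200L, length = 400L, gc = 0.55, obs_exp = 1.2
    ),
    seed = 8
  )
  out <- generate_mito_genome(spec)
  regions <- seek_regions(out$genome)
  ann <- classify_regions(regions, out$features, genome_length = 16500)
  inside <- ann[ann$start >= nd5$start & ann$end <= nd5$end, ]
  expect_gt(nrow(inside), 0L)
  expect_true(all(inside$classification == "single_feature"))
  expect_true(all(inside$features == "ND5"))
})
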