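toy_features <- function() {
  feature_table(
    name = c("ND1", "TRNW", "ND5", "intergenic region", "D-LOOP"),
    kind = c("protein_gene", "tRNA", "protein_gene", "intergenic", "noncoding"),
    start = c(1, 5, 9, 20, 900),
    end = c(4, 8, 19, 30, 100),
    wraps_origin = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    genome_length = 1000
  )
}

test_that("overlap_features requires >= 1 bp overlap and orders by position", {
  ft <- toy_features()[1:4, ] # drop the wrapping D-loop: it covers 1..100
  expect_equal(nrow(overlap_features(5, 8, ft[1, ], genome_length = 1000)), 0L)
  hits <- overlap_features(4, 5, ft, genome_length = 1000)
  expect_equal(hits$name, c("ND1", "TRNW"))
  # identical interval overlaps itself (reflexive)
  expect_equal(
    overlap_features(9, 19, ft, genome_length = 1000)$name[1], "ND5"
  )
})

test_that("origin-wrapping features overlap through both spans and conserve length", {
  ft <- toy_features()
  # D-LOOP wraps 900..1000 + 1..100 and is found from either side
  expect_true("D-LOOP" %in% overlap_features(950, 960, ft, 1000)$name)
  expect_true("D-LOOP" %in% overlap_features(50, 60, ft, 1000)$name)
  expect_false("D-LOOP" %in% overlap_features(200, 300, ft, 1000)$name)
  spans <- mitocpg:::feature_spans(ft, 1000)
  dl <- spans[spans$name == "D-LOOP", ]
  expect_equal(nrow(dl), 2L)
  expect_equal(
    sum(dl$end - dl$start + 1),
    mitocpg:::feature_length(ft, 1000)[ft$name == "D-LOOP"]
  )
})

test_that("classify_regions distinguishes single-, multi-feature and intergenic regions", {
  ft <- toy_features()[1:4, ] # drop the wrapping D-loop: it covers 1..100
  regions <- data.frame(
    start = c(10, 3, 22, 400),
    end = c(15, 7, 28, 450),
    cpg_count = c(5L, 3L, 2L, 4L),
    strand = c("L", "L", "L", "H")
  )
  ann <- classify_regions(regions, ft, genome_length = 1000)
  expect_equal(ann$classification, c(
    "single_feature", "multi_feature", "intergenic", "intergenic"
  ))
  expect_equal(ann$features[1], "ND5")
  expect_match(ann$features[2], "ND1")
  expect_match(ann$features[2], "TRNW")
  expect_equal(ann$features[4], "intergenic region")
})

test_that("build_summary counts each region once and conserves strand totals", {
  ft <- toy_features()[1:4, ] # drop the wrapping D-loop: it covers 1..100
  regions <- data.frame(
    start = c(10, 3, 22, 10),
    end = c(15, 7, 28, 18),
    cpg_count = c(5L, 3L, 2L, 7L),
    strand = c("L", "L", "L", "H")
  )
  ann <- classify_regions(regions, ft, genome_length = 1000)
  summ <- build_summary(ann, species = "toy")
  # strand totals conserve every region's count exactly once
  expect_equal(unname(summ$strand_totals["L"]), 5 + 3 + 2)
  expect_equal(
    unname(summ$strand_totals["L"]),
    region_sites(cbind(regions, score = 0)[regions$strand == "L", ])
  )
  expect_equal(unname(summ$strand_totals["H"]), 7)
  # the multi-feature region appears in the multi table, not in per-feature counts
  expect_equal(nrow(summ$multi_feature), 1L)
  expect_equal(summ$counts$L[summ$counts$feature == "ND1"], numeric(0))
  expect_equal(summ$counts$L[summ$counts$feature == "ND5"], 5)
  expect_equal(summ$counts$H[summ$counts$feature == "ND5"], 7)
  # per-feature sums plus multi-feature and intergenic counts equal the total
  expect_equal(
    sum(summ$counts$L) + sum(summ$multi_feature$cpg_count[summ$multi_feature$strand == "L"]),
    unname(summ$strand_totals["L"])
  )
})

test_that("an empty annotation set produces an all-zero summary", {
  ann <- classify_regions(
    data.frame(
      start = integer(0), end = integer(0), cpg_count = integer(0),
      strand = character(0)
    ),
    toy_features()[1:4, ], genome_length = 1000
  )
  summ <- build_summary(ann, species = "empty")
  expect_equal(unname(summ$strand_totals), c(0, 0))
  expect_equal(nrow(summ$counts), 0L)
})

test_that("proportional split divides a multi-feature region by overlap length", {
  ft <- feature_table(
    name = c("A1", "B1"), start = c(1, 11), end = c(10, 30),
    kind = "protein_gene", genome_length = 100
  )
  regions <- data.frame(start = 6, end = 25, cpg_count = 12L, strand = "L")
  ann <- classify_regions(regions, ft, genome_length = 100)
  summ <- build_summary(ann,
    proportional_split = TRUE, ft = ft, genome_length = 100
  )
  # overlaps: A1 gets 5 bp, B1 gets 15 bp of the 20 bp region
  expect_equal(summ$counts$L[summ$counts$feature == "A1"], 12 * 5 / 20)
  expect_equal(summ$counts$L[summ$counts$feature == "B1"], 12 * 15 / 20)
  expect_equal(sum(summ$counts$L), 12)
})

test_that("compare_species aligns features and reports group means", {
  mk <- function(species, group, nd1_L, nd1_H) {
    ann <- data.frame(
      start = c(1, 5), end = c(3, 8), strand = c("L", "H"),
      cpg_count = c(nd1_L, nd1_H),
      features = "ND1", n_features = 1L, classification = "single_feature"
    )
    build_summary(ann, species = species, group = group)
  }
  a <- mk("sp1", "vertebrate", 4, 6)
  b <- mk("sp2", "invertebrate", 4, 6)
  cmp <- compare_species(list(a, b))
  # identical summaries: zero between-group difference
  gm <- cmp$group_means
  expect_equal(
    gm$mean_total[gm$group == "vertebrate"],
    gm$mean_total[gm$group == "invertebrate"]
  )
  expect_true("ND1" %in% cmp$widespread)

  c1 <- mk("sp3", "vertebrate", 10, 10)
  c2 <- mk("sp4", "invertebrate", 20, 20)
  gm <- compare_species(list(c1, c2))$group_means
  expect_equal(gm$mean_total[gm$group == "vertebrate"], c(10, 10))
  expect_equal(gm$mean_total[gm$group == "invertebrate"], c(20, 20))
})

test_that("feature names canonicalize to comparative-table labels", {
  expect_equal(
    canonical_feature_names(
      c("tRNA-Trp", "COII", "MT-ND1", "s-rRNA", "cytb", "D-loop", "NAD5"),
      warn = FALSE
    ),
    c("TRNW", "COX2", "ND1", "12s rRNA", "CYTB", "D-LOOP", "ND5")
  )
  expect_equal(canonical_feature_names("tRNA-Leu 1", warn = FALSE), "TRNL1")
  expect_warning(
    out <- canonical_feature_names("mystery_orf"),
    "mystery_orf"
  )
  expect_equal(out, "mystery_orf")
})
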