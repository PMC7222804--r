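#' Canonical mtDNA locus names
#'
#' Maps common GenBank spellings of animal mtDNA loci (e.g. `tRNA-Trp`,
#' `COII`, `MT-ND1`, `s-rRNA`) to the canonical labels used in comparative
#' tables (`TRNW`, `COX2`, `ND1`, `12s rRNA`, ...). Unmapped names pass
#' through unchanged with a warning.
#'
#' @param names Character vector of locus names.
#' @param warn Warn about names that could not be canonicalized.
#' @return Character vector of canonical names.
#' @export
canonical_feature_names <- function(names, warn = TRUE) {
  aa3 <- c(
    Phe = "F", Val = "V", Leu = "L", Ile = "I", Gln = "Q", Met = "M",
    Trp = "W", Ala = "A", Asn = "N", Cys = "C", Tyr = "Y", Ser = "S",
    Asp = "D", Lys = "K", Gly = "G", Arg = "R", His = "H", Glu = "E",
    Thr = "T", Pro = "P"
  )
  out <- character(length(names))
  unmatched <- character(0)
  for (i in seq_along(names)) {
    nm <- names[i]
    up <- toupper(gsub("[ _]", "", nm))
    up <- sub("^MT-", "", up)
    res <- NA_character_
    if (grepl("^TRN[A-Z][0-9]?$", up)) {
      res <- up
    } else if (grepl("^TRNA-", up)) {
      code <- sub("^TRNA-", "", up)
      three <- substr(code, 1, 3)
      hit <- aa3[toupper(names(aa3)) == three]
      if (length(hit) == 1) {
        # tRNA-Leu / tRNA-Ser exist twice; keep a trailing 1/2 if present
        suffix <- sub("^[A-Z]{3}", "", code)
        suffix <- gsub("[^0-9]", "", suffix)
        res <- paste0("TRN", hit, suffix)
      }
    } else if (up %in% c("12SRRNA", "RRNS", "S-RRNA", "SSURRNA", "12SRIBOSOMALRNA")) {
      res <- "12s rRNA"
    } else if (up %in% c("16SRRNA", "RRNL", "L-RRNA", "LSURRNA", "16SRIBOSOMALRNA")) {
      res <- "16s rRNA"
    } else if (grepl("^CO(X)?I$|^COX?1$", up)) {
      res <- "COX1"
    } else if (grepl("^CO(X)?II$|^COX?2$", up)) {
      res <- "COX2"
    } else if (grepl("^CO(X)?III$|^COX?3$", up)) {
      res <- "COX3"
    } else if (grepl("^ND[1-6]L?$|^NAD[1-6]L?$", up)) {
      res <- sub("^NAD", "ND", up)
    } else if (up %in% c("CYTB", "COB", "CYB")) {
      res <- "CYTB"
    } else if (up %in% c("ATP6", "ATPASE6", "ATP8", "ATPASE8")) {
      res <- sub("ATPASE", "ATP", up)
    } else if (grepl("^D-?LOOP$|^CONTROLREGION$", up)) {
      res <- "D-LOOP"
    } else if (grepl("^REP_?ORIGIN$|^OL$|^O_L$|^ORIL$", up)) {
      res <- "rep_origin"
    } else if (grepl("^AT-?REGION$", up)) {
      res <- "AT-REGION"
    } else if (grepl("^INTERGENIC", up)) {
      res <- "intergenic region"
    }
    if (is.na(res)) {
      unmatched <- c(unmatched, nm)
      res <- nm
    }
    out[i] <- res
  }
  if (warn && length(unmatched) > 0) {
    warning(
      "feature names passed through without canonical mapping: ",
      paste(unique(unmatched), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

# Split origin-wrapping features into two reference-frame spans so interval
# arithmetic stays linear. Adds a `.row` column pointing back at the original
# feature row.
feature_spans <- function(ft, genome_length = NULL) {
  wraps <- ft$wraps_origin
  if (any(wraps) && is.null(genome_length)) {
    stop("`genome_length` is required when features wrap the origin",
      call. = FALSE
    )
  }
  plain <- ft[!wraps, , drop = FALSE]
  plain$.row <- which(!wraps)
  if (!any(wraps)) {
    return(plain)
  }
  w <- ft[wraps, , drop = FALSE]
  upper <- w
  upper$end <- rep(genome_length, nrow(w))
  upper$.row <- which(wraps)
  lower <- w
  lower$start <- rep(1L, nrow(w))
  lower$.row <- which(wraps)
  out <- rbind(plain, upper, lower)
  out[order(out$start), , drop = FALSE]
}

#' Features overlapping an interval
#'
#' Returns all features with at least 1 bp of overlap with `start..end`
#' (reference frame), ordered by genomic position. Origin-wrapping features
#' are split into their two spans for the test and reported once.
#'
#' @param start,end 1-based inclusive interval in the reference frame.
#' @param ft A [feature_table()].
#' @param genome_length Needed when `ft` contains origin-wrapping features.
#' @return The overlapped rows of `ft` (possibly zero rows).
#' @export
overlap_features <- function(start, end, ft, genome_length = NULL) {
  stopifnot(length(start) == 1L, length(end) == 1L, start <= end)
  spans <- feature_spans(ft, genome_length)
  if (nrow(spans) == 0) {
    return(ft[integer(0), , drop = FALSE])
  }
  q <- IRanges::IRanges(start = as.integer(start), end = as.integer(end))
  s <- IRanges::IRanges(start = spans$start, end = spans$end)
  hits <- IRanges::findOverlaps(q, s, minoverlap = 1L)
  rows <- unique(spans$.row[S4Vectors::subjectHits(hits)])
  out <- ft[rows, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Classify detected regions against a feature table
#'
#' Attributes each detected region (reference-frame coordinates) to the
#' features it overlaps by at least 1 bp, and classifies it as
#' `single_feature`, `multi_feature` (two or more named features) or
#' `intergenic` (no feature, or only intergenic spacers). Multi-feature rows
#' are the analogue of a "regions overlapping more than one gene" table;
#' single-feature counts feed the per-gene distribution table.
#'
#' @param regions A `data.frame` with columns `start`, `end`, `cpg_count` and
#'   `strand` (e.g. from [seek_regions()], H-strand rows already mapped with
#'   [map_interval_to_reference()]).
#' @param ft A [feature_table()].
#' @param genome_length Needed when `ft` has origin-wrapping features.
#' @return A `data.frame` of class `region_annotations` with columns `start`,
#'   `end`, `strand`, `cpg_count`, `features` (comma-separated names),
#'   `n_features`, `classification`.
#' @export
classify_regions <- function(regions, ft, genome_length = NULL) {
  n <- nrow(regions)
  feats <- character(n)
  nf <- integer(n)
  cls <- character(n)
  for (i in seq_len(n)) {
    hits <- overlap_features(regions$start[i], regions$end[i], ft,
      genome_length = genome_length
    )
    named <- hits[hits$kind != "intergenic", , drop = FALSE]
    nms <- unique(named$name)
    feats[i] <- paste(unique(hits$name), collapse = ", ")
    nf[i] <- length(nms)
    cls[i] <- if (length(nms) >= 2) {
      "multi_feature"
    } else if (length(nms) == 1) {
      "single_feature"
    } else {
      "intergenic"
    }
    if (cls[i] == "intergenic" && feats[i] == "") {
      feats[i] <- "intergenic region"
    }
  }
  out <- data.frame(
    start = regions$start, end = regions$end,
    strand = regions$strand, cpg_count = regions$cpg_count,
    features = feats, n_features = nf, classification = cls,
    stringsAsFactors = FALSE
  )
  class(out) <- c("region_annotations", "data.frame")
  out
}

#' Per-species CpG-site summary
#'
#' Builds the per-feature, per-strand CpG-site matrix of one species from
#' classified regions of both strands. A region overlapping a single feature
#' contributes its whole CpG count to that feature; a multi-feature or
#' intergenic region contributes to the strand total only (each region is
#' counted exactly once, so the strand total equals the per-feature sum plus
#' the multi-feature and intergenic counts).
#'
#' @param annotations A [classify_regions()] result covering both strands
#'   (or a list of them, concatenated).
#' @param species Species label or accession.
#' @param group Optional group label (e.g. `"vertebrate"`/`"invertebrate"`).
#' @param proportional_split If `TRUE`, a multi-feature region's CpG count is
#'   instead divided across its features in proportion to overlap length
#'   (requires `ft` and `genome_length`); off by default.
#' @param ft,genome_length Only used for `proportional_split`.
#' @return A list of class `species_summary` with elements `species`,
#'   `group`, `counts` (data.frame `feature`, `L`, `H`), `strand_totals`
#'   (named numeric, `L` and `H`), `multi_feature` (the multi-feature rows).
#' @export
build_summary <- function(annotations, species = "species", group = NA_character_,
                          proportional_split = FALSE, ft = NULL,
                          genome_length = NULL) {
  if (is.list(annotations) && !is.data.frame(annotations)) {
    annotations <- do.call(rbind, annotations)
  }
  ann <- as.data.frame(annotations)
  totals <- c(L = 0, H = 0)
  for (s in c("L", "H")) {
    totals[s] <- sum(ann$cpg_count[ann$strand == s])
  }
  tally <- list()
  add <- function(tally, feature, strand, count) {
    key <- paste0(feature, "\r", strand)
    tally[[key]] <- (if (is.null(tally[[key]])) 0 else tally[[key]]) + count
    tally
  }
  for (i in seq_len(nrow(ann))) {
    if (ann$classification[i] == "single_feature") {
      tally <- add(tally, ann$features[i], ann$strand[i], ann$cpg_count[i])
    } else if (ann$classification[i] == "multi_feature" && proportional_split) {
      if (is.null(ft)) {
        stop("`proportional_split` requires `ft`", call. = FALSE)
      }
      hits <- overlap_features(ann$start[i], ann$end[i], ft,
        genome_length = genome_length
      )
      hits <- hits[hits$kind != "intergenic", , drop = FALSE]
      ov <- pmin(hits$end, ann$end[i]) - pmax(hits$start, ann$start[i]) + 1L
      share <- ann$cpg_count[i] * ov / sum(ov)
      for (k in seq_len(nrow(hits))) {
        tally <- add(tally, hits$name[k], ann$strand[i], share[k])
      }
    } else if (ann$classification[i] == "intergenic") {
      tally <- add(tally, "intergenic region", ann$strand[i], ann$cpg_count[i])
    }
  }
  keys <- names(tally)
  if (length(keys) > 0) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    fdf <- data.frame(
      feature = vapply(parts, `[`, character(1), 1),
      strand = vapply(parts, `[`, character(1), 2),
      count = unlist(tally, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    feats <- unique(fdf$feature)
    counts <- data.frame(
      feature = feats,
      L = vapply(feats, function(f) {
        sum(fdf$count[fdf$feature == f & fdf$strand == "L"])
      }, numeric(1)),
      H = vapply(feats, function(f) {
        sum(fdf$count[fdf$feature == f & fdf$strand == "H"])
      }, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    counts <- data.frame(
      feature = character(0), L = numeric(0), H = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  multi <- ann[ann$classification == "multi_feature", , drop = FALSE]
  structure(
    list(
      species = species, group = group, counts = counts,
      strand_totals = totals, multi_feature = multi
    ),
    class = "species_summary"
  )
}

#' @export
print.species_summary <- function(x, ...) {
  cat(sprintf(
    "<species_summary> %s%s | CpG sites L=%g H=%g | %d feature(s), %d multi-feature region(s)\n",
    x$species, if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
    x$strand_totals["L"], x$strand_totals["H"],
    nrow(x$counts), nrow(x$multi_feature)
  ))
  invisible(x)
}

#' Cross-species comparative table
#'
#' Merges per-species summaries into a features x species x strand matrix
#' (the comparative-distribution layout), aligning features by canonical
#' locus name, plus per-group mean strand totals and a flag for features
#' populated in at least `min_species` species.
#'
#' @param summaries List of [build_summary()] results (>= 2).
#' @param min_species Threshold for the `widespread` flag.
#' @return A list of class `species_comparison` with elements `matrix` (long
#'   data.frame `feature`, `species`, `group`, `strand`, `count`), `totals`
#'   (per species/strand), `group_means` (per group/strand),
#'   `widespread` (features populated in >= `min_species` species).
#' @export
compare_species <- function(summaries, min_species = 2L) {
  stopifnot(length(summaries) >= 2L)
  long <- do.call(rbind, lapply(summaries, function(s) {
    if (nrow(s$counts) == 0) {
      return(NULL)
    }
    data.frame(
      feature = rep(s$counts$feature, 2L),
      species = s$species, group = s$group,
      strand = rep(c("L", "H"), each = nrow(s$counts)),
      count = c(s$counts$L, s$counts$H),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(long)) {
    long <- data.frame(
      feature = character(0), species = character(0),
      group = character(0), strand = character(0), count = numeric(0)
    )
  }
  long <- long[long$count > 0, , drop = FALSE]
  totals <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(
      species = s$species, group = s$group, strand = c("L", "H"),
      total = as.numeric(s$strand_totals[c("L", "H")]),
      stringsAsFactors = FALSE
    )
  }))
  groups <- unique(totals$group[!is.na(totals$group)])
  group_means <- do.call(rbind, lapply(groups, function(g) {
    data.frame(
      group = g, strand = c("L", "H"),
      mean_total = c(
        mean(totals$total[totals$group == g & totals$strand == "L"]),
        mean(totals$total[totals$group == g & totals$strand == "H"])
      ),
      stringsAsFactors = FALSE
    )
  }))
  per_feature <- if (nrow(long) > 0) {
    tapply(long$species, long$feature, function(x) length(unique(x)))
  } else {
    integer(0)
  }
  widespread <- names(per_feature)[per_feature >= min_species]
  structure(
    list(
      matrix = long, totals = totals, group_means = group_means,
      widespread = widespread
    ),
    class = "species_comparison"
  )
}
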