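#' Running-sum region seek parameters
#'
#' The running-sum detector scores every position of the sequence: a position
#' that starts a CG dinucleotide adds `cpg_score`, any other position
#' subtracts `gap_penalty`. Maximal-scoring segments whose score reaches
#' `threshold` are reported. The per-CG increment and the reporting threshold
#' share the classical default of 17 but are independently configurable; with
#' a large increment relative to the unit gap penalty, even small clusters of
#' a few CpGs within a few dozen bases are reportable, which is what makes
#' short tRNA-gene clusters visible.
#'
#' @param cpg_score Integer increment per CG dinucleotide (>= 1).
#' @param gap_penalty Integer decrement per non-CG position (>= 1).
#' @param threshold Minimum segment score for reporting (>= 1).
#' @param strict If `TRUE`, a segment must score strictly above `threshold`;
#'   the default is inclusive (score >= threshold), which makes the minimal
#'   single-CpG case decidable.
#' @return A list of class `seek_params`.
#' @export
seek_params <- function(cpg_score = 17L, gap_penalty = 1L, threshold = 17L,
                        strict = FALSE) {
  cpg_score <- as.integer(cpg_score)
  gap_penalty <- as.integer(gap_penalty)
  threshold <- as.integer(threshold)
  stopifnot(cpg_score >= 1L, gap_penalty >= 1L, threshold >= 1L)
  structure(
    list(
      cpg_score = cpg_score, gap_penalty = gap_penalty,
      threshold = threshold, strict = isTRUE(strict)
    ),
    class = "seek_params"
  )
}

# Best-scoring segment of v[lo..hi] with ties broken by leftmost start, then
# shortest (earliest end). Vectorised scan over prefix sums: the sum of
# segment (i..j) is pre[j+1] - pre[i], maximised per j by the running minimum
# of pre over i in lo..j; the first maximal j and, within it, the first
# minimal i realise the tie-break order. Returns NULL when the range is
# empty.
best_segment <- function(pre, lo, hi) {
  if (lo > hi) return(NULL)
  idx <- lo:hi
  cand <- pre[idx + 1L] - cummin(pre[idx])
  jrel <- which.max(cand)
  j <- lo + jrel - 1L
  m <- min(pre[lo:j])
  i <- (lo:j)[which(pre[lo:j] == m)[1L]]
  list(start = i, end = j, score = pre[j + 1L] - pre[i])
}

# Recursive maximal-scoring-segment search: report the best segment of the
# range when it reaches the threshold, then recurse on both flanks.
seek_recurse <- function(pre, lo, hi, threshold, strict, acc) {
  if (lo > hi) return(acc)
  seg <- best_segment(pre, lo, hi)
  hit <- if (strict) seg$score > threshold else seg$score >= threshold
  if (!hit) return(acc)
  acc[[length(acc) + 1L]] <- seg
  acc <- seek_recurse(pre, lo, seg$start - 1L, threshold, strict, acc)
  seek_recurse(pre, seg$end + 1L, hi, threshold, strict, acc)
}

#' Detect CpG-rich regions by running sum
#'
#' Scores each position (+`cpg_score` when a CG dinucleotide starts there,
#' -`gap_penalty` otherwise) and reports maximal-scoring segments whose score
#' reaches the threshold, found recursively: the best segment of the sequence
#' is reported first, then the search recurses on the left and right flanks.
#' Ties between equal-scoring segments are broken leftmost-first, then
#' shortest. Every reported region begins at the C of a CG and ends at the G
#' of a CG; regions are disjoint and returned sorted by start. A CG spanning
#' the end of the linear sequence is not counted. Per-region CpG count, C+G
#' sum and observed/expected ratio are recomputed from the region
#' subsequence.
#'
#' @param g A [genome_record()].
#' @param params A [seek_params()].
#' @return A `data.frame` of class `cpg_regions` with columns `start`, `end`,
#'   `score`, `cpg_count`, `cg_sum`, `pct_cg`, `obs_exp`, `strand` (in `g`'s
#'   own coordinate frame).
#' @examples
#' g <- genome_record(paste0(strrep("A", 20), "CGCG", strrep("A", 20)))
#' seek_regions(g) # one region, score 33, 2 CpGs
#' @export
seek_regions <- function(g, params = seek_params()) {
  stopifnot(inherits(g, "genome_record"))
  if (g$length < 2L) stop("genome too short", call. = FALSE)
  n <- g$length
  v <- rep(-params$gap_penalty, n)
  cp <- cpg_starts(g$sequence)
  v[cp] <- params$cpg_score
  pre <- c(0, cumsum(v))
  segs <- seek_recurse(pre, 1L, n, params$threshold, params$strict, list())
  if (length(segs) == 0) {
    out <- data.frame(
      start = integer(0), end = integer(0), score = integer(0),
      cpg_count = integer(0), cg_sum = integer(0), pct_cg = numeric(0),
      obs_exp = numeric(0)
    )
  } else {
    rows <- lapply(segs, function(seg) {
      # segment positions end at the C of the last CG; the region includes
      # the following G
      start <- seg$start
      end <- seg$end + 1L
      sub <- substr(g$sequence, start, end)
      cg <- count_cg_bases(sub)
      data.frame(
        start = start, end = end, score = as.integer(seg$score),
        cpg_count = length(cpg_starts(sub)),
        cg_sum = cg,
        pct_cg = 100 * cg / nchar(sub),
        obs_exp = obs_exp_ratio(sub)
      )
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$start), , drop = FALSE]
  }
  out$strand <- rep(g$strand, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("cpg_regions", "data.frame")
  out
}

#' Total CpG sites across regions of one strand
#'
#' Sums the per-region CpG counts, i.e. the per-strand "sum of all CpG sites"
#' printed at the foot of comparative distribution tables.
#'
#' @param regions Output of [seek_regions()] for one strand of one genome.
#' @return Integer total.
#' @export
region_sites <- function(regions) {
  if (nrow(regions) == 0) return(0L)
  as.integer(sum(regions$cpg_count))
}

#' Tabulate running-sum regions
#'
#' @param regions Output of [seek_regions()].
#' @param ft Optional [feature_table()] for labels.
#' @param genome_length Genome length for origin-wrapping features.
#' @return A `data.frame` with rounded `pct_cg` / `obs_exp` and a `region`
#'   label column.
#' @export
region_report <- function(regions, ft = NULL, genome_length = NULL) {
  region <- rep("", nrow(regions))
  if (!is.null(ft) && nrow(regions) > 0) {
    region <- vapply(seq_len(nrow(regions)), function(i) {
      hits <- overlap_features(regions$start[i], regions$end[i], ft,
        genome_length = genome_length
      )
      paste(unique(hits$name), collapse = ", ")
    }, character(1))
  }
  data.frame(
    start = regions$start,
    end = regions$end,
    region = region,
    score = regions$score,
    cpg_count = regions$cpg_count,
    cg_sum = regions$cg_sum,
    pct_cg = round_half_up(regions$pct_cg, 2),
    obs_exp = round_half_up(regions$obs_exp, 2),
    strand = regions$strand,
    stringsAsFactors = FALSE
  )
}
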