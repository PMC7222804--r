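#' Sliding-window island scan parameters
#'
#' Defaults follow the classical island definition used by sliding-window
#' CpG-island reporters: a 100 bp window moved 1 bp at a time, with an island
#' required to reach 200 bp, observed/expected CpG >= 0.6 and %C+%G >= 50.
#'
#' @param window Window size in bp.
#' @param shift Window shift in bp.
#' @param min_length Minimum island length in bp.
#' @param min_obs_exp Minimum observed/expected CpG ratio.
#' @param min_pct_cg Minimum percent C+G.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(window = 100L, shift = 1L, min_length = 200L,
                        min_obs_exp = 0.6, min_pct_cg = 50) {
  window <- as.integer(window)
  shift <- as.integer(shift)
  min_length <- as.integer(min_length)
  stopifnot(window >= 2L, shift >= 1L, min_length >= window,
            min_obs_exp >= 0, min_pct_cg >= 0, min_pct_cg <= 100)
  structure(
    list(
      window = window, shift = shift, min_length = min_length,
      min_obs_exp = min_obs_exp, min_pct_cg = min_pct_cg
    ),
    class = "scan_params"
  )
}

#' Observed/expected CpG ratio of a sequence
#'
#' The standard enrichment measure for CpG dinucleotides:
#' `N_CpG * N / (N_C * N_G)` where `N` is the sequence length, `N_CpG` the
#' number of CG dinucleotides and `N_C`, `N_G` the base counts. Returns 0
#' when the sequence contains no C or no G. Ambiguity characters (`N`) count
#' as neither C nor G and never form a CpG.
#'
#' @param subseq Character scalar, non-empty.
#' @return The observed/expected ratio (>= 0).
#' @examples
#' obs_exp_ratio("CGCGCGCG") # 2
#' obs_exp_ratio("AAAA") # 0
#' @export
obs_exp_ratio <- function(subseq) {
  if (!is.character(subseq) || length(subseq) != 1L || nchar(subseq) == 0L) {
    stop("`subseq` must be a non-empty string", call. = FALSE)
  }
  subseq <- toupper(subseq)
  n <- nchar(subseq)
  chars <- seq_chars(subseq)
  n_c <- sum(chars == "C")
  n_g <- sum(chars == "G")
  if (n_c == 0L || n_g == 0L) return(0)
  n_cpg <- length(cpg_starts(subseq))
  n_cpg * n / (n_c * n_g)
}

# Internal: per-window counts of C, G and CpG for all window starts, computed
# once with cumulative sums. CpG dinucleotides are counted when fully inside
# the window. Returns a list with vectors aligned to `starts`.
window_counts <- function(sequence, window, shift, circular = FALSE) {
  n <- nchar(sequence)
  chars <- seq_chars(sequence)
  is_c <- as.integer(chars == "C")
  is_g <- as.integer(chars == "G")
  is_cpg <- integer(n)
  cp <- cpg_starts(sequence)
  is_cpg[cp] <- 1L
  if (circular && n >= 2L) {
    # CG spanning the origin counts at position n
    if (chars[n] == "C" && chars[1] == "G") is_cpg[n] <- 1L
  }
  if (circular) {
    ext <- window - 1L
    is_c <- c(is_c, is_c[seq_len(ext)])
    is_g <- c(is_g, is_g[seq_len(ext)])
    is_cpg <- c(is_cpg, is_cpg[seq_len(ext)])
    starts <- seq.int(1L, n, by = shift)
  } else {
    starts <- seq.int(1L, n - window + 1L, by = shift)
  }
  cum_c <- c(0, cumsum(is_c))
  cum_g <- c(0, cumsum(is_g))
  cum_cpg <- c(0, cumsum(is_cpg))
  ends <- starts + window - 1L
  rng <- function(cum, a, b) cum[b + 1L] - cum[a]
  list(
    starts = starts,
    n_c = rng(cum_c, starts, ends),
    n_g = rng(cum_g, starts, ends),
    # CpGs fully inside the window start in [start, end-1]
    n_cpg = rng(cum_cpg, starts, ends - 1L)
  )
}

#' Per-window CpG statistics along a genome
#'
#' Slides a window of `params$window` bp along the sequence in steps of
#' `params$shift` bp and reports, for each window start, the percent C+G and
#' the observed/expected CpG ratio of that window.
#'
#' @param g A [genome_record()].
#' @param params A [scan_params()].
#' @param circular If `TRUE`, windows spanning the sequence origin are also
#'   evaluated (the sequence is treated as circular). Off by default.
#' @return A `data.frame` with columns `window_start`, `pct_cg`, `obs_exp`.
#' @export
window_profile <- function(g, params = scan_params(), circular = FALSE) {
  stopifnot(inherits(g, "genome_record"))
  if (g$length < params$window) {
    stop("genome (", g$length, " bp) shorter than window (", params$window,
      " bp)",
      call. = FALSE
    )
  }
  wc <- window_counts(g$sequence, params$window, params$shift, circular)
  denom <- wc$n_c * wc$n_g
  obs_exp <- ifelse(denom == 0, 0, wc$n_cpg * params$window / denom)
  data.frame(
    window_start = wc$starts,
    pct_cg = 100 * (wc$n_c + wc$n_g) / params$window,
    obs_exp = obs_exp
  )
}

# Internal: aggregate island statistics for an interval of a sequence.
island_stats <- function(sequence, start, end) {
  sub <- substr(sequence, start, end)
  len <- end - start + 1L
  cg <- count_cg_bases(sub)
  list(
    length = len,
    cg_sum = cg,
    pct_cg = 100 * cg / len,
    obs_exp = obs_exp_ratio(sub)
  )
}

#' Call CpG islands with a sliding window
#'
#' A window passes when its observed/expected CpG ratio and percent C+G both
#' reach the thresholds in `params`. Window values are attributed to bases by
#' one of two documented rules:
#' * `"cover"` (default): a base is flagged when at least one window covering
#'   it passes both thresholds;
#' * `"midpoint"`: each window's values are attributed to its midpoint base
#'   only.
#'
#' Maximal runs of flagged bases at least `min_length` bp long become
#' candidate islands; their aggregate statistics are recomputed over the
#' island subsequence, and candidates whose aggregate values fall below the
#' thresholds are dropped, so every reported island satisfies all three
#' criteria as written. Islands are disjoint and sorted by start. The
#' attribution rule is the main source of boundary differences between
#' sliding-window implementations; both rules are exposed so results can be
#' compared across conventions.
#'
#' @inheritParams window_profile
#' @param attribution `"cover"` or `"midpoint"`.
#' @param profile Optional precomputed [window_profile()] for `g` and
#'   `params` (with matching `circular`); recomputed when `NULL`.
#' @return A `data.frame` of class `cpg_islands` with columns `start`, `end`,
#'   `length`, `cg_sum`, `pct_cg`, `obs_exp`, `strand` (reported in the
#'   coordinates of `g`'s own frame).
#' @export
call_islands <- function(g, params = scan_params(),
                         attribution = c("cover", "midpoint"),
                         circular = FALSE, profile = NULL) {
  stopifnot(inherits(g, "genome_record"))
  attribution <- match.arg(attribution)
  if (is.null(profile)) profile <- window_profile(g, params, circular)
  n <- g$length
  pass <- profile$obs_exp >= params$min_obs_exp &
    profile$pct_cg >= params$min_pct_cg
  flags <- logical(n)
  if (any(pass)) {
    starts <- profile$window_start[pass]
    if (attribution == "cover") {
      # mark [s, s + window - 1] for each passing window via a diff array
      bump <- integer(n + 1L)
      ends <- starts + params$window - 1L
      if (circular) {
        wrap <- ends > n
        for (i in which(wrap)) {
          bump[1L] <- bump[1L] + 1L
          e2 <- ends[i] - n
          bump[e2 + 1L] <- bump[e2 + 1L] - 1L
        }
        ends[wrap] <- n
      }
      tab_s <- tabulate(starts, nbins = n)
      tab_e <- tabulate(ends + 1L, nbins = n + 1L)
      cover <- cumsum(tab_s - tab_e[seq_len(n)] + bump[seq_len(n)])
      flags <- cover > 0L
    } else {
      mids <- starts + params$window %/% 2L
      mids <- ifelse(mids > n, mids - n, mids)
      flags[mids] <- TRUE
    }
  }
  runs <- rle(flags)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  keep <- runs$values
  cand <- data.frame(start = run_start[keep], end = run_end[keep])
  if (circular && nrow(cand) >= 2L && flags[1L] && flags[n]) {
    # the first and last runs are one origin-spanning run; merge them
    last <- nrow(cand)
    if (cand$start[1L] == 1L && cand$end[last] == n) {
      cand$start[1L] <- cand$start[last]
      cand <- cand[-last, , drop = FALSE]
    }
  }
  span <- ifelse(cand$start <= cand$end,
    cand$end - cand$start + 1L,
    cand$end + n - cand$start + 1L
  )
  cand <- cand[span >= params$min_length, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    s <- cand$start[i]
    e <- cand$end[i]
    if (s <= e) {
      st <- island_stats(g$sequence, s, e)
    } else {
      sub <- paste0(substr(g$sequence, s, n), substr(g$sequence, 1L, e))
      st <- list(
        length = nchar(sub), cg_sum = count_cg_bases(sub),
        pct_cg = 100 * count_cg_bases(sub) / nchar(sub),
        obs_exp = obs_exp_ratio(sub)
      )
    }
    c(list(start = s, end = e), st)
  })
  out <- if (length(rows) == 0) {
    data.frame(
      start = integer(0), end = integer(0), length = integer(0),
      cg_sum = integer(0), pct_cg = numeric(0), obs_exp = numeric(0)
    )
  } else {
    do.call(rbind, lapply(rows, as.data.frame))
  }
  ok <- out$length >= params$min_length &
    out$pct_cg >= params$min_pct_cg &
    out$obs_exp >= params$min_obs_exp
  out <- out[ok, , drop = FALSE]
  out$strand <- rep(g$strand, nrow(out))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpg_islands", "data.frame")
  out
}

#' Tabulate called islands with feature labels
#'
#' Formats islands the way comparative mtDNA island tables are printed: one
#' row per island with its coordinates, the features it overlaps, its length,
#' C+G sum, %C+%G and observed/expected ratio (the last two rounded half-up
#' to 2 decimal places). H-strand islands should be mapped to reference
#' coordinates (see [map_interval_to_reference()]) before annotation.
#'
#' @param islands Output of [call_islands()] (reference-frame coordinates).
#' @param ft Optional [feature_table()] used to label overlapped features.
#' @param genome_length Genome length (needed for origin-wrapping features).
#' @return A `data.frame` with columns `start`, `end`, `region`, `length`,
#'   `cg_sum`, `pct_cg`, `obs_exp`, `strand`.
#' @export
island_report <- function(islands, ft = NULL, genome_length = NULL) {
  region <- rep("", nrow(islands))
  if (!is.null(ft) && nrow(islands) > 0) {
    region <- vapply(seq_len(nrow(islands)), function(i) {
      hits <- overlap_features(islands$start[i], islands$end[i], ft,
        genome_length = genome_length
      )
      paste(unique(hits$name), collapse = ", ")
    }, character(1))
  }
  data.frame(
    start = islands$start,
    end = islands$end,
    region = region,
    length = islands$length,
    cg_sum = islands$cg_sum,
    pct_cg = round_half_up(islands$pct_cg, 2),
    obs_exp = round_half_up(islands$obs_exp, 2),
    strand = islands$strand,
    stringsAsFactors = FALSE
  )
}
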