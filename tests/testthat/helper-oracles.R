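# Brute-force reference implementations used as independent oracles, plus
# small random-sequence helpers. These deliberately avoid the cumulative-sum
# and prefix-sum machinery of the package: statistics are recomputed from
# substrings, and maximal segments are found by exhaustive enumeration.

random_seq <- function(n, p_cg = 0.4) {
  p <- c(A = (1 - p_cg) / 2, C = p_cg / 2, G = p_cg / 2, T = (1 - p_cg) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

count_char <- function(s, ch) {
  lengths(regmatches(s, gregexpr(ch, s, fixed = TRUE)))
}

brute_obs_exp <- function(s) {
  n <- nchar(s)
  nc <- count_char(s, "C")
  ng <- count_char(s, "G")
  ncpg <- count_char(s, "CG")
  if (nc == 0 || ng == 0) 0 else ncpg * n / (nc * ng)
}

# Oracle island caller: every base is tested against every covering window,
# each window's statistics recomputed directly from its substring.
brute_islands <- function(s, params, attribution = "cover") {
  n <- nchar(s)
  w <- params$window
  starts <- seq.int(1L, n - w + 1L, by = params$shift)
  pass <- vapply(starts, function(st) {
    win <- substr(s, st, st + w - 1L)
    pct <- 100 * (count_char(win, "C") + count_char(win, "G")) / w
    pct >= params$min_pct_cg && brute_obs_exp(win) >= params$min_obs_exp
  }, logical(1))
  flags <- logical(n)
  if (attribution == "cover") {
    for (b in seq_len(n)) {
      covering <- starts[starts <= b & starts + w - 1L >= b]
      flags[b] <- any(pass[match(covering, starts)])
    }
  } else {
    flags[starts[pass] + w %/% 2L] <- TRUE
  }
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$min_length
  out <- data.frame(start = begins[keep], end = ends[keep])
  if (nrow(out) > 0) {
    ok <- vapply(seq_len(nrow(out)), function(i) {
      sub <- substr(s, out$start[i], out$end[i])
      pct <- 100 * (count_char(sub, "C") + count_char(sub, "G")) / nchar(sub)
      pct >= params$min_pct_cg && brute_obs_exp(sub) >= params$min_obs_exp
    }, logical(1))
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# Oracle running-sum detector: the best segment of each range is found by
# enumerating all O(n^2) candidate segments, then the search recurses on the
# flanks, mirroring the definition (leftmost, then shortest, on ties).
brute_best_segment <- function(v, lo, hi) {
  best <- NULL
  for (i in lo:hi) {
    acc <- 0
    for (j in i:hi) {
      acc <- acc + v[j]
      if (is.null(best) || acc > best$score) {
        best <- list(start = i, end = j, score = acc)
      }
    }
  }
  best
}

brute_regions <- function(s, params) {
  n <- nchar(s)
  v <- rep(-params$gap_penalty, n)
  chars <- strsplit(s, "")[[1]]
  for (i in seq_len(n - 1L)) {
    if (chars[i] == "C" && chars[i + 1L] == "G") v[i] <- params$cpg_score
  }
  acc <- list()
  recurse <- function(lo, hi) {
    if (lo > hi) {
      return()
    }
    seg <- brute_best_segment(v, lo, hi)
    hit <- if (params$strict) {
      seg$score > params$threshold
    } else {
      seg$score >= params$threshold
    }
    if (!hit) {
      return()
    }
    acc[[length(acc) + 1L]] <<- seg
    recurse(lo, seg$start - 1L)
    recurse(seg$end + 1L, hi)
  }
  recurse(1L, n)
  if (length(acc) == 0) {
    return(data.frame(start = integer(0), end = integer(0), score = integer(0)))
  }
  out <- data.frame(
    start = vapply(acc, `[[`, integer(1), "start"),
    end = vapply(acc, function(x) x$end + 1L, integer(1)),
    score = vapply(acc, function(x) as.integer(x$score), integer(1))
  )
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# A tiny AT-rich background with an alternating-CG block planted at `at`.
planted_block_seq <- function(n = 2000L, at = 900L, block = 250L) {
  bg <- paste(sample(c("A", "T"), n, replace = TRUE), collapse = "")
  cg <- strrep("CG", ceiling(block / 2))
  cg <- substr(cg, 1, block)
  substr(bg, at, at + block - 1L) <- cg
  bg
}
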