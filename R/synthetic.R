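#' Specification of a synthetic mitochondria-like genome
#'
#' Describes a synthetic genome used to validate every pipeline stage without
#' downloads: a CpG-depleted background of given length, GC fraction and
#' observed/expected CpG ratio, plus planted CpG islands of specified
#' position, length and composition. Defaults emulate a typical vertebrate
#' mitochondrial genome: ~16.5 kb, 40% GC, strong genome-wide CpG depletion
#' (obs/exp 0.25), with two planted islands that the caller should detect
#' (one inside the protein-coding gene cluster, one in the D-loop).
#'
#' @param length Genome length in bp.
#' @param background_gc Background GC fraction (0 < gc < 1).
#' @param background_obs_exp Background observed/expected CpG ratio (>= 0).
#' @param islands `data.frame` with columns `position` (1-based start),
#'   `length`, `gc`, `obs_exp`; islands must fit in the genome and not
#'   overlap. Use `NULL` or a zero-row frame for no islands.
#' @param topology `"linear"` or `"circular"`.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(length = 16500L, background_gc = 0.40,
                       background_obs_exp = 0.25,
                       islands = default_islands(), topology = "linear",
                       seed = 1L) {
  length <- as.integer(length)
  stopifnot(
    length > 0L, background_gc > 0, background_gc < 1,
    background_obs_exp >= 0
  )
  if (is.null(islands)) {
    islands <- data.frame(
      position = integer(0), length = integer(0),
      gc = numeric(0), obs_exp = numeric(0)
    )
  }
  stopifnot(all(c("position", "length", "gc", "obs_exp") %in% names(islands)))
  if (nrow(islands) > 0) {
    ends <- islands$position + islands$length - 1L
    if (any(islands$position < 1L) || any(ends > length)) {
      stop("island(s) fall outside the genome", call. = FALSE)
    }
    o <- order(islands$position)
    if (nrow(islands) > 1 &&
      any(islands$position[o][-1] <= ends[o][-nrow(islands)])) {
      stop("islands overlap", call. = FALSE)
    }
  }
  structure(
    list(
      length = length, background_gc = background_gc,
      background_obs_exp = background_obs_exp, islands = islands,
      topology = match.arg(topology, c("linear", "circular")),
      seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
}

#' Default planted islands of the synthetic genome
#'
#' Two islands sized and composed so that a sliding-window caller at the
#' standard thresholds must recover them: 300-320 bp (minimum length 200 plus
#' margin for boundary attribution), 55% GC and obs/exp 1.2 on the depleted
#' 40%-GC / 0.25-obs-exp background. One sits in the protein-gene cluster,
#' one in the D-loop region of the default feature layout.
#'
#' @return A `data.frame` with columns `position`, `length`, `gc`, `obs_exp`.
#' @export
default_islands <- function() {
  data.frame(
    position = c(7800L, 15650L),
    length = c(300L, 320L),
    gc = c(0.55, 0.55),
    obs_exp = c(1.2, 1.2)
  )
}

# Transition matrix of a first-order Markov chain over A,C,G,T whose
# stationary distribution has the requested GC fraction and whose C->G
# transition yields the requested observed/expected CpG ratio. Rows other
# than C use the stationary distribution itself; row C pins P(G|C) =
# obs_exp * pi_G and rescales the rest. A short fixed-point iteration
# corrects the stationary drift introduced by modifying row C.
markov_transition <- function(gc, obs_exp) {
  target <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  if (obs_exp * target["G"] >= 1) {
    stop("infeasible (gc, obs_exp): required P(G|C) >= 1", call. = FALSE)
  }
  base <- target
  build <- function(base) {
    P <- matrix(rep(base, each = 4L),
      nrow = 4L,
      dimnames = list(names(base), names(base))
    )
    pg <- obs_exp * target["G"]
    scale <- (1 - pg) / (1 - base["G"])
    P["C", ] <- base * scale
    P["C", "G"] <- pg
    P
  }
  stationary <- function(P) {
    e <- eigen(t(P))
    v <- Re(e$vectors[, which.min(abs(e$values - 1))])
    v / sum(v)
  }
  for (iter in seq_len(60L)) {
    P <- build(base)
    s <- stationary(P)
    names(s) <- names(base)
    if (max(abs(s - target)) < 1e-10) break
    adj <- base * (target / pmax(s, 1e-12))
    base <- adj / sum(adj)
    if (any(base <= 0) || any(base >= 1)) {
      stop("infeasible (gc, obs_exp) combination", call. = FALSE)
    }
  }
  P <- build(base)
  if (any(P < -1e-12)) {
    stop("infeasible (gc, obs_exp) combination", call. = FALSE)
  }
  P[P < 0] <- 0
  P / rowSums(P)
}

# Sample n bases from the chain defined by transition matrix P, starting
# from its stationary distribution. Assumes the RNG is already seeded.
sample_chain <- function(n, P) {
  e <- eigen(t(P))
  s <- Re(e$vectors[, which.min(abs(e$values - 1))])
  s <- s / sum(s)
  bases <- rownames(P)
  # cumulative rows for inverse-CDF sampling with one runif(n) draw
  cum <- t(apply(P, 1L, cumsum))
  u <- stats::runif(n)
  out <- integer(n)
  out[1L] <- findInterval(u[1L], cumsum(s)) + 1L
  if (n == 1L) return(bases[out])
  for (i in 2:n) {
    out[i] <- findInterval(u[i], cum[out[i - 1L], ],
      rightmost.closed = FALSE
    ) + 1L
  }
  paste(bases[out], collapse = "")
}

# Draw island pieces until the realized composition matches the nominal one
# (GC within 0.015, obs/exp within 10% or 0.1, whichever is larger); keep
# the closest draw if the cap is hit. Assumes the RNG is already seeded.
sample_conditioned_piece <- function(n, P, gc, obs_exp, max_tries = 500L) {
  best <- NULL
  best_d <- Inf
  for (try in seq_len(max_tries)) {
    s <- sample_chain(n, P)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    gc_hat <- sum(chars == "C" | chars == "G") / n
    oe_hat <- obs_exp_ratio(s)
    d_gc <- abs(gc_hat - gc)
    d_oe <- abs(oe_hat - obs_exp)
    if (d_gc <= 0.015 && d_oe <= max(0.1, 0.1 * obs_exp)) {
      return(s)
    }
    d <- d_gc / 0.015 + d_oe / max(0.1, 0.1 * obs_exp)
    if (d < best_d) {
      best_d <- d
      best <- s
    }
  }
  best
}

#' Generate a CpG-depleted background genome
#'
#' Draws the background sequence from a first-order Markov dinucleotide
#' chain whose stationary base composition matches `background_gc` and whose
#' C-to-G transition probability is set so the expected observed/expected
#' CpG ratio equals `background_obs_exp`. A first-order chain (rather than
#' i.i.d. bases) is used because CpG depletion is a dinucleotide property:
#' independent draws cannot hold GC fixed while suppressing CpG.
#' Deterministic given `spec$seed`; the caller's RNG state is untouched.
#'
#' @param spec A [synth_spec()].
#' @return A [genome_record()] labelled with the seed.
#' @export
generate_background <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  P <- markov_transition(spec$background_gc, spec$background_obs_exp)
  seq <- with_local_seed(
    spec$seed,
    sample_chain(spec$length, P)
  )
  genome_record(seq,
    id = sprintf("synth_seed%d", spec$seed),
    topology = spec$topology, strand = "L"
  )
}

#' Plant CpG islands into a background genome
#'
#' Replaces (never inserts, so all coordinates stay stable) each island
#' interval of the spec with sequence drawn from a Markov chain at the
#' island's own GC fraction and observed/expected ratio. Because the truth
#' table asserts the island's composition, each piece is drawn repeatedly
#' (within the same seeded stream, so the result stays deterministic) until
#' its realized GC fraction and obs/exp ratio match the nominal values
#' within a small tolerance; a finite draw cannot otherwise be relied on to
#' carry the composition it was sampled from. Returns the modified genome
#' together with a truth table recording the planted intervals and the seed.
#'
#' @param g Background [genome_record()] of length `spec$length`.
#' @param spec The [synth_spec()] used to generate `g`.
#' @return A list with elements `genome` ([genome_record()]) and `truth`
#'   (`data.frame` with `start`, `end`, `gc`, `obs_exp`, `seed`).
#' @export
plant_islands <- function(g, spec) {
  stopifnot(inherits(g, "genome_record"), inherits(spec, "synth_spec"))
  if (g$length != spec$length) {
    stop("genome length does not match spec", call. = FALSE)
  }
  isl <- spec$islands
  seq <- g$sequence
  if (nrow(isl) > 0) {
    for (i in seq_len(nrow(isl))) {
      P <- markov_transition(isl$gc[i], isl$obs_exp[i])
      # island seeds are offset from the spec seed so islands differ from
      # the background stream but stay reproducible
      piece <- with_local_seed(
        (spec$seed + 104729L * i) %% .Machine$integer.max,
        sample_conditioned_piece(isl$length[i], P, isl$gc[i], isl$obs_exp[i])
      )
      substr(seq, isl$position[i], isl$position[i] + isl$length[i] - 1L) <- piece
    }
  }
  truth <- data.frame(
    start = as.integer(isl$position),
    end = as.integer(isl$position + isl$length - 1L),
    gc = isl$gc, obs_exp = isl$obs_exp,
    seed = rep(spec$seed, nrow(isl))
  )
  list(
    genome = genome_record(seq,
      id = g$id, topology = g$topology,
      strand = g$strand
    ),
    truth = truth
  )
}

# Canonical vertebrate mtDNA gene order with realistic lengths (bp),
# following the standard TRNF ... CYTB, TRNT, TRNP, D-loop arrangement.
MITO_LAYOUT <- data.frame(
  name = c(
    "TRNF", "12s rRNA", "TRNV", "16s rRNA", "TRNL1", "ND1", "TRNI", "TRNQ",
    "TRNM", "ND2", "TRNW", "TRNA", "TRNN", "rep_origin", "TRNC", "TRNY",
    "COX1", "TRNS1", "TRND", "COX2", "TRNK", "ATP8", "ATP6", "COX3", "TRNG",
    "ND3", "TRNR", "ND4L", "ND4", "TRNH", "TRNS2", "TRNL2", "ND5", "ND6",
    "TRNE", "CYTB", "TRNT", "TRNP"
  ),
  kind = c(
    "tRNA", "rRNA", "tRNA", "rRNA", "tRNA", "protein_gene", "tRNA", "tRNA",
    "tRNA", "protein_gene", "tRNA", "tRNA", "tRNA", "rep_origin", "tRNA",
    "tRNA", "protein_gene", "tRNA", "tRNA", "protein_gene", "tRNA",
    "protein_gene", "protein_gene", "protein_gene", "tRNA", "protein_gene",
    "tRNA", "protein_gene", "protein_gene", "tRNA", "tRNA", "tRNA",
    "protein_gene", "protein_gene", "tRNA", "protein_gene", "tRNA", "tRNA"
  ),
  length = c(
    71L, 954L, 69L, 1559L, 75L, 956L, 70L, 72L, 68L, 1042L, 68L, 69L, 73L,
    31L, 66L, 66L, 1542L, 69L, 68L, 684L, 70L, 207L, 681L, 784L, 68L, 346L,
    65L, 297L, 1378L, 69L, 59L, 71L, 1812L, 528L, 69L, 1141L, 66L, 69L
  ),
  strand = "L",
  stringsAsFactors = FALSE
)

#' Generate a mitochondria-like feature layout
#'
#' Tiles the genome with the 37 loci of the canonical vertebrate mtDNA gene
#' order (tRNA-Phe, 12S rRNA, ..., CYTB, tRNA-Thr, tRNA-Pro) at realistic
#' lengths, followed by a D-loop filling the remainder. With
#' `dloop_wraps = TRUE` the gene block starts downstream of position 1 and
#' the D-loop spans the sequence origin (as in the human reference), which
#' exercises origin-wrapping interval handling.
#'
#' Genomes shorter than the canonical ~15.7 kb gene span (compact
#' invertebrate-like mitogenomes carry the same gene complement in less
#' space) get all locus lengths scaled down proportionally, keeping a
#' non-coding tail of at least 200 bp.
#'
#' @param length Genome length in bp (or a [synth_spec()]).
#' @param dloop_wraps Should the D-loop span the sequence origin?
#' @return A [feature_table()].
#' @export
generate_feature_layout <- function(length = 16500L, dloop_wraps = FALSE) {
  if (inherits(length, "synth_spec")) length <- length$length
  length <- as.integer(length)
  layout <- MITO_LAYOUT
  gene_span <- sum(layout$length)
  if (length < gene_span + 200L) {
    scale <- (length - 200L) / gene_span
    layout$length <- pmax(20L, as.integer(floor(layout$length * scale)))
    gene_span <- sum(layout$length)
    if (length < gene_span + 200L) {
      stop(
        "genome too short for the canonical layout (need >= ",
        gene_span + 200L, " bp)",
        call. = FALSE
      )
    }
  }
  offset <- if (dloop_wraps) {
    min(576L, length - gene_span - 1L)
  } else {
    0L
  }
  starts <- offset + cumsum(c(1L, layout$length[-nrow(layout)]))
  ends <- starts + layout$length - 1L
  if (dloop_wraps) {
    dl <- data.frame(
      name = "D-LOOP", kind = "noncoding",
      start = max(ends) + 1L, end = offset, strand = "L",
      wraps_origin = TRUE, stringsAsFactors = FALSE
    )
  } else {
    dl <- data.frame(
      name = "D-LOOP", kind = "noncoding",
      start = max(ends) + 1L, end = length, strand = "L",
      wraps_origin = FALSE, stringsAsFactors = FALSE
    )
  }
  feature_table(
    name = c(MITO_LAYOUT$name, dl$name),
    kind = c(MITO_LAYOUT$kind, dl$kind),
    start = c(starts, dl$start),
    end = c(ends, dl$end),
    strand = "L",
    wraps_origin = c(rep(FALSE, nrow(MITO_LAYOUT)), dl$wraps_origin),
    genome_length = length
  )
}

#' Generate a complete synthetic genome with truth table and features
#'
#' Convenience wrapper: background + planted islands + feature layout.
#'
#' @param spec A [synth_spec()].
#' @param dloop_wraps Passed to [generate_feature_layout()].
#' @return A list with `genome`, `truth`, `features`, `spec`.
#' @export
generate_mito_genome <- function(spec = synth_spec(), dloop_wraps = FALSE) {
  bg <- generate_background(spec)
  planted <- plant_islands(bg, spec)
  features <- generate_feature_layout(spec$length, dloop_wraps = dloop_wraps)
  list(
    genome = planted$genome, truth = planted$truth,
    features = features, spec = spec
  )
}

#' Write the truth table of planted islands as TSV
#'
#' @param truth Truth `data.frame` from [plant_islands()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
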