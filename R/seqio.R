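#' Construct a genome record
#'
#' A `genome_record` holds one strand of a (typically mitochondrial) genome:
#' the sequence itself plus its accession, length, topology and strand label.
#' Reference sequences deposited in GenBank correspond to the light (L)
#' strand of animal mtDNA; the heavy (H) strand is obtained with
#' [reverse_complement()].
#'
#' @param sequence Character scalar over `A`, `C`, `G`, `T`, `N`. Lower-case
#'   input is accepted and upper-cased; IUPAC ambiguity codes other than `N`
#'   are collapsed to `N` (they count as neither C nor G and never form a
#'   CpG).
#' @param id Accession or other identifier.
#' @param topology `"linear"` or `"circular"`.
#' @param strand `"L"` or `"H"`.
#'
#' @return An object of class `genome_record` with fields `id`, `sequence`,
#'   `length`, `topology`, `strand`.
#' @examples
#' g <- genome_record("ACGTACGT", id = "toy")
#' g$length
#' @export
genome_record <- function(sequence, id = "genome",
                          topology = c("linear", "circular"),
                          strand = c("L", "H")) {
  topology <- match.arg(topology)
  strand <- match.arg(strand)
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("`sequence` must be a single character string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  sequence <- gsub("[^ACGT]", "N", sequence)
  if (nchar(sequence) == 0L) {
    stop("zero-length sequence", call. = FALSE)
  }
  structure(
    list(
      id = as.character(id),
      sequence = sequence,
      length = nchar(sequence),
      topology = topology,
      strand = strand
    ),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf(
    "<genome_record> %s | %d bp | %s | strand %s\n",
    x$id, x$length, x$topology, x$strand
  ))
  invisible(x)
}

#' Read a genome sequence from a FASTA file
#'
#' @param path Path to a FASTA file. Multi-record files are read record by
#'   record and `which` selects one.
#' @param which Index of the record to return (default first).
#' @inheritParams genome_record
#' @return A [genome_record()].
#' @export
read_fasta <- function(path, which = 1L, topology = "linear", strand = "L") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path, call. = FALSE)
  )
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (which < 1L || which > length(set)) {
    stop("record index out of range: ", which, call. = FALSE)
  }
  id <- sub("\\s.*$", "", names(set)[which])
  if (is.na(id) || id == "") id <- basename(path)
  genome_record(as.character(set[[which]]),
    id = id,
    topology = topology, strand = strand
  )
}

#' Write a genome record to FASTA
#'
#' @param g A [genome_record()].
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "genome_record"))
  set <- Biostrings::BStringSet(setNames(g$sequence, g$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement a genome record
#'
#' Produces the complementary strand written 5' to 3' (the H strand of a
#' reference L-strand sequence, and vice versa). `N` maps to `N`; length is
#' preserved and the strand label flips.
#'
#' @param g A [genome_record()].
#' @return A [genome_record()] on the opposite strand.
#' @examples
#' reverse_complement(genome_record("AACG"))$sequence # "CGTT"
#' @export
reverse_complement <- function(g) {
  stopifnot(inherits(g, "genome_record"))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g$sequence)))
  out <- genome_record(rc,
    id = g$id, topology = g$topology,
    strand = if (g$strand == "L") "H" else "L"
  )
  out
}

#' Map an interval between strand coordinate frames
#'
#' An interval `start..end` (1-based inclusive) on the reverse-complemented
#' sequence of a genome of length `L` corresponds to `(L - end + 1)..(L -
#' start + 1)` on the original sequence. The mapping is an involution, so the
#' same function converts in either direction.
#'
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param genome_length Sequence length in bp.
#' @return A list with fields `start` and `end` in the opposite frame.
#' @examples
#' map_interval_to_reference(1, 4, 10) # 7..10
#' @export
map_interval_to_reference <- function(start, end, genome_length) {
  start <- as.integer(start)
  end <- as.integer(end)
  genome_length <- as.integer(genome_length)
  if (any(start < 1L) || any(end > genome_length) || any(start > end)) {
    stop("interval out of bounds for genome of length ", genome_length,
      call. = FALSE
    )
  }
  list(start = genome_length - end + 1L, end = genome_length - start + 1L)
}

FEATURE_KINDS <- c(
  "protein_gene", "tRNA", "rRNA", "noncoding", "rep_origin", "intergenic"
)

# Guess a feature kind from a canonical locus name.
guess_feature_kind <- function(name) {
  up <- toupper(name)
  ifelse(grepl("^TRN", up), "tRNA",
    ifelse(grepl("RRNA|^12S|^16S", up), "rRNA",
      ifelse(grepl("D-?LOOP|AT-?REGION|CONTROL", up), "noncoding",
        ifelse(grepl("REP_?ORIGIN|^OL$|^O_L$", up), "rep_origin",
          ifelse(grepl("INTERGENIC", up), "intergenic", "protein_gene")
        )
      )
    )
  )
}

#' Construct a feature table
#'
#' A feature table is a data frame of annotated mtDNA intervals (protein
#' genes, tRNAs, rRNAs, the D-loop, the replication origin, intergenic
#' spacers) with 1-based inclusive coordinates. Features spanning the
#' sequence origin of a circular genome carry `wraps_origin = TRUE` and have
#' `start > end`.
#'
#' @param name Locus labels (e.g. `ND1`, `TRNW`, `D-LOOP`, `rep_origin`).
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"L"` or `"H"` per feature.
#' @param kind One of `r paste(FEATURE_KINDS, collapse = ", ")`; guessed from
#'   the name when omitted.
#' @param wraps_origin Logical; `TRUE` for origin-spanning features.
#' @param genome_length Optional length used to validate coordinates.
#' @return A `data.frame` with class `feature_table`.
#' @export
feature_table <- function(name, start, end, strand = "L", kind = NULL,
                          wraps_origin = FALSE, genome_length = NULL) {
  n <- length(name)
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- rep_len(as.character(strand), n)
  wraps_origin <- rep_len(as.logical(wraps_origin), n)
  if (is.null(kind)) kind <- guess_feature_kind(name)
  kind <- rep_len(as.character(kind), n)
  bad <- !kind %in% FEATURE_KINDS
  if (any(bad)) {
    stop("unknown feature kind(s): ", paste(unique(kind[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  ft <- data.frame(
    name = as.character(name), kind = kind, start = start, end = end,
    strand = strand, wraps_origin = wraps_origin,
    stringsAsFactors = FALSE
  )
  problems <- character(0)
  if (!is.null(genome_length)) {
    out_of_range <- ft$start < 1L | ft$end < 1L |
      ft$start > genome_length | ft$end > genome_length
    if (any(out_of_range)) {
      problems <- c(problems, paste0(
        ft$name[out_of_range], " (", ft$start[out_of_range], "..",
        ft$end[out_of_range], ") outside 1..", genome_length
      ))
    }
  }
  inverted <- !ft$wraps_origin & ft$start > ft$end
  if (any(inverted)) {
    problems <- c(problems, paste0(
      ft$name[inverted], " has start > end without wraps_origin"
    ))
  }
  if (length(problems) > 0) {
    stop("invalid features:\n  ", paste(problems, collapse = "\n  "),
      call. = FALSE
    )
  }
  class(ft) <- c("feature_table", "data.frame")
  ft
}

feature_length <- function(ft, genome_length) {
  ifelse(ft$wraps_origin,
    ft$end + genome_length - ft$start + 1L,
    ft$end - ft$start + 1L
  )
}

#' Read feature annotations
#'
#' Reads annotated mtDNA features from one of three dialects:
#' * `tsv` — tab-separated with header columns `name`, `kind`, `start`,
#'   `end`, `strand`, `wraps_origin` (1-based inclusive; `kind` and
#'   `wraps_origin` optional);
#' * `bed` — BED with 0-based half-open coordinates, converted on input;
#' * `genbank` — the FEATURES block of a GenBank flat file (`gene`, `tRNA`,
#'   `rRNA`, `D-loop`, `rep_origin` keys; `complement(...)` marks the H
#'   strand and `join(a..L,1..b)` marks origin-wrapping features).
#'
#' @param path Input file.
#' @param dialect `"tsv"`, `"bed"` or `"genbank"`; guessed from the file
#'   extension when omitted.
#' @param genome_length Optional length for coordinate validation.
#' @return A [feature_table()].
#' @export
read_features <- function(path, dialect = NULL, genome_length = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      bed = "bed",
      gb = "genbank", gbk = "genbank", genbank = "genbank",
      "tsv"
    )
  }
  dialect <- match.arg(dialect, c("tsv", "bed", "genbank"))
  switch(dialect,
    tsv = read_features_tsv(path, genome_length),
    bed = read_features_bed(path, genome_length),
    genbank = read_features_genbank(path, genome_length)
  )
}

read_features_tsv <- function(path, genome_length) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, quote = ""
  )
  required <- c("name", "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("feature TSV lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  feature_table(
    name = df$name, start = df$start, end = df$end,
    strand = if ("strand" %in% names(df)) df$strand else "L",
    kind = if ("kind" %in% names(df)) df$kind else NULL,
    wraps_origin = if ("wraps_origin" %in% names(df)) df$wraps_origin else FALSE,
    genome_length = genome_length
  )
}

read_features_bed <- function(path, genome_length) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("empty BED file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3)) stop("BED lines need >= 3 fields", call. = FALSE)
  start0 <- as.integer(vapply(fields, `[`, character(1), 2))
  end0 <- as.integer(vapply(fields, `[`, character(1), 3))
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[4], character(1)), ".")
  strand <- ifelse(
    nf >= 6 & vapply(fields, function(f) if (length(f) >= 6) f[6] else "+", character(1)) == "-",
    "H", "L"
  )
  feature_table(
    name = name, start = start0 + 1L, end = end0, strand = strand,
    genome_length = genome_length
  )
}

# Minimal parser for the FEATURES block of a GenBank flat file. Only the
# feature keys relevant to mtDNA annotation are retained; qualifiers /gene,
# /product and /note provide the name, in that priority.
read_features_genbank <- function(path, genome_length) {
  lines <- readLines(path)
  feat_start <- grep("^FEATURES", lines)
  if (length(feat_start) == 0) {
    stop("no FEATURES block in GenBank file: ", path, call. = FALSE)
  }
  block_end <- grep("^(ORIGIN|CONTIG|//)", lines)
  block_end <- block_end[block_end > feat_start[1]]
  end_idx <- if (length(block_end) > 0) block_end[1] - 1L else length(lines)
  block <- lines[(feat_start[1] + 1L):end_idx]

  keep_keys <- c("gene", "tRNA", "rRNA", "D-loop", "rep_origin", "misc_feature", "CDS")
  key_re <- "^ {5}(\\S+) +(.+)$"
  is_key <- grepl(key_re, block)
  recs <- list()
  cur <- NULL
  for (ln in block) {
    if (grepl(key_re, ln)) {
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
      cur <- list(
        key = sub(key_re, "\\1", ln),
        loc = sub(key_re, "\\2", ln),
        quals = character(0)
      )
    } else if (!is.null(cur)) {
      trimmed <- sub("^ +", "", ln)
      if (grepl("^/", trimmed)) {
        cur$quals <- c(cur$quals, trimmed)
      } else {
        # location or qualifier continuation line
        if (length(cur$quals) == 0) {
          cur$loc <- paste0(cur$loc, trimmed)
        } else {
          cur$quals[length(cur$quals)] <-
            paste(cur$quals[length(cur$quals)], trimmed)
        }
      }
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
  recs <- Filter(function(r) r$key %in% keep_keys, recs)
  # prefer gene over CDS duplicates: drop CDS whose location equals a gene's
  gene_locs <- vapply(
    Filter(function(r) r$key == "gene", recs),
    function(r) r$loc, character(1)
  )
  recs <- Filter(
    function(r) !(r$key == "CDS" && r$loc %in% gene_locs),
    recs
  )
  if (length(recs) == 0) {
    stop("no usable features in GenBank file: ", path, call. = FALSE)
  }

  qual_value <- function(quals, tag) {
    hit <- grep(paste0("^/", tag, "="), quals, value = TRUE)
    if (length(hit) == 0) {
      return(NA_character_)
    }
    gsub("\"", "", sub(paste0("^/", tag, "="), "", hit[1]))
  }

  parsed <- lapply(recs, function(r) {
    loc <- gsub(" ", "", r$loc)
    strand <- "L"
    if (grepl("^complement\\(", loc)) {
      strand <- "H"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    wraps <- FALSE
    if (grepl("^join\\(", loc)) {
      inner <- sub("^join\\((.*)\\)$", "\\1", loc)
      parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        return(NULL)
      }
      rng <- lapply(parts, function(p) {
        as.integer(strsplit(gsub("[<>]", "", p), "\\.\\.")[[1]])
      })
      start <- rng[[1]][1]
      end <- rng[[2]][length(rng[[2]])]
      wraps <- TRUE
    } else {
      nums <- as.integer(strsplit(gsub("[<>]", "", loc), "\\.\\.")[[1]])
      start <- nums[1]
      end <- nums[length(nums)]
    }
    name <- qual_value(r$quals, "gene")
    if (is.na(name)) name <- qual_value(r$quals, "product")
    if (is.na(name)) name <- qual_value(r$quals, "note")
    if (is.na(name)) name <- r$key
    kind <- switch(r$key,
      tRNA = "tRNA",
      rRNA = "rRNA",
      `D-loop` = "noncoding",
      rep_origin = "rep_origin",
      "protein_gene"
    )
    if (r$key == "D-loop") name <- "D-LOOP"
    if (r$key == "rep_origin") name <- "rep_origin"
    list(
      name = name, kind = kind, start = start, end = end,
      strand = strand, wraps_origin = wraps
    )
  })
  parsed <- Filter(Negate(is.null), parsed)
  feature_table(
    name = vapply(parsed, `[[`, character(1), "name"),
    kind = vapply(parsed, `[[`, character(1), "kind"),
    start = vapply(parsed, function(p) as.integer(p$start), integer(1)),
    end = vapply(parsed, function(p) as.integer(p$end), integer(1)),
    strand = vapply(parsed, `[[`, character(1), "strand"),
    wraps_origin = vapply(parsed, `[[`, logical(1), "wraps_origin"),
    genome_length = genome_length
  )
}

#' Write a feature table as TSV
#'
#' @param ft A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(ft, path) {
  utils::write.table(as.data.frame(ft), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
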