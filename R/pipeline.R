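#' Scan one genome on one or both strands
#'
#' Runs the sliding-window island caller and the running-sum region detector
#' on the reference (L) strand and/or its reverse complement (H strand).
#' H-strand detections are mapped back to reference coordinates before
#' annotation, so their gene labels line up with the L-strand feature table;
#' the `strand` column records which strand the detection was made on.
#'
#' @param g A [genome_record()] (the deposited reference, L strand).
#' @param ft Optional [feature_table()] for annotation.
#' @param scan A [scan_params()].
#' @param seek A [seek_params()].
#' @param strands `"both"`, `"L"` or `"H"`.
#' @param attribution Window-to-base attribution rule, see [call_islands()].
#' @param circular Evaluate windows spanning the origin (islands only).
#' @return A list of class `genome_scan` with elements `islands`, `regions`
#'   (both in reference coordinates), `annotations` (classified regions; only
#'   when `ft` is given) and `summary` (a [build_summary()]; only when `ft`
#'   is given and both strands were scanned).
#' @export
scan_genome <- function(g, ft = NULL, scan = scan_params(),
                        seek = seek_params(),
                        strands = c("both", "L", "H"),
                        attribution = "cover", circular = FALSE) {
  stopifnot(inherits(g, "genome_record"))
  strands <- match.arg(strands)
  todo <- if (strands == "both") c("L", "H") else strands
  islands <- list()
  regions <- list()
  for (s in todo) {
    gs <- if (s == g$strand) g else reverse_complement(g)
    isl <- call_islands(gs,
      params = scan, attribution = attribution,
      circular = circular
    )
    reg <- seek_regions(gs, params = seek)
    if (s != g$strand) {
      # map detections back to the reference frame
      if (nrow(isl) > 0) {
        m <- map_interval_to_reference(isl$start, isl$end, g$length)
        isl$start <- m$start
        isl$end <- m$end
        isl <- isl[order(isl$start), , drop = FALSE]
      }
      if (nrow(reg) > 0) {
        m <- map_interval_to_reference(reg$start, reg$end, g$length)
        reg$start <- m$start
        reg$end <- m$end
        reg <- reg[order(reg$start), , drop = FALSE]
      }
    }
    islands[[s]] <- isl
    regions[[s]] <- reg
  }
  islands <- do.call(rbind, islands)
  regions <- do.call(rbind, regions)
  rownames(islands) <- rownames(regions) <- NULL
  out <- list(islands = islands, regions = regions)
  if (!is.null(ft)) {
    out$annotations <- classify_regions(regions, ft,
      genome_length = g$length
    )
    if (strands == "both") {
      out$summary <- build_summary(out$annotations,
        species = g$id,
        ft = ft, genome_length = g$length
      )
    }
  }
  class(out) <- "genome_scan"
  out
}

#' @export
print.genome_scan <- function(x, ...) {
  cat(sprintf(
    "<genome_scan> %d island(s), %d region(s)%s\n",
    nrow(x$islands), nrow(x$regions),
    if (!is.null(x$summary)) {
      sprintf(
        " | CpG sites L=%g H=%g",
        x$summary$strand_totals["L"], x$summary$strand_totals["H"]
      )
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Build a run configuration
#'
#' @param inputs `data.frame` with columns `sequence` (FASTA path),
#'   `features` (annotation path or `NA`), `label` (species label) and
#'   optionally `group` (`"vertebrate"`/`"invertebrate"`).
#' @param scan A [scan_params()].
#' @param seek A [seek_params()].
#' @param strands `"both"`, `"L"` or `"H"`.
#' @param out_dir Output directory (created if needed).
#' @param attribution Window-to-base attribution rule.
#' @param circular Evaluate origin-spanning windows.
#' @param quiet Suppress progress messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(inputs, scan = scan_params(), seek = seek_params(),
                       strands = "both", out_dir = ".",
                       attribution = "cover", circular = FALSE,
                       quiet = FALSE) {
  stopifnot(is.data.frame(inputs), nrow(inputs) >= 1L)
  stopifnot(all(c("sequence", "label") %in% names(inputs)))
  if (!"features" %in% names(inputs)) inputs$features <- NA_character_
  if (!"group" %in% names(inputs)) inputs$group <- NA_character_
  structure(
    list(
      inputs = inputs, scan = scan, seek = seek,
      strands = match.arg(strands, c("both", "L", "H")),
      out_dir = out_dir, attribution = attribution,
      circular = isTRUE(circular), quiet = isTRUE(quiet)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file has optional top-level keys `scan`, `seek`, `strands`,
#' `out_dir`, `attribution`, `circular`, and a required `inputs` list whose
#' entries carry `sequence`, `label` and optionally `features` and `group`.
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p)) {
      return(NA_character_)
    }
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  inputs <- do.call(rbind, lapply(cfg$inputs, function(x) {
    data.frame(
      sequence = resolve(x$sequence),
      features = resolve(x$features),
      label = x$label,
      group = if (is.null(x$group)) NA_character_ else x$group,
      stringsAsFactors = FALSE
    )
  }))
  scan <- do.call(scan_params, as.list(cfg$scan %||% list()))
  seek <- do.call(seek_params, as.list(cfg$seek %||% list()))
  run_config(
    inputs = inputs, scan = scan, seek = seek,
    strands = cfg$strands %||% "both",
    out_dir = resolve(cfg$out_dir %||% "."),
    attribution = cfg$attribution %||% "cover",
    circular = isTRUE(cfg$circular)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path,
    header = TRUE, sep = "\t", quote = "",
    stringsAsFactors = FALSE
  )
}

#' Run the scan stage of the pipeline
#'
#' For every input genome and requested strand, writes
#' `<label>.<strand>.islands.tsv` and `<label>.<strand>.regions.tsv` (plus
#' `<label>.annotations.tsv` when features are supplied) into
#' `config$out_dir`, together with a `params.yaml` recording the parameters
#' used. Outputs contain no timestamps, so re-running an identical
#' configuration reproduces them byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of `genome_scan` results keyed by label.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  missing <- config$inputs$sequence[!file.exists(config$inputs$sequence)]
  if (length(missing) > 0) {
    stop("unreadable input file(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  params <- list(
    scan = unclass(config$scan), seek = unclass(config$seek),
    strands = config$strands, attribution = config$attribution,
    circular = config$circular
  )
  yaml::write_yaml(params, file.path(config$out_dir, "params.yaml"))
  results <- list()
  for (i in seq_len(nrow(config$inputs))) {
    row <- config$inputs[i, ]
    if (!config$quiet) {
      message("scanning ", row$label, " (", row$sequence, ")")
    }
    g <- read_fasta(row$sequence)
    g$id <- row$label
    ft <- NULL
    if (!is.na(row$features)) {
      ft <- read_features(row$features, genome_length = g$length)
    }
    res <- scan_genome(g,
      ft = ft, scan = config$scan, seek = config$seek,
      strands = config$strands, attribution = config$attribution,
      circular = config$circular
    )
    for (s in unique(res$islands$strand)) {
      write_tsv(
        island_report(res$islands[res$islands$strand == s, ], ft, g$length),
        file.path(config$out_dir, paste0(row$label, ".", s, ".islands.tsv"))
      )
    }
    for (s in unique(res$regions$strand)) {
      write_tsv(
        region_report(res$regions[res$regions$strand == s, ], ft, g$length),
        file.path(config$out_dir, paste0(row$label, ".", s, ".regions.tsv"))
      )
    }
    # always emit (possibly empty) island files for requested strands so
    # downstream comparison never misses a strand with zero islands
    todo <- if (config$strands == "both") c("L", "H") else config$strands
    for (s in setdiff(todo, unique(res$islands$strand))) {
      write_tsv(
        island_report(res$islands[integer(0), ], ft, g$length),
        file.path(config$out_dir, paste0(row$label, ".", s, ".islands.tsv"))
      )
    }
    for (s in setdiff(todo, unique(res$regions$strand))) {
      write_tsv(
        region_report(res$regions[integer(0), ], ft, g$length),
        file.path(config$out_dir, paste0(row$label, ".", s, ".regions.tsv"))
      )
    }
    if (!is.null(res$annotations)) {
      write_tsv(
        res$annotations,
        file.path(config$out_dir, paste0(row$label, ".annotations.tsv"))
      )
    }
    results[[row$label]] <- res
  }
  invisible(results)
}

#' Run the comparative stage of the pipeline
#'
#' Reads the per-species scan outputs produced by [run_scan()] from
#' `config$out_dir` and renders the comparative tables: an island table per
#' strand (coordinates, region labels, length, C+G sum, %C+%G, obs/exp), a
#' per-feature CpG-site distribution matrix with per-strand totals, and a
#' multi-feature-region table. Written as `islands_by_strand.tsv`,
#' `cpg_site_matrix.tsv`, `strand_totals.tsv` and `multi_feature_regions.tsv`
#' in `config$out_dir`, plus an aligned-text rendering
#' `comparative_report.txt`.
#'
#' @param config The [run_config()] used for [run_scan()].
#' @return Invisibly, a list with `islands`, `matrix`, `totals`, `multi`
#'   data frames and the [compare_species()] object as `comparison`.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  labels <- config$inputs$label
  todo <- if (config$strands == "both") c("L", "H") else config$strands
  missing <- character(0)
  for (lab in labels) {
    for (s in todo) {
      f <- file.path(config$out_dir, paste0(lab, ".", s, ".islands.tsv"))
      if (!file.exists(f)) missing <- c(missing, lab)
    }
  }
  if (length(missing) > 0) {
    stop(
      "missing scan outputs for species: ",
      paste(unique(missing), collapse = ", "),
      "; run run_scan() first",
      call. = FALSE
    )
  }
  islands <- do.call(rbind, lapply(labels, function(lab) {
    do.call(rbind, lapply(todo, function(s) {
      df <- read_tsv(file.path(
        config$out_dir,
        paste0(lab, ".", s, ".islands.tsv")
      ))
      if (nrow(df) == 0) {
        return(NULL)
      }
      cbind(species = lab, df, stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(islands)) {
    islands <- data.frame(
      species = character(0), start = integer(0), end = integer(0),
      region = character(0), length = integer(0), cg_sum = integer(0),
      pct_cg = numeric(0), obs_exp = numeric(0), strand = character(0)
    )
  }
  summaries <- list()
  multi <- list()
  for (i in seq_len(nrow(config$inputs))) {
    lab <- labels[i]
    ann_path <- file.path(config$out_dir, paste0(lab, ".annotations.tsv"))
    if (!file.exists(ann_path)) next
    ann <- read_tsv(ann_path)
    summ <- build_summary(ann,
      species = lab,
      group = config$inputs$group[i]
    )
    summaries[[lab]] <- summ
    if (nrow(summ$multi_feature) > 0) {
      multi[[lab]] <- cbind(
        species = lab, summ$multi_feature,
        stringsAsFactors = FALSE
      )
    }
  }
  multi <- if (length(multi) > 0) {
    do.call(rbind, multi)
  } else {
    data.frame(
      species = character(0), start = integer(0), end = integer(0),
      strand = character(0), cpg_count = integer(0), features = character(0),
      n_features = integer(0), classification = character(0)
    )
  }
  rownames(multi) <- NULL
  comparison <- NULL
  mat <- data.frame(
    feature = character(0), species = character(0), group = character(0),
    strand = character(0), count = numeric(0)
  )
  totals <- data.frame(
    species = character(0), group = character(0), strand = character(0),
    total = numeric(0)
  )
  if (length(summaries) >= 2) {
    comparison <- compare_species(unname(summaries))
    mat <- comparison$matrix
    totals <- comparison$totals
  } else if (length(summaries) == 1) {
    s <- summaries[[1]]
    totals <- data.frame(
      species = s$species, group = s$group, strand = c("L", "H"),
      total = as.numeric(s$strand_totals[c("L", "H")]),
      stringsAsFactors = FALSE
    )
  }
  write_tsv(islands, file.path(config$out_dir, "islands_by_strand.tsv"))
  write_tsv(mat, file.path(config$out_dir, "cpg_site_matrix.tsv"))
  write_tsv(totals, file.path(config$out_dir, "strand_totals.tsv"))
  write_tsv(multi, file.path(config$out_dir, "multi_feature_regions.tsv"))
  writeLines(
    render_comparative_report(islands, mat, totals, multi),
    file.path(config$out_dir, "comparative_report.txt")
  )
  invisible(list(
    islands = islands, matrix = mat, totals = totals, multi = multi,
    comparison = comparison
  ))
}

# Fixed-width text rendering of the comparative tables; deterministic, no
# timestamps.
render_comparative_report <- function(islands, mat, totals, multi) {
  fmt_df <- function(df) {
    if (nrow(df) == 0) {
      return("  (none)")
    }
    txt <- utils::capture.output(print(df, row.names = FALSE))
    paste0("  ", txt)
  }
  c(
    "== CpG islands per species and strand ==",
    fmt_df(islands),
    "",
    "== CpG sites per feature (single-feature regions) ==",
    fmt_df(mat),
    "",
    "== CpG sites per strand (all regions) ==",
    fmt_df(totals),
    "",
    "== Regions overlapping more than one feature ==",
    fmt_df(multi)
  )
}

#' Scan locally stored reference genomes
#'
#' Reproduction helper for the published comparative analysis of the twelve
#' reference mitochondrial genomes: given a directory of FASTA files named
#' `<accession>.fasta` (see `scripts/fetch_references.R` for a download
#' helper; this package never downloads), scans each genome on both strands
#' with the supplied parameters and returns per-species island tables and
#' strand totals.
#'
#' @param dir Directory containing `<accession>.fasta` files.
#' @param accessions Character vector of accessions to analyse (defaults to
#'   the twelve-species manifest shipped in
#'   `system.file("extdata", "reference_manifest.tsv", package = "mitocpg")`).
#' @param scan,seek,attribution Passed to [scan_genome()].
#' @return A list with `islands` (per-species island report rows) and
#'   `strand_totals` (species x strand CpG-site totals).
#' @export
reproduce_reference_tables <- function(dir,
                                       accessions = NULL,
                                       scan = scan_params(),
                                       seek = seek_params(),
                                       attribution = "cover") {
  manifest <- utils::read.table(
    system.file("extdata", "reference_manifest.tsv", package = "mitocpg"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE
  )
  if (is.null(accessions)) accessions <- manifest$accession
  islands <- list()
  totals <- list()
  for (acc in accessions) {
    path <- file.path(dir, paste0(acc, ".fasta"))
    if (!file.exists(path)) {
      stop("reference FASTA not found: ", path,
        "\nFetch the sequences first (see scripts/fetch_references.R).",
        call. = FALSE
      )
    }
    g <- read_fasta(path)
    g$id <- acc
    res <- scan_genome(g,
      scan = scan, seek = seek, strands = "both",
      attribution = attribution
    )
    isl <- island_report(res$islands)
    if (nrow(isl) > 0) {
      islands[[acc]] <- cbind(accession = acc, isl, stringsAsFactors = FALSE)
    }
    totals[[acc]] <- data.frame(
      accession = acc,
      L = region_sites(res$regions[res$regions$strand == "L", ]),
      H = region_sites(res$regions[res$regions$strand == "H", ]),
      stringsAsFactors = FALSE
    )
  }
  list(
    islands = if (length(islands) > 0) {
      do.call(rbind, c(islands, list(make.row.names = FALSE)))
    } else {
      NULL
    },
    strand_totals = do.call(rbind, c(totals, list(make.row.names = FALSE)))
  )
}
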