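#!/usr/bin/env Rscript
# Downloads the twelve reference mitochondrial genomes analysed in the
# comparative study (see inst/extdata/reference_manifest.tsv) from NCBI
# E-utilities into a local directory as <accession>.fasta. Needs network
# access; the mitocpg package itself never downloads.
#
#   Rscript scripts/fetch_references.R [dest_dir]
#
# Default destination is tests/testthat/references/, where the
# reproduction tests in tests/testthat/test-acceptance.R look for them.

args <- commandArgs(trailingOnly = TRUE)
dest <- if (length(args) >= 1) args[1] else "tests/testthat/references"
dir.create(dest, showWarnings = FALSE, recursive = TRUE)

manifest_path <- system.file("extdata", "reference_manifest.tsv",
  package = "mitocpg"
)
if (manifest_path == "") manifest_path <- "inst/extdata/reference_manifest.tsv"
manifest <- read.table(manifest_path, header = TRUE, sep = "\t")

base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
for (acc in manifest$accession) {
  out <- file.path(dest, paste0(acc, ".fasta"))
  if (file.exists(out)) {
    message(acc, " already present")
    next
  }
  url <- sprintf(
    "%s?db=nuccore&id=%s&rettype=fasta&retmode=text", base, acc
  )
  message("fetching ", acc)
  download.file(url, out, quiet = TRUE, mode = "wb")
  Sys.sleep(0.4) # E-utilities rate limit
}
message("done; sequences in ", dest)
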