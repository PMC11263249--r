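#!/usr/bin/env Rscript

# Download the deposited mitogenome records of six Hymenochaetales species
# as GenBank flat files, for running the mitocomp pipeline on real data.
#
# Usage:
#   Rscript scripts/fetch_genbank.R [outdir]
#
# Requires network access to NCBI E-utilities. No test or validation
# script depends on this; it is a convenience for users with connectivity.

args <- commandArgs(trailingOnly = TRUE)
outdir <- if (length(args) >= 1) args[1] else "genbank_records"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

accessions <- c(
  Inonotus_hispidus          = "ON969135",
  Phellinus_gilvus           = "OP265749",
  Phellinus_viticola         = "OP141808",
  Porodaedalea_chrysoloma    = "OP141806",
  Phellinus_ferrugineofuscus = "OP141805",
  Porodaedalea_niemelaei     = "OP141804")

base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
for (sp in names(accessions)) {
  acc <- accessions[[sp]]
  url <- sprintf("%s?db=nuccore&id=%s&rettype=gbwithparts&retmode=text",
                 base, acc)
  dest <- file.path(outdir, paste0(sp, "_", acc, ".gb"))
  message("fetching ", acc, " (", sp, ") -> ", dest)
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  Sys.sleep(0.5) # stay within NCBI's unauthenticated request rate
}
message("done: ", length(accessions), " records in ", outdir)
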