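#!/usr/bin/env Rscript
# OPTIONAL, network-using helper: download the GSE2240 (U133A) series matrix
# from GEO and run the full pipeline on it in both basis conventions.
# Nothing in the package or its tests depends on this script.
#
#   Rscript scripts/reproduce_gse2240.R [--out DIR]
#
# Sample classes are assigned from the series metadata: samples whose
# characteristics/title mention atrial fibrillation are cases, the
# sinus-rhythm samples controls. Expect the duplicate collapse to leave 29
# samples (19 controls); score-scale quantities depend on the value scale of
# the deposited matrix and on the basis convention, so both are reported
# rather than asserted.

suppressPackageStartupMessages(library(apcadeg))

args <- commandArgs(trailingOnly = TRUE)
out_root <- if (length(args) >= 2L && args[1L] == "--out") args[2L] else "gse2240_results"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

url <- "https://ftp.ncbi.nlm.nih.gov/geo/series/GSE2nnn/GSE2240/matrix/GSE2240-GPL96_series_matrix.txt.gz"
gz <- file.path(out_root, basename(url))
if (!file.exists(gz)) {
  message("downloading ", url)
  utils::download.file(url, gz, mode = "wb")
}

# class labels from the metadata lines
meta <- readLines(gzfile(gz), warn = FALSE)
acc <- strsplit(grep("^!Sample_geo_accession", meta, value = TRUE)[1L], "\t")[[1L]][-1L]
acc <- gsub('"', "", acc)
chr_lines <- grep("^!Sample_(characteristics|title|source_name)", meta, value = TRUE)
desc <- apply(do.call(rbind, strsplit(chr_lines, "\t")), 2L, paste, collapse = " ")[-1L]
is_af <- grepl("fibrillation|\\bAF\\b", desc, ignore.case = TRUE) &
  !grepl("no history|sinus", desc, ignore.case = TRUE)
labels <- stats::setNames(ifelse(is_af, "case", "control"), acc)
message("classes: ", sum(labels == "control"), " control / ",
        sum(labels == "case"), " case")

txt <- file.path(out_root, "series_matrix.txt")
writeLines(meta, txt)

for (mode in c("raw", "orthonormal")) {
  message("=== basis mode: ", mode, " ===")
  res <- apca_run(txt, labels = labels, a = 0.3, b = 20, basis = mode,
                  out_dir = file.path(out_root, mode))
  cat(res$log, sep = "\n")
  cat(sprintf("max |score| = %.4f at %s; theta = %d; %d probes / %d genes called\n",
              max(abs(res$scores$score)),
              res$scores$probe_id[which.max(abs(res$scores$score))],
              res$theta, res$degs$n_probes, res$degs$n_genes))
}
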