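#!/usr/bin/env Rscript
# Align the top-50 windows, tally the frequency matrix, compute per-column
# information content and call the consensus motif. Writes results/logo.tsv.

suppressPackageStartupMessages(library(mazfscan))

cand <- read.delim("results/candidates.tsv", stringsAsFactors = FALSE)
fm <- build_frequency_matrix(cand$window)
tab <- logo_table(fm, alphabet = "RNA")
write_results_table(tab, "results/logo.tsv")

call <- call_consensus(fm, alphabet = "RNA")
cat("consensus:", call$consensus, "\n")
if (!is.null(call$called_span)) {
  cat(sprintf("called span: positions %d..%d (cleavage 5' of position %d)\n",
              call$called_span[1], call$called_span[2], call$cut_offset))
}
cat(sprintf("IC at -1/0/+1: %s bits\n",
            paste(sprintf("%.2f", call$ic[fm$labels %in% -1:1]),
                  collapse = "/")))
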