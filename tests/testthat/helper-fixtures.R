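# Shared fixture builders; all randomness is locally seeded.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

write_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Printed per-CDS parameters shipped with the package (replay inputs).
published_params <- function() {
  read.delim(system.file("extdata", "nitrosomonas_ugg_burden_params.tsv",
                         package = "mazfscan"), stringsAsFactors = FALSE)
}
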