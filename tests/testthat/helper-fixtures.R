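# write a detailed-links TSV from a data.frame of rows
write_links_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- c("chemical1", "chemical2", "similarity", "experimental",
              "database", "textmining", "combined_score")
  stopifnot(identical(names(rows), header))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

links_row <- function(c1, c2, combined, textmining = 0, similarity = 0,
                      experimental = 0, database = 0) {
  data.frame(chemical1 = c1, chemical2 = c2, similarity = similarity,
             experimental = experimental, database = database,
             textmining = textmining, combined_score = combined,
             stringsAsFactors = FALSE)
}
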