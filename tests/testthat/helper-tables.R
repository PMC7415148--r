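# Shared helpers: write a data.frame as a delimited temp file, and pull the
# abundance matrix of a simulated lipid table.

writeTempTable <- function(df, sep = ",", ext = ".csv", preamble = NULL) {
  path <- tempfile(fileext = ext)
  lines <- c(preamble,
             paste(names(df), collapse = sep),
             vapply(seq_len(nrow(df)), function(i)
               paste(vapply(df[i, ], function(v)
                 if (is.numeric(v)) sprintf("%.17g", v)
                 else as.character(v), character(1)),
                     collapse = sep), character(1)))
  writeLines(lines, path)
  path
}

simAbundances <- function(sim) {
  m <- as.matrix(as.data.frame(sim$table)[, -1, drop = FALSE])
  rownames(m) <- NULL
  m
}
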