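# Independent dip oracle: linear programs over piecewise-linear unimodal
# CDFs, solved by scipy's HiGHS backend via the shipped python helper (one
# batched call). Used only as a reference in tests.
dip_oracle_batch <- function(cases) {
  tool <- system.file("tools", "dip_lp_oracle.py", package = "tpgfuse")
  stopifnot(nzchar(tool))
  inp <- tempfile(fileext = ".json")
  on.exit(unlink(inp), add = TRUE)
  writeLines(jsonlite::toJSON(cases, digits = NA), inp)
  out <- system2("python", shQuote(tool), stdout = TRUE, stdin = inp)
  as.numeric(jsonlite::fromJSON(paste(out, collapse = "")))
}
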