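withr_local_csv <- function(lines, env = parent.frame()) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  withr::defer(unlink(f), envir = env)
  f
}

bind_reports <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("srs_reports", "data.frame")
  out
}
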