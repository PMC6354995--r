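# Deterministic substream seeds: every stochastic operation derives its own
# seed from (master seed, string labels) so datasets are pure functions of
# (config, seed) regardless of evaluation order.  Plain polynomial string
# hash kept below 2^31; doubles stay exact (31 * 2^31 + 255 << 2^53).
hash_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "\r")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483629
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# numbers written so that read.delim() restores them to ~1e-15 relative
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
  }
  df
}

write_tsv <- function(df, path) {
  write.table(format_num_df(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

read_tsv <- function(path) read.delim(path, sep = "\t", stringsAsFactors = FALSE)
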