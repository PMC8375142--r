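# Internal helpers shared across modules.

# Stop with a consistent error class so callers/tests can assert on it.
evi_abort <- function(msg, ..., class = "rnaevi_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

evi_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a data.frame as TSV with full double precision so that a re-read
# reproduces identical values (round-trip contract of the master table).
write_tsv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""), ...)
}

# case-insensitive symbol canonicalisation used for GMT/TRRUST matching
canon_symbol <- function(x) toupper(trimws(x))
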