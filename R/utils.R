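`%||%` <- function(a, b) if (is.null(a)) b else a

# Delimiter chosen from extension: .tsv/.txt are tab, everything else comma.
.table_sep <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

.read_table <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.table(path, header = TRUE, sep = .table_sep(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", comment.char = "", na.strings = c("NA", ""))
}

.write_table <- function(df, path) {
  utils::write.table(df, path, sep = .table_sep(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

# Lexicographic midranks over the rows of a data.frame of sort keys.
# NA is treated as +Inf (sorts after every finite value at each level,
# censored-vs-censored falls through to the next key). Rows identical on
# every key share the mean of the positions they occupy.
.lex_midrank <- function(keys) {
  keys <- as.data.frame(lapply(keys, function(v) {
    v <- as.numeric(v)
    v[is.na(v)] <- Inf
    v
  }))
  n <- nrow(keys)
  o <- do.call(order, keys)
  sorted <- keys[o, , drop = FALSE]
  new_group <- !duplicated(sorted)
  grp_sorted <- cumsum(new_group)
  rank_sorted <- stats::ave(seq_len(n), grp_sorted, FUN = mean)
  out <- numeric(n)
  grp <- integer(n)
  out[o] <- rank_sorted
  grp[o] <- grp_sorted
  list(rank = out, tie_group = grp)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
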