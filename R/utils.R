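# Internal fast data-frame helpers: data.frame() spends most of its time
# deparsing argument names and checking inputs, which matters inside the
# Monte-Carlo simulation loops. Columns are taken as given (equal-length
# atomic vectors, no factor conversion).

.df <- function(...) {
  l <- list(...)
  n <- max(lengths(l))
  short <- lengths(l) == 1L & n > 1L
  l[short] <- lapply(l[short], rep.int, n)
  structure(l, class = "data.frame", row.names = .set_row_names(n))
}

.rbind_df <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(NULL)
  cols <- names(lst[[1]])
  out <- lapply(cols, function(cc) unlist(lapply(lst, `[[`, cc),
                                          use.names = FALSE))
  names(out) <- cols
  structure(out, class = "data.frame",
            row.names = .set_row_names(length(out[[1]])))
}
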