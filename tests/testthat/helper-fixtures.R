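# Shared fixture builders; everything is generated in code at test time.

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_window <- function(with_x = FALSE) {
  letters_pool <- if (with_x) c(aa20, "X") else aa20
  paste(sample(letters_pool, 16, replace = TRUE), collapse = "")
}

tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

tmp_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# small labelled window set with an artificial D-at-P1 signal, for cheap
# model-training tests
toy_window_set <- function(n_pos = 25, n_neg = 75, seed = 42) {
  set.seed(seed)
  pos <- vapply(seq_len(n_pos), function(i) {
    w <- sample(aa20, 16, replace = TRUE)
    w[8] <- "D"
    paste(w, collapse = "")
  }, character(1))
  neg <- vapply(seq_len(n_neg), function(i) {
    w <- sample(setdiff(aa20, "D"), 16, replace = TRUE)
    paste(w, collapse = "")
  }, character(1))
  list(windows = c(pos, neg), labels = c(rep(1L, n_pos), rep(0L, n_neg)))
}

small_grid <- function() {
  expand.grid(cost = c(1, 8), gamma = c(0.01, 0.05), epsilon = 0.1,
              KEEP.OUT.ATTRS = FALSE)
}
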