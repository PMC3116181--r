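# Shared helpers: tiny in-code fixtures for the unit tests.

# A valid 4-sample composition with simple round numbers (rows sum to 100).
tiny_composition <- function() {
  vals <- rbind(
    c(10, 5, 5, 15, 5, 5, 5, 1, 5, 2, 4, 8, 4, 6, 3, 5, 11, 1),
    c(12, 4, 6, 14, 4, 4, 6, 2, 4, 1, 5, 7, 5, 5, 4, 6, 10, 1),
    c(8, 6, 4, 16, 6, 6, 4, 1, 6, 1, 3, 9, 3, 7, 2, 4, 12, 2),
    c(11, 5, 5, 15, 5, 5, 5, 1, 5, 1, 4, 8, 4, 6, 3, 5, 11, 1)
  )
  colnames(vals) <- aapls::aa_labels
  aapls::composition_matrix(vals, sample_ids = paste0("T", 1:4))
}

# Write a delimited composition file and return its path.
write_tiny_composition_csv <- function(path = tempfile(fileext = ".csv"),
                                       drop_col = NULL, sep = ",") {
  comp <- tiny_composition()
  df <- data.frame(sample_id = rownames(comp), unclass(comp),
                   check.names = FALSE)
  if (!is.null(drop_col)) df[[drop_col]] <- NULL
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# Random well-conditioned regression instance for oracle comparisons.
random_instance <- function(n, p, seed) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("V", seq_len(p))))
  y <- stats::rnorm(n)
  list(x = x, y = y)
}
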