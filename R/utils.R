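# Internal helpers shared across modules.

# Deterministic substream seed derivation: the scenario seed plus a stream
# index give an integer seed below 2^31, so day k's draws do not depend on
# what happens on other days. Exact in double arithmetic (< 2^53).
derive_seed <- function(seed, index) {
  base <- (abs(as.numeric(seed)) %% 2147483587) + 1
  as.integer((base * 48271 + as.numeric(index) * 9973) %% 2147483629)
}

# Column names used for feature coordinates: f0 ... f{dim-1}.
feature_names <- function(dim) paste0("f", seq_len(dim) - 1L)

# Extract the feature block of a stream/embedding tibble as a numeric matrix.
feature_matrix <- function(data) {
  cols <- grep("^f[0-9]+$", names(data), value = TRUE)
  if (length(cols) == 0L) {
    abort("no feature columns (f0, f1, ...) found in `data`.")
  }
  cols <- cols[order(as.integer(sub("^f", "", cols)))]
  m <- as.matrix(data[cols])
  storage.mode(m) <- "double"
  m
}

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
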