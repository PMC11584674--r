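# shared internal helpers

sample_cols <- function(counts) setdiff(names(counts), "feature_id")

# wide counts tibble (feature_id + one column per sample) -> numeric matrix
as_count_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "feature_id" %in% names(counts))
  if (anyDuplicated(counts$feature_id)) {
    abort("duplicate feature_id values in count table")
  }
  m <- as.matrix(counts[, sample_cols(counts), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$feature_id
  m
}

matrix_to_tibble <- function(m) {
  dplyr::bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# distance from a point to a 0-based half-open interval (0 when inside)
point_interval_distance <- function(pos, start, end) {
  pmax(0L, start - pos, pos - end)
}
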