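# Internal helpers shared across modules.

# Deterministic 32-bit seed derived from a master seed and a string id, so
# individual tubes can be re-simulated without replaying the whole experiment.
# Plain polynomial rolling hash; stays below 2^31 - 1.
derive_seed <- function(master_seed, id) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  mod <- 2147483563
  h <- as.numeric(master_seed) %% mod
  for (ch in utf8ToInt(as.character(id))) {
    h <- (h * 31 + ch) %% mod
  }
  as.integer(h)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

is_qsip_data <- function(x) inherits(x, "qsip_data")

assert_qsip_data <- function(x) {
  if (!is_qsip_data(x)) {
    abort("expected a `qsip_data` object (see `qsip_data()` / `load_qsip_data()`)")
  }
  invisible(x)
}
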