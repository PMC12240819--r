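# internal helpers shared across modules

# Derive a vector of child seeds from one master seed, reproducibly and
# independently of the caller's RNG state. Values stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

# Stop with a classed condition so callers/tests can catch specific failures.
ct_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "coretrans_error"))
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    ct_abort(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "coretrans_format_error"
    )
  }
  invisible(df)
}

# Sample standard deviation (n - 1). The population variant (n) is kept as an
# explicit option surfaced by `sd_convention` arguments.
ct_sd <- function(x, convention = c("sample", "population")) {
  convention <- match.arg(convention)
  if (convention == "sample") return(stats::sd(x))
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Median with the even-length midpoint rule (stats::median already does this;
# wrapped to make the convention explicit and greppable).
ct_median <- function(x) stats::median(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == as.integer(x)
}
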