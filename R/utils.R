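# shared condition helpers and small numerics

vvs_abort <- function(msg, class = "vvsreadout_invalid_argument") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

vvs_abort_missing_data <- function(msg) {
  vvs_abort(msg, class = "vvsreadout_missing_data")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Pearson correlation that returns NA (without warning) when either side is
# constant; used wherever a degenerate fold/split must be recorded as missing.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Muffle only warnings whose message matches `pattern`; anything else
# propagates. Used around fits whose small-sample or exact-fit notes are
# expected by design (tiny synthetic configs, trivially perfect fits).
muffle_warning <- function(expr, pattern) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl(pattern, conditionMessage(w))) invokeRestart("muffleWarning")
  })
}

# Average a 2-D map down to at most g x g cells (block means). Used to expose
# convolutional layers at a fixed, low-dimensional spatial resolution.
pool_to_grid <- function(m, g = 7L) {
  n1 <- nrow(m); n2 <- ncol(m)
  if (n1 <= g && n2 <= g) return(m)
  b1 <- if (n1 <= g) seq_len(n1) else as.integer(cut(seq_len(n1), g, labels = FALSE))
  b2 <- if (n2 <= g) seq_len(n2) else as.integer(cut(seq_len(n2), g, labels = FALSE))
  out <- rowsum(m, b1)
  out <- t(rowsum(t(out), b2))
  cnt <- tabulate(b1)[seq_len(nrow(out))] %o% tabulate(b2)[seq_len(ncol(out))]
  out / cnt
}
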