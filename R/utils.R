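# Shared internal helpers.

# Round half away from zero (paper-style display rounding), not banker's.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Numeric-aware label ordering: allele labels are opaque strings, but when all
# labels parse as numbers they sort numerically ("10" after "9").
label_order <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  if (!anyNA(n)) order(n, x) else order(x, method = "radix")
}

sort_labels <- function(x) x[label_order(x)]

# Zero-padded form used to make lexicographic composition order numeric-aware.
pad_label <- function(x) {
  n <- suppressWarnings(as.integer(x))
  ifelse(!is.na(n) & n >= 0, sprintf("%08d", n), x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

allele_key <- function(locus, label) paste(locus, label, sep = "|")
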