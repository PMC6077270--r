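# Internal helpers shared across modules.

#' @importFrom stats rnorm rpois runif quantile
#' @importFrom utils write.csv read.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_eduquant <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "eduquant_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_eduquant(sprintf("`%s` must be a single finite number", name),
                  "eduquant_validation_error")
  if ((strict && x <= min) || (!strict && x < min))
    stop_eduquant(sprintf("`%s` must be %s %s, got %s", name,
                          if (strict) ">" else ">=", format(min), format(x)),
                  "eduquant_validation_error")
  x
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, min = min)
  if (x != round(x))
    stop_eduquant(sprintf("`%s` must be an integer", name),
                  "eduquant_validation_error")
  as.integer(x)
}

# Separable convolution as banded-matrix multiplication (BLAS-backed), with
# replicate (edge-clamp) boundary handling so structures touching the frame
# edge are not mixed with wrap-around content. Exact and deterministic.
# band_matrix(n, k): dense n x n operator applying 1-D kernel k (odd length)
# along one dimension; out-of-range taps are clamped to the border sample,
# so each row sums to sum(k) regardless of position.
band_matrix <- function(n, k) {
  p <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  rows <- seq_len(n)
  for (j in seq_along(k)) {
    src <- pmin(pmax(rows + j - p - 1L, 1L), n)
    idx <- cbind(rows, src)
    K[idx] <- K[idx] + k[j]
  }
  K
}

gaussian_kernel_1d <- function(sigma, half = max(2L, ceiling(4 * sigma))) {
  t <- (-half):half
  g <- exp(-t^2 / (2 * sigma^2))
  g / sum(g)
}

gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  g <- gaussian_kernel_1d(sigma)
  Kr <- band_matrix(nrow(mat), g)
  Kc <- band_matrix(ncol(mat), g)
  Kr %*% mat %*% t(Kc)
}

# Binary disk stamped on an existing-size canvas; boundary-inclusive (<= r^2),
# the same membership rule used for ROI counting.
disk_mask <- function(nrow, ncol, center_row, center_col, radius) {
  rr <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  ((rr - center_row)^2 + (cc - center_col)^2 <= radius^2) * 1L
}

# Deterministic 31-bit sub-seed derivation: a Lehmer-style mix of the master
# seed and a stream index, kept exact in double precision (48271 * 2^31 < 2^53).
# Stable across platforms; documented in the methods vignette.
mix_seed <- function(master_seed, index) {
  m <- 2147483647
  h <- (abs(master_seed) %% m)
  h <- (h * 48271) %% m
  h <- (h + index %% m) %% m
  h <- (h * 48271) %% m
  as.integer(h)
}

# 31-bit polynomial string hash (h = h*33 + byte mod 2^31-1) used only to label
# provenance records with a reproducible config fingerprint.
string_hash31 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 5381
  m <- 2147483647
  for (b in bytes) h <- (h * 33 + b) %% m
  sprintf("%08x", h)
}

# Fixed-format numeric CSV writer: deterministic, locale-independent text for
# artifact files (counts stay integral, reals get 15 significant digits).
write_table_csv <- function(df, path) {
  fmt <- function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      out <- vapply(col, function(v) {
        if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
      }, character(1))
      out
    } else col
  }
  out <- as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE,
                       check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
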