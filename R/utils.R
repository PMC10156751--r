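# Internal helpers shared across modules.

#' Centered moving average with shrunken edge windows
#'
#' Edges average over the available frames only; no padding values are
#' invented, so a constant series stays constant and the output length
#' equals the input length.
#'
#' @param x numeric vector.
#' @param window odd integer window width (frames), >= 1.
#' @return numeric vector, same length as `x`.
#' @keywords internal
#' @noRd
moving_average <- function(x, window) {
  n <- length(x)
  if (n == 0L) stop("cannot smooth an empty series (no frames)")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("smoothing window must be an odd integer >= 1")
  }
  if (window == 1L) return(as.numeric(x))
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(as.numeric(x)))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# 32-bit FNV-1a over a character scalar; returns 8-char hex
fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (h may exceed the 32-bit signed range)
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # multiply mod 2^32 in 16-bit halves (a direct product would exceed
    # the exact-double range)
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# deterministic sub-seed derivation; stays below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

provenance_line <- function(seed = NA, config_hash = NA) {
  ver <- as.character(utils::packageVersion("facefwd"))
  sprintf("# facefwd %s seed=%s config=%s", ver, seed, config_hash)
}

# write a data.frame as CSV with a single '#' provenance comment line
write_csv_prov <- function(df, path, seed = NA, config_hash = NA) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_line(seed, config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_prov <- function(path, ...) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
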