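# Half-open interval arithmetic on numeric time (seconds since epoch).
# All interval sets are data.frames with columns start < end, kept sorted.
# Convention throughout the package: an interval covers [start, end).

iv <- function(start = numeric(0), end = numeric(0)) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  stopifnot(length(start) == length(end))
  keep <- is.finite(start) & is.finite(end) & end > start
  out <- data.frame(start = start[keep], end = end[keep])
  out[order(out$start, out$end), , drop = FALSE]
}

iv_empty <- function() iv()

# Merge intervals closer than `gap`. With open = FALSE intervals separated by
# exactly `gap` are merged (touching intervals merge at gap = 0); with
# open = TRUE the separation must be strictly below `gap` to merge, which is
# the episode closing rule ("not fulfilled for a minimum of 24 h" ends an
# episode, so a gap of exactly 24 h separates).
iv_merge <- function(x, gap = 0, open = FALSE) {
  if (nrow(x) < 2) return(x)
  x <- x[order(x$start, x$end), , drop = FALSE]
  out_s <- numeric(0); out_e <- numeric(0)
  cs <- x$start[1]; ce <- x$end[1]
  for (i in 2:nrow(x)) {
    d <- x$start[i] - ce
    joins <- if (open) d < gap else d <= gap
    if (joins) {
      ce <- max(ce, x$end[i])
    } else {
      out_s <- c(out_s, cs); out_e <- c(out_e, ce)
      cs <- x$start[i]; ce <- x$end[i]
    }
  }
  iv(c(out_s, cs), c(out_e, ce))
}

iv_union <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, nrow, 0L) > 0]
  if (!length(parts)) return(iv_empty())
  iv_merge(do.call(rbind, parts))
}

iv_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(iv_empty())
  s <- pmax(rep(a$start, each = nrow(b)), rep(b$start, times = nrow(a)))
  e <- pmin(rep(a$end, each = nrow(b)), rep(b$end, times = nrow(a)))
  iv_merge(iv(s, e))
}

# a minus b
iv_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(iv_empty())
  b <- iv_merge(b)
  if (nrow(b) == 0) return(a)
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    s <- a$start[i]; e <- a$end[i]
    for (j in seq_len(nrow(b))) {
      bs <- b$start[j]; be <- b$end[j]
      if (be <= s || bs >= e) next
      if (bs > s) { out_s <- c(out_s, s); out_e <- c(out_e, bs) }
      s <- max(s, be)
      if (s >= e) break
    }
    if (s < e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
  }
  iv(out_s, out_e)
}

iv_clip <- function(x, lo, hi) {
  if (nrow(x) == 0) return(x)
  iv(pmax(x$start, lo), pmin(x$end, hi))
}

iv_length <- function(x) if (nrow(x) == 0) 0 else sum(x$end - x$start)

# membership of time points in a merged, sorted interval set
iv_covers <- function(x, t) {
  if (nrow(x) == 0) return(rep(FALSE, length(t)))
  x <- iv_merge(x)
  bounds <- as.vector(rbind(x$start, x$end))
  findInterval(t, bounds) %% 2 == 1
}

# TRUE iff every point of a lies inside the union of b
iv_subset_of <- function(a, b) iv_length(iv_setdiff(a, b)) < 1e-9
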