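# Independent brute-force oracles. These deliberately re-derive results by
# enumeration / direct definition rather than sharing code with the package.

# Centred moving average with truncated edges, O(n * w).
oracle_moving_average <- function(v, half) {
  n <- length(v)
  vapply(seq_len(n),
         function(i) mean(v[max(1, i - half):min(n, i + half)]),
         numeric(1))
}

# Exhaustive segment-and-max peak scan: enumerate every above-threshold
# sample, group contiguous runs, merge runs closer than the gap, take the
# earliest maximum of each group.
oracle_detect_peaks <- function(trace, cfg) {
  v <- trace$values
  tt <- trace_times(trace)
  above <- which(v >= cfg$threshold)
  if (!length(above))
    return(data.frame(time_s = numeric(0), amplitude_mV = numeric(0)))
  segs <- unname(split(above, cumsum(c(1, diff(above) != 1))))
  gap <- cfg$min_peak_gap * trace$sample_rate
  merged <- list(segs[[1]])
  for (s in segs[-1]) {
    last <- merged[[length(merged)]]
    if (s[1] - last[length(last)] - 1 < gap)
      merged[[length(merged)]] <- c(last, s)
    else merged[[length(merged) + 1]] <- s
  }
  idx <- vapply(merged, function(s) s[which.max(v[s])], numeric(1))
  data.frame(time_s = tt[idx], amplitude_mV = v[idx])
}

# Brute-force rasterized disk area: enumerate every pixel centre.
oracle_disk_area <- function(cx, cy, r, width, height) {
  n <- 0L
  for (x in 0:(width - 1))
    for (y in 0:(height - 1))
      if ((x - cx)^2 + (y - cy)^2 <= r^2) n <- n + 1L
  n
}

# Peak height of a Gaussian pulse passed through a one-pole low-pass,
# computed by direct numeric convolution on a fine grid (independent of the
# recursive filter in the package).
oracle_filtered_peak <- function(amplitude, fwhm, tau, fs_fine = 20000) {
  dt <- 1 / fs_fine
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  tg <- seq(-6 * sig, 6 * sig + 12 * tau, by = dt)
  g <- amplitude * exp(-(tg - 0)^2 / (2 * sig^2))
  th <- seq(0, 12 * tau, by = dt)
  h <- exp(-th / tau)
  h <- h / sum(h)
  y <- stats::convolve(g, rev(h), type = "open")
  max(y)
}

# Optimal one-to-one assignment (max pairs, then min total |dt|) by
# exhaustive search, split into connected components so it stays feasible
# on sparse instances.
oracle_match <- function(crossings, peak_times, window) {
  dt <- abs(outer(crossings, peak_times, `-`))
  ok <- dt <= window
  # connected components over the bipartite candidate graph
  nt <- length(crossings)
  np <- length(peak_times)
  comp <- rep(NA_integer_, nt + np)   # tracks then peaks
  cid <- 0L
  for (s in seq_len(nt)) {
    if (!is.na(comp[s]) || !any(ok[s, ])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      if (u <= nt) {
        nb <- which(ok[u, ]) + nt
      } else {
        nb <- which(ok[, u - nt])
      }
      fresh <- nb[is.na(comp[nb])]
      comp[fresh] <- cid
      queue <- c(queue, fresh)
    }
  }
  best_pairs <- NULL
  for (k in seq_len(cid)) {
    trs <- which(comp[seq_len(nt)] == k)
    pks <- which(comp[nt + seq_len(np)] == k)
    best <- list(npairs = -1L, total = Inf, pairs = NULL)
    rec <- function(i, used, pairs, total) {
      if (i > length(trs)) {
        np_ <- nrow(pairs) %||% 0L
        if (np_ > best$npairs ||
            (np_ == best$npairs && total < best$total))
          best <<- list(npairs = np_, total = total, pairs = pairs)
        return(invisible())
      }
      rec(i + 1L, used, pairs, total)  # leave track i unmatched
      for (p in pks[!pks %in% used]) {
        if (ok[trs[i], p])
          rec(i + 1L, c(used, p),
              rbind(pairs, data.frame(track = trs[i], peak = p)),
              total + dt[trs[i], p])
      }
    }
    rec(1L, integer(0), NULL, 0)
    best_pairs <- rbind(best_pairs, best$pairs)
  }
  if (is.null(best_pairs))
    best_pairs <- data.frame(track = integer(0), peak = integer(0))
  best_pairs[order(best_pairs$track), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
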