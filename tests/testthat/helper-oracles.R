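# Independent oracles, kept deliberately naive: brute-force window scans
# and exhaustive enumerations against which the fast implementations are
# checked.

# Brute-force I-DT: at each position find the longest window with
# dispersion <= thr by recomputing dispersion from scratch over every
# candidate window; emit if it reaches the minimum duration, else slide.
# Invalid samples split the trace into independent segments.
oracle_idt <- function(t, x, y, valid, dispersion, min_dur, period) {
  out <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                    duration_ms = numeric(0), cx = numeric(0), cy = numeric(0))
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    tt <- t[idx]; xx <- x[idx]; yy <- y[idx]
    n <- length(tt)
    i <- 1L
    while (i <= n) {
      jbest <- NA_integer_
      for (j in i:n) {
        disp <- (max(xx[i:j]) - min(xx[i:j])) + (max(yy[i:j]) - min(yy[i:j]))
        if (disp <= dispersion) jbest <- j else break
      }
      if (!is.na(jbest) && tt[jbest] + period - tt[i] >= min_dur) {
        out <- rbind(out, data.frame(
          onset_ms = tt[i], offset_ms = tt[jbest] + period,
          duration_ms = tt[jbest] + period - tt[i],
          cx = mean(xx[i:jbest]), cy = mean(yy[i:jbest])))
        i <- jbest + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  out
}

# Per-sample recount of the epoch curve: rasterize fixations onto a fine
# sample grid and recount eyes / (eyes + face) samples per window.
oracle_epoch_curve <- function(fixations, window, step, duration_ms,
                               rate = 300) {
  period <- 1000 / rate
  t_s <- seq(0, duration_ms - period, by = period)
  lab <- rep("none", length(t_s))
  for (i in seq_len(nrow(fixations))) {
    inside <- t_s >= fixations$onset_ms[i] & t_s < fixations$offset_ms[i]
    lab[inside] <- fixations$aoi[i]
  }
  starts <- seq(0, duration_ms - window, by = step)
  vapply(starts, function(s) {
    w <- t_s >= s & t_s < s + window
    ne <- sum(lab[w] == "eyes"); nf <- sum(lab[w] == "face")
    if (ne + nf > 0) ne / (ne + nf) else NA_real_
  }, 0)
}

# Exhaustive cluster-permutation p-values by direct enumeration of all
# group relabelings, written independently of the package internals.
oracle_cluster_p <- function(curves, groups, cluster_alpha = 0.05) {
  g <- factor(groups)
  n <- nrow(curves)
  n1 <- sum(g == levels(g)[1])
  tstat <- function(idx1) {
    vapply(seq_len(ncol(curves)), function(j) {
      a <- curves[idx1, j]; b <- curves[setdiff(seq_len(n), idx1), j]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) return(NA_real_)
      tryCatch(unname(t.test(a, b)$statistic), error = function(e) NA_real_)
    }, 0)
  }
  dfw <- function(idx1) {
    vapply(seq_len(ncol(curves)), function(j) {
      a <- curves[idx1, j]; b <- curves[setdiff(seq_len(n), idx1), j]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) return(NA_real_)
      tryCatch(unname(t.test(a, b)$parameter), error = function(e) NA_real_)
    }, 0)
  }
  clusters_of <- function(t, df) {
    crit <- qt(1 - cluster_alpha / 2, df)
    sup <- !is.na(t) & abs(t) > crit
    masses <- numeric(0); bounds <- list()
    i <- 1
    while (i <= length(t)) {
      if (!sup[i]) { i <- i + 1; next }
      j <- i
      while (j < length(t) && sup[j + 1] && sign(t[j + 1]) == sign(t[i])) j <- j + 1
      masses <- c(masses, sum(t[i:j])); bounds[[length(bounds) + 1]] <- c(i, j)
      i <- j + 1
    }
    list(masses = masses, bounds = bounds)
  }
  obs_idx <- which(g == levels(g)[1])
  obs <- clusters_of(tstat(obs_idx), dfw(obs_idx))
  combos <- combn(n, n1)
  null_max <- apply(combos, 2, function(idx) {
    cl <- clusters_of(tstat(idx), dfw(idx))
    if (length(cl$masses) == 0) 0 else max(abs(cl$masses))
  })
  p <- vapply(obs$masses, function(m) mean(null_max >= abs(m)), 0)
  list(masses = obs$masses, bounds = obs$bounds, p = p, null_max = null_max)
}
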