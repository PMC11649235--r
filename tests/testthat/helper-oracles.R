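# Independent brute-force oracles the detectors and statistics are checked
# against. These deliberately use naive frame-by-frame scans and textbook
# formulas, not the package's own code paths.

# frame-by-frame run-length scan for sub-threshold runs of >= min_dur
oracle_freeze <- function(v, t, fps, eps, min_dur) {
  dt <- 1 / fps
  out <- data.frame(start_s = numeric(0), end_s = numeric(0))
  i <- 1
  n <- length(v)
  while (i <= n) {
    if (v[i] < eps) {
      j <- i
      while (j < n && v[j + 1] < eps) j <- j + 1
      if ((j - i + 1) * dt >= min_dur - 1e-9) {
        out <- rbind(out, data.frame(start_s = t[i], end_s = t[j] + dt))
      }
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# frame-by-frame hysteresis state machine for darts
oracle_darts <- function(v, t, fps, v_start, v_stop, min_frames) {
  dt <- 1 / fps
  out <- data.frame(start_s = numeric(0), end_s = numeric(0))
  armed <- FALSE
  open <- 0
  n <- length(v)
  for (i in seq_len(n)) {
    if (open > 0) {
      if (v[i] < v_stop) {
        if ((i - 1) - open + 1 >= min_frames) {
          out <- rbind(out, data.frame(start_s = t[open], end_s = t[i - 1] + dt))
        }
        open <- 0
        armed <- TRUE
      }
    } else {
      if (v[i] < v_stop) armed <- TRUE
      else if (armed && v[i] > v_start) open <- i
    }
  }
  if (open > 0 && n - open + 1 >= min_frames) {
    out <- rbind(out, data.frame(start_s = t[open], end_s = t[n] + dt))
  }
  out
}

# interval-overlap F1: greedy one-to-one matching at IoU >= 0.5
bout_f1 <- function(truth, detected, iou = 0.5) {
  if (nrow(truth) == 0 && nrow(detected) == 0) return(1)
  if (nrow(truth) == 0 || nrow(detected) == 0) return(0)
  used <- rep(FALSE, nrow(detected))
  tp <- 0
  for (i in seq_len(nrow(truth))) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(detected))) {
      if (used[j]) next
      inter <- max(0, min(truth$end_s[i], detected$end_s[j]) -
                     max(truth$start_s[i], detected$start_s[j]))
      uni <- max(truth$end_s[i], detected$end_s[j]) -
        min(truth$start_s[i], detected$start_s[j])
      r <- inter / uni
      if (r > best) { best <- r; bj <- j }
    }
    if (best >= iou) { tp <- tp + 1; used[bj] <- TRUE }
  }
  prec <- tp / nrow(detected)
  rec <- tp / nrow(truth)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# textbook Welch statistic / Welch-Satterthwaite df / two-sided p
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# explicit sums-of-squares one-way ANOVA
oracle_anova1 <- function(samples) {
  all <- unlist(samples)
  gm <- mean(all)
  ssb <- sum(vapply(samples, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(samples, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(samples) - 1
  df2 <- length(all) - length(samples)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

# a speed_series from a bare numeric vector
speed_of <- function(v, fps = 30) {
  structure(tibble::tibble(t_s = (seq_along(v) - 1) / fps, v_cms = v),
            class = c("speed_series", "tbl_df", "tbl", "data.frame"),
            fps = fps)
}
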