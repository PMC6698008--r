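# Independent oracles used across the suite. These deliberately use naive
# algorithms (flood fill, exhaustive scans, hand-rolled risk sets) so they
# share no code with the implementation they check.

# BFS flood-fill connected-component labeling
flood_fill_labels <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  }
  cur <- 0L
  for (c in seq_len(w)) for (r in seq_len(h)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r, c)); lab[r, c] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# partitions equal up to label renaming
same_partition <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  if (!identical(a > 0, b > 0)) return(FALSE)
  pos <- a > 0
  key <- paste(a[pos], b[pos])
  length(unique(key)) == length(unique(a[pos])) &&
    length(unique(key)) == length(unique(b[pos]))
}

# exhaustive Youden scan over all midpoints, both orientations
youden_oracle <- function(values, outcome) {
  u <- sort(unique(values))
  cuts <- (u[-length(u)] + u[-1]) / 2
  best <- list(j = -Inf)
  for (dir in c("high_positive", "low_positive")) {
    for (c in cuts) {
      test_pos <- if (dir == "high_positive") values > c else values <= c
      sens <- mean(test_pos[outcome == 1])
      spec <- mean(!test_pos[outcome == 0])
      j <- sens + spec - 1
      if (j > best$j + 1e-12) best <- list(cutoff = c, j = j, dir = dir)
    }
  }
  best
}

# hand-rolled two-group log-rank statistic over risk sets
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group)) # 1/2
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# small default slide used in several tests
small_slide <- function(seed = 11, target = 0.05, n_vessels = 15,
                        size = c(120, 600), wh = 320, excluded = 0) {
  generate_slide(slide_spec(wh, wh, target_positive_fraction = target,
                            vessel_count = n_vessels,
                            vessel_size_range_px = size,
                            excluded_fraction = excluded, seed = seed))
}
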