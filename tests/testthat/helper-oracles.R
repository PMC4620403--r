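# Independent brute-force oracles, kept deliberately naive.

# O(n^2) minimal covering sector: try every phase as the sector start and
# take the maximal wrapped offset to any other phase; the answer is the
# start minimizing that span (ties toward the smallest start).
brute_smallest_sector <- function(phases_deg) {
  ph <- sort(deg_mod(phases_deg))
  best_span <- Inf
  best_start <- NA_real_
  for (s in ph) {
    span <- max(deg_mod(ph - s))
    if (span < best_span - 1e-12 ||
        (abs(span - best_span) <= 1e-12 && s < best_start)) {
      best_span <- span
      best_start <- s
    }
  }
  list(start = best_start, span = best_span)
}

# Recursive-free flood fill component labelling.
brute_label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  comp <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- ((cur - 1L) %% nr) + 1L
      cl <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(nb))) {
        r2 <- r + nb[k, 1]; c2 <- cl + nb[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        j <- (c2 - 1L) * nr + r2
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- comp
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# Canonical partition signature of a labelling (invariant to label order).
component_signature <- function(lab) {
  groups <- split(which(lab != 0), lab[lab != 0])
  sorted <- lapply(groups, sort)
  unname(sorted[order(vapply(sorted, min, numeric(1)))])
}

# Midpoint-grid approximation of a sector split (0.1 degree grid).
grid_split_sector <- function(start, span, region, table = aha_segment_table(),
                              step = 0.1) {
  if (span <= 0) return(numeric(0))
  mids <- deg_mod(start + seq(step / 2, span, by = step))
  ids <- assign_pixel_to_segment(mids, region, table)
  tab <- table(ids) * step
  stats::setNames(as.numeric(tab), names(tab))
}
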