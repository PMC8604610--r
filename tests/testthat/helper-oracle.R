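# Independent brute-force oracle for proximity clustering: transitive
# closure by repeated set merging over the full O(n^2) distance table.
# Deliberately naive and separate from the package's graph-based path.
brute_force_cluster <- function(pts, threshold) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  member <- seq_len(n)
  d <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(d[i, ] <= threshold & member != member[i])
      if (length(linked)) {
        merged <- min(member[i], member[linked])
        member[member %in% c(member[i], member[linked])] <- merged
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  member
}

# Canonical form of a partition: sorted list of sorted member index sets,
# so two membership vectors can be compared regardless of cluster ids.
partition_canonical <- function(membership) {
  parts <- unname(split(seq_along(membership), membership))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, min, integer(1)))]
}

expect_same_partition <- function(a, b) {
  expect_identical(partition_canonical(a), partition_canonical(b))
}

# Small solid-color frame with optional bright-green pixels at given
# 0-based (x, y) coordinates.
make_test_frame <- function(h, w, green_at = NULL, g = 255L, bg = 0L,
                            frame_index = 0L) {
  px <- array(0L, dim = c(h, w, 3L))
  px[, , 2] <- bg
  if (!is.null(green_at)) {
    for (i in seq_len(nrow(green_at))) {
      px[green_at$y[i] + 1L, green_at$x[i] + 1L, 2L] <- g
    }
  }
  new_frame(px, frame_index = frame_index)
}

# Stamp a filled disk of green value `g` into a frame (0-based center).
stamp_disk <- function(frame, cx, cy, r, g = 255L) {
  px <- unclass(frame)
  for (dy in -ceiling(r):ceiling(r)) {
    for (dx in -ceiling(r):ceiling(r)) {
      if (dx^2 + dy^2 <= r^2) {
        px[cy + dy + 1L, cx + dx + 1L, 2L] <- as.integer(g)
      }
    }
  }
  new_frame(px, frame_index = frame_index(frame))
}
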