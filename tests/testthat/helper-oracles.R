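# Independent oracles and fixture builders used across the suite.

# 6-connectivity check by breadth-first flood fill from the first voxel.
is_connected6 <- function(arr) {
  idx <- which(arr != 0)
  if (length(idx) <= 1L) return(TRUE)
  d <- dim(arr)
  visited <- array(FALSE, d)
  queue <- idx[1L]
  visited[queue] <- TRUE
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ijk <- arrayInd(v, d)
    for (r in seq_len(6L)) {
      p <- ijk + nbr[r, , drop = FALSE]
      if (any(p < 1L) || any(p > d)) next
      li <- p[1L] + (p[2L] - 1L) * d[1L] + (p[3L] - 1L) * d[1L] * d[2L]
      if (arr[li] != 0 && !visited[li]) {
        visited[li] <- TRUE
        queue <- c(queue, li)
      }
    }
  }
  all(visited[idx])
}

# All permutations of 1..n (n! rows), lexicographic; used for the
# exhaustive permutation oracle at tiny n.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Random binary lesion masks on a small grid (not blob-shaped; for
# matrix-algebra tests where geometry is irrelevant).
random_masks <- function(n, d = c(6L, 6L, 4L), prob = 0.3, seed = 1L,
                         voxel_dims = c(1, 1, 1)) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    lapply(seq_len(n), function(i) {
      lesion_mask(array(rbinom(prod(d), 1L, prob), d),
                  voxel_dims = voxel_dims,
                  subject_id = sprintf("s%02d", i))
    })
  })
}

# A valid random span curve honoring the stop rule at threshold 0.75.
random_span_curve <- function(task) {
  b <- list(phonological_digit_matching = list(2L, 6L, c(6L, 8L, 6L, 8L, 10L)),
            semantic_category_probe = list(1L, 4L, c(8L, 8L, 12L, 16L)))[[task]]
  lens <- seq(b[[1L]], b[[2L]])
  nt <- b[[3L]]
  nc <- integer(0)
  used <- integer(0)
  for (i in seq_along(lens)) {
    k <- rbinom(1L, nt[i], runif(1, 0.3, 1))
    used <- c(used, i)
    nc <- c(nc, k)
    if (k / nt[i] < 0.75) break
  }
  span_curve(task, lens[used], nt[used], nc)
}
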