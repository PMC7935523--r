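# Independent oracles, written from first principles and kept separate from
# the package's own geometry/metric code paths.

# interior angle at vertex i of polygon v (degrees), via dot product
oracle_angle <- function(v, i) {
  n <- nrow(v)
  a <- v[if (i == 1) n else i - 1, ] - v[i, ]
  b <- v[if (i == n) 1 else i + 1, ] - v[i, ]
  acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
}

oracle_angles <- function(v) vapply(seq_len(nrow(v)), oracle_angle, 0, v = v)

# are edges (i,i+1) and (j,j+1) parallel? cross product of unit directions
oracle_parallel <- function(v, i, j, tol_deg = 0.5) {
  n <- nrow(v)
  e <- function(k) {
    d <- v[if (k == n) 1 else k + 1, ] - v[k, ]
    d / sqrt(sum(d^2))
  }
  ei <- e(i); ej <- e(j)
  abs(ei[1] * ej[2] - ei[2] * ej[1]) < sin(tol_deg * pi / 180)
}

oracle_side_lengths <- function(v) {
  n <- nrow(v)
  vapply(seq_len(n), function(i) {
    sqrt(sum((v[if (i == n) 1 else i + 1, ] - v[i, ])^2))
  }, 0)
}

# shoelace area
oracle_area <- function(v) {
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
  }
  abs(s) / 2
}

# point-to-segment distance (for clearance checks)
oracle_pt_seg <- function(p, a, b) {
  d <- b - a
  t <- sum((p - a) * d) / sum(d^2)
  t <- max(0, min(1, t))
  sqrt(sum((a + t * d - p)^2))
}

# brute-force HAUC: explicit loop, no vectorized shortcuts
oracle_hauc <- function(curve, k) {
  total <- 0
  for (e in 1:k) total <- total + (curve[e] - 50)
  total
}

# closed-form simple OLS slope and Pearson r
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxy <- sum(x * y); sxx <- sum(x^2); syy <- sum(y^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  list(slope = slope, r = r)
}

# flood-fill connected component count in pure R (tiny masks only)
oracle_components <- function(mask, eight = TRUE) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  moves <- if (eight) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  for (i0 in seq_len(nrow(mask))) {
    for (j0 in seq_len(ncol(mask))) {
      if (!mask[i0, j0] || lab[i0, j0]) next
      nxt <- nxt + 1L
      queue <- list(c(i0, j0))
      lab[i0, j0] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (m in seq_len(nrow(moves))) {
          ni <- p[1] + moves[m, 1]; nj <- p[2] + moves[m, 2]
          if (ni >= 1 && ni <= nrow(mask) && nj >= 1 && nj <= ncol(mask) &&
              mask[ni, nj] && !lab[ni, nj]) {
            lab[ni, nj] <- nxt
            queue <- c(queue, list(c(ni, nj)))
          }
        }
      }
    }
  }
  nxt
}

# small in-memory dataset shared by protocol tests
tiny_dataset <- function(categories, n = 6, seed = 11, canvas = 128) {
  generate_images(categories, n_per_category = n, master_seed = seed,
                  canvas_size = canvas)
}
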