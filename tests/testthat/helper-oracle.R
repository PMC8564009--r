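# Brute-force GLCM oracle: explicit loop over every pixel pair at the
# given (row, col) offset. Independent of the package's vectorized path.
brute_glcm_counts <- function(levels, n_levels, dr, dc) {
  h <- nrow(levels); w <- ncol(levels)
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
          !is.na(levels[r, c]) && !is.na(levels[r2, c2])) {
        i <- levels[r, c] + 1; j <- levels[r2, c2] + 1
        counts[i, j] <- counts[i, j] + 1
      }
    }
  }
  counts
}

brute_offset <- function(angle_deg, d) {
  switch(as.character(angle_deg),
         "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
}

brute_glcm <- function(levels, n_levels, distance, angles_deg,
                       symmetric, average) {
  per <- lapply(angles_deg, function(a) {
    off <- brute_offset(a, distance)
    cm <- brute_glcm_counts(levels, n_levels, off[1], off[2])
    if (symmetric) cm <- cm + t(cm)
    cm / sum(cm)
  })
  if (average || length(per) == 1) Reduce(`+`, per) / length(per) else per
}

# statistics straight from the moment definitions, scalar accumulation
brute_stats <- function(g) {
  n <- nrow(g)
  homog <- contrast <- energy <- mu_x <- mu_y <- eij <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    p <- g[i + 1, j + 1]
    homog <- homog + p / (1 + (i - j)^2)
    contrast <- contrast + (i - j)^2 * p
    energy <- energy + p^2
    mu_x <- mu_x + i * p; mu_y <- mu_y + j * p
    eij <- eij + i * j * p
  }
  vx <- vy <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    p <- g[i + 1, j + 1]
    vx <- vx + (i - mu_x)^2 * p
    vy <- vy + (j - mu_y)^2 * p
  }
  corr <- if (vx <= .Machine$double.eps || vy <= .Machine$double.eps) 0
          else (eij - mu_x * mu_y) / sqrt(vx * vy)
  c(homogeneity = homog, contrast = contrast, energy = energy,
    correlation = corr)
}
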