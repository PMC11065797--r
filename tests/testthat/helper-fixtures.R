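# shared fixtures: everything is generated in code, nothing stored on disk

desk_config <- function(seed = 101L, n = 128L)
  cohort_config(image_size = n, seed = seed)

# one deterministic diseased/healthy phantom pair at desk scale, cached per
# session because generation is not free
local({
  cache <- new.env(parent = emptyenv())
  fixture_phantom <<- function(diseased = TRUE, seed = 101L, n = 128L) {
    key <- paste(diseased, seed, n)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_phantom(paste0("FIX", seed), diseased,
                                      desk_config(seed, n), seed = seed)
    cache[[key]]
  }
  fixture_series <<- function(views = c(16L, 64L, 256L), seed = 101L,
                              n = 64L, windowed = TRUE) {
    key <- paste("vs", paste(views, collapse = "-"), seed, n, windowed)
    if (is.null(cache[[key]])) {
      ph <- fixture_phantom(TRUE, seed, n)
      vs <- make_view_series(ph$image, view_counts = views,
                             subject_id = ph$subject_id)
      if (windowed) vs <- window_view_series(vs)
      cache[[key]] <- vs
    }
    cache[[key]]
  }
})

# a centred disk image, the classic projection test object
disk_image <- function(n = 64, radius = n / 4, value = 1) {
  d <- sqrt(outer((seq_len(n) - (n + 1) / 2)^2,
                  (seq_len(n) - (n + 1) / 2)^2, "+"))
  matrix(as.numeric(d <= radius) * value, n, n)
}

# tiny synthetic residual pairs with a learnable (smooth sinusoidal) artifact
toy_pairs <- function(n_pairs, size = 64L, seed = 1L, subject_prefix = "S") {
  with_seed <- function(s, e) { set.seed(s); e }
  set.seed(seed)
  lapply(seq_len(n_pairs), function(i) {
    g <- expand.grid(y = seq_len(size), x = seq_len(size))
    f1 <- runif(1, 0.05, 0.2); f2 <- runif(1, 0.05, 0.2)
    full <- matrix(0.5 + 0.3 * sin(f1 * g$y) * cos(f2 * g$x), size, size)
    artifact <- matrix(0.1 * sin(0.8 * g$x + runif(1, 0, pi)), size, size)
    make_residual_pair(full, pmin(pmax(full + artifact, 0), 1), 64L,
                       paste0(subject_prefix, i))
  })
}

# independent brute-force oracles ------------------------------------------

bf_mse <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + (a[i, j] - b[i, j])^2
  s / (nrow(a) * ncol(a))
}

bf_dice <- function(a, b) {
  na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  if (na == 0 || nb == 0 || ni == 0) return(0)
  2 * ni / (na + nb)
}

# textbook SSIM: explicit loop over gaussian windows
bf_ssim <- function(a, b, data_range = 1, K1 = 0.01, K2 = 0.03,
                    size = 11L, sigma = 1.5) {
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  x <- seq_len(size) - (size + 1) / 2
  k1d <- exp(-x^2 / (2 * sigma^2)); k1d <- k1d / sum(k1d)
  w <- outer(k1d, k1d)
  vals <- c()
  for (i in seq_len(nrow(a) - size + 1)) {
    for (j in seq_len(ncol(a) - size + 1)) {
      wa <- a[i:(i + size - 1), j:(j + size - 1)]
      wb <- b[i:(i + size - 1), j:(j + size - 1)]
      mua <- sum(w * wa); mub <- sum(w * wb)
      va <- sum(w * wa^2) - mua^2; vb <- sum(w * wb^2) - mub^2
      cab <- sum(w * wa * wb) - mua * mub
      vals <- c(vals, ((2 * mua * mub + C1) * (2 * cab + C2)) /
                  ((mua^2 + mub^2 + C1) * (va + vb + C2)))
    }
  }
  mean(vals)
}

# classical (non-clustered) signed-rank test, normal approximation, average
# ranks for ties, zeros dropped — the reduction target for the clustered test
bf_signed_rank <- function(d, alternative = "greater") {
  d <- d[d != 0]
  r <- rank(abs(d))
  tstat <- sum(sign(d) * r)
  z <- tstat / sqrt(sum(r^2))
  p <- switch(alternative,
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z),
              two.sided = 2 * pnorm(abs(z), lower.tail = FALSE))
  list(t = tstat, z = z, p = p)
}

# single connected component check (4-connectivity flood fill)
is_connected <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(FALSE)
  n <- nrow(mask)
  visited <- matrix(FALSE, n, ncol(mask))
  queue <- idx[1]
  visited[queue] <- TRUE
  count <- 0
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]; count <- count + 1
    i <- (p - 1) %% n + 1; j <- (p - 1) %/% n + 1
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= ncol(mask) &&
          mask[ii, jj] && !visited[ii, jj]) {
        visited[ii, jj] <- TRUE
        queue <- c(queue, ii + (jj - 1) * n)
      }
    }
  }
  count == sum(mask)
}
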