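# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# construct a raw vector with exactly the requested mean, sd and n
raw_with_summary <- function(mean, sd, n) {
  z <- seq_len(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# brute-force two-sided Fisher p: enumerate every table with the observed
# margins, sum the probabilities of tables no more probable than observed
fisher_bruteforce <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); N <- sum(tab)
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  }, numeric(1))
  p_obs <- probs[match(tab[1, 1], a_range)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# bracket matcher by depth profile rather than an explicit stack
match_pairs_depth <- function(db) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  pair <- integer(n)
  depth <- cumsum((ch == "(") - (ch == ")"))
  for (i in which(ch == "(")) {
    d <- depth[i]
    js <- which(ch == ")" & depth == d - 1L)
    j <- js[js > i][1]
    pair[i] <- j; pair[j] <- i
  }
  pair
}

# brute-force in-plane erosion: keep a pixel iff every disc offset stays
# inside the mask (per-pixel neighbourhood scan; slow but transparent)
erode_bruteforce <- function(mask2d, r) {
  d <- dim(mask2d)
  out <- matrix(FALSE, d[1], d[2])
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!mask2d[i, j]) next
    xi <- i + offs$dx; yj <- j + offs$dy
    inside <- xi >= 1 & xi <= d[1] & yj >= 1 & yj <= d[2]
    out[i, j] <- all(inside) && all(mask2d[cbind(xi, yj)])
  }
  out
}

# a small noiseless phantom reused by several tests (kept small for speed)
small_phantom <- function(seed = 42, noise_sd_hu = 0) {
  generate_ct_phantom(phantom_spec(
    bone_length_mm = 80, bone_radius_mm = 12, voxel_spacing_mm = c(0.8, 0.8, 1),
    n_fat_voxels_per_region = c(epiphysis = 100L, metaphysis = 150L,
                                diaphysis = 200L),
    noise_sd_hu = noise_sd_hu, seed = seed))
}
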