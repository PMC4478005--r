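# Shared fixtures, built in code.

# Regular polygon approximating a circle.
circleOutline <- function(r = 1, centre = c(0, 0), n = 256L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# Small specimen table with valid fields.
makeSpecimens <- function(n = 6L, pops = c("A", "B")) {
  data.frame(
    specimen_id = sprintf("F%02d", seq_len(n)),
    population_id = rep(pops, length.out = n),
    latitude = 60 + seq_len(n) / 10,
    longitude = 5,
    length_cm = 25 + seq_len(n),
    age_years = rep(c(4L, 7L, 10L), length.out = n),
    year = 2012L,
    stringsAsFactors = FALSE
  )
}

# Random wavelet-descriptor object over `n` specimens of length `nAngles`
# radii near 1; groups alternate over `pops`.
makeDescriptors <- function(n = 8L, nAngles = 64L, pops = c("A", "B"),
                            seed = 1) {
  set.seed(seed)
  radii <- matrix(runif(n * nAngles, 0.9, 1.1), n)
  rownames(radii) <- sprintf("F%02d", seq_len(n))
  sp <- makeSpecimens(n, pops)
  buildDescriptors(radii, sp, family = "haar")
}

# Explicit orthonormal Haar analysis matrix for length-8 signals at full
# depth, written out by hand (not via the package's pyramid algorithm):
# rows are the discrete Haar basis functions, coarse to fine, with the
# high-pass sign convention g = (1, -1)/sqrt(2).
haarMatrix8 <- function() {
  rbind(
    rep(1, 8) / sqrt(8),                       # scaling, level 3
    c(1, 1, 1, 1, -1, -1, -1, -1) / sqrt(8),   # detail, level 3
    c(1, 1, -1, -1, 0, 0, 0, 0) / 2,           # detail, level 2
    c(0, 0, 0, 0, 1, 1, -1, -1) / 2,
    c(1, -1, 0, 0, 0, 0, 0, 0) / sqrt(2),      # detail, level 1
    c(0, 0, 1, -1, 0, 0, 0, 0) / sqrt(2),
    c(0, 0, 0, 0, 1, -1, 0, 0) / sqrt(2),
    c(0, 0, 0, 0, 0, 0, 1, -1) / sqrt(2)
  )
}
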