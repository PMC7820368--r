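# Independent oracles and fixture builders shared across tests.

# Noise-scaled projection form of the RNL chromatic distance, written
# independently of the closed-form implementation: scale signal
# differences by 1/omega, project off the achromatic direction
# (1/omega_1, ..., 1/omega_n), take the Euclidean norm.
proj_delta_s <- function(df, omega) {
  x <- df / omega
  u <- 1 / omega
  uhat <- u / sqrt(sum(u^2))
  resid <- x - sum(x * uhat) * uhat
  sqrt(sum(resid^2))
}

# random symmetric disparity matrix with named species
random_disparity <- function(n, names = sprintf("s%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(names, names))
  vals <- runif(n * (n - 1) / 2, 0.5, 10)
  m[upper.tri(m)] <- vals
  m + t(m)
}

# flat spectrum helper
flat_spectrum <- function(value, kind = "reflectance",
                          wl = seq(300, 700, by = 1)) {
  chromacomm::spectrum(wl, rep(value, length(wl)), kind = kind)
}

# exhaustive mean of community mean disparities over all subsets of size k
exhaustive_null_mean <- function(d, k) {
  idx <- utils::combn(nrow(d), k)
  mean(apply(idx, 2, function(s) sum(d[s, s]) / (k * (k - 1))))
}

# write a two-column CSV and return its path
write_spec_file <- function(wl, val, header = c("wl", "reflectance")) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(stats::setNames(data.frame(wl, val), header), f,
                   row.names = FALSE)
  f
}
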