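## Independent oracles used across the suite. Each re-derives a quantity
## by brute force / enumeration so the package code path is never its
## own check.

## RMSF by an explicit double loop over snapshots and atoms
brute_force_rmsf <- function(ensemble) {
  co <- ensemble$coords
  m <- dim(co)[1]; n <- dim(co)[2]
  per_atom <- numeric(n)
  for (j in seq_len(n)) {
    mean_pos <- c(mean(co[, j, 1]), mean(co[, j, 2]), mean(co[, j, 3]))
    acc <- 0
    for (i in seq_len(m))
      acc <- acc + sum((co[i, j, ] - mean_pos)^2)
    per_atom[j] <- sqrt(acc / m)
  }
  res <- sort(unique(ensemble$residue))
  vapply(res, function(r) mean(per_atom[ensemble$residue == r]), numeric(1))
}

## OLS slope via the closed-form normal equations
normal_equations_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

## Consistency proportion by explicit enumeration
enumerate_consistency <- function(fc, slope, threshold) {
  n_cons <- 0L; n_det <- 0L
  for (i in seq_along(fc)) {
    if (abs(slope[i]) <= threshold) next
    if (fc[i] == 1 || slope[i] == 0) next
    n_det <- n_det + 1L
    if ((fc[i] > 1 && slope[i] > 0) || (fc[i] < 1 && slope[i] < 0))
      n_cons <- n_cons + 1L
  }
  if (n_det == 0L) NA_real_ else n_cons / n_det
}

## Random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}
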