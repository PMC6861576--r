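# Brute-force tensor oracles, independent of the package's scalar
# reductions: full symmetric tensors, explicit-summation contractions and
# explicit index-by-index rotation.

beta_names <- c("xxx", "xxy", "xxz", "xyy", "xyz", "xzz", "yyy", "yyz", "yzz", "zzz")
gamma_names <- c("xxxx", "yyyy", "zzzz", "xxyy", "xxzz", "yyzz")

axis_index <- c(x = 1L, y = 2L, z = 3L)

# full 3x3x3 symmetric tensor from the 10 Kleinman components
beta_array <- function(b) {
  arr <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    key <- paste(c("x", "y", "z")[sort(c(i, j, k))], collapse = "")
    arr[i, j, k] <- b[[key]]
  }
  arr
}

beta_components <- function(arr) {
  vapply(beta_names, function(nm) {
    idx <- axis_index[strsplit(nm, "")[[1]]]
    arr[idx[1], idx[2], idx[3]]
  }, numeric(1))
}

# beta_total by explicit summation over the full tensor
beta_total_oracle <- function(arr) {
  bvec <- vapply(1:3, function(i) sum(vapply(1:3, function(j) arr[i, j, j], numeric(1))),
                 numeric(1))
  sqrt(sum(bvec^2))
}

rotate_beta <- function(arr, R) {
  out <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    s <- 0
    for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
      s <- s + R[i, a] * R[j, b] * R[k, cc] * arr[a, b, cc]
    }
    out[i, j, k] <- s
  }
  out
}

# fully symmetric random rank-4 tensor (symmetrized over all 24 permutations)
random_gamma_array <- function() {
  raw <- array(rnorm(81), c(3, 3, 3, 3))
  out <- array(0, c(3, 3, 3, 3))
  perms <- list(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 2, 4), c(1, 3, 4, 2),
                c(1, 4, 2, 3), c(1, 4, 3, 2), c(2, 1, 3, 4), c(2, 1, 4, 3),
                c(2, 3, 1, 4), c(2, 3, 4, 1), c(2, 4, 1, 3), c(2, 4, 3, 1),
                c(3, 1, 2, 4), c(3, 1, 4, 2), c(3, 2, 1, 4), c(3, 2, 4, 1),
                c(3, 4, 1, 2), c(3, 4, 2, 1), c(4, 1, 2, 3), c(4, 1, 3, 2),
                c(4, 2, 1, 3), c(4, 2, 3, 1), c(4, 3, 1, 2), c(4, 3, 2, 1))
  for (p in perms) out <- out + aperm(raw, p)
  out / 24
}

gamma_components <- function(arr) {
  c(xxxx = arr[1, 1, 1, 1], yyyy = arr[2, 2, 2, 2], zzzz = arr[3, 3, 3, 3],
    xxyy = arr[1, 1, 2, 2], xxzz = arr[1, 1, 3, 3], yyzz = arr[2, 2, 3, 3])
}

# isotropic average by explicit double contraction
gamma_average_oracle <- function(arr) {
  s <- 0
  for (i in 1:3) for (j in 1:3) s <- s + arr[i, i, j, j]
  s / 5
}

rotate_gamma <- function(arr, R) {
  out <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- 0
    for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (d in 1:3) {
      s <- s + R[i, a] * R[j, b] * R[k, cc] * R[l, d] * arr[a, b, cc, d]
    }
    out[i, j, k, l] <- s
  }
  out
}

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# named component vector with all zeros except those supplied
beta_vec <- function(...) {
  b <- setNames(rep(0, 10), beta_names)
  dots <- c(...)
  b[names(dots)] <- dots
  b
}

gamma_vec <- function(...) {
  g <- setNames(rep(0, 6), gamma_names)
  dots <- c(...)
  g[names(dots)] <- dots
  g
}

# study molecule inputs in the layout photovoltaic_table() wants
benzil_pv_inputs <- function() {
  benzil_molecules() |>
    dplyr::mutate(
      f = purrr::map_dbl(excitations, ~ .x$f[1]),
      lambda_max_nm = purrr::map_dbl(excitations, ~ .x$lambda_nm[1])
    )
}
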