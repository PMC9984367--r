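# Independent brute-force oracles, deliberately naive so they share no code
# paths with the package implementation.

# Minkowski functionals by explicit pixel loops: V, S via pair counting and
# chi via flood-fill component counts (white 8-connected, black 4-connected).
oracle_minkowski <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  N <- nr * nc
  N_w <- sum(mask)
  nb <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r < nr && mask[r, c] != mask[r + 1, c]) nb <- nb + 1L
    if (c < nc && mask[r, c] != mask[r, c + 1]) nb <- nb + 1L
  }
  comps <- function(m, diag) {
    seen <- matrix(FALSE, nr, nc)
    cnt <- 0L
    for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
      if (!m[r0, c0] || seen[r0, c0]) next
      cnt <- cnt + 1L
      stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        offs <- if (diag) expand.grid(dr = -1:1, dc = -1:1)
                else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
        for (k in seq_len(nrow(offs))) {
          r2 <- p[1] + offs$dr[k]; c2 <- p[2] + offs$dc[k]
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              m[r2, c2] && !seen[r2, c2]) {
            seen[r2, c2] <- TRUE
            stack[[length(stack) + 1]] <- c(r2, c2)
          }
        }
      }
    }
    cnt
  }
  C_w <- comps(mask, diag = TRUE)
  C_b <- comps(!mask, diag = FALSE)
  list(V = 100 * N_w / N, S = 100 * nb / N, chi = (C_w - C_b) / N,
       N_bound = nb, C_w = C_w, C_b = C_b)
}

# Structure function by explicit loops over axis-aligned pixel pairs.
oracle_structure_function <- function(z, max_lag) {
  nr <- nrow(z); nc <- ncol(z)
  vapply(seq_len(max_lag), function(tau) {
    s <- 0; n <- 0
    for (r in seq_len(nr - tau)) for (c in seq_len(nc)) {
      s <- s + (z[r + tau, c] - z[r, c])^2; n <- n + 1
    }
    for (r in seq_len(nr)) for (c in seq_len(nc - tau)) {
      s <- s + (z[r, c + tau] - z[r, c])^2; n <- n + 1
    }
    s / n
  }, numeric(1))
}

# Circular autocorrelation by explicit shifted products.
oracle_autocorrelation <- function(z) {
  z <- z - mean(z)
  nr <- nrow(z); nc <- ncol(z)
  R <- matrix(0, nr, nc)
  for (dr in 0:(nr - 1)) for (dc in 0:(nc - 1)) {
    zs <- z[((seq_len(nr) - 1 + dr) %% nr) + 1,
            ((seq_len(nc) - 1 + dc) %% nc) + 1]
    R[dr + 1, dc + 1] <- sum(z * zs)
  }
  R / R[1, 1]
}

random_mask <- function(nr, nc, p = 0.5) {
  matrix(runif(nr * nc) < p, nr, nc)
}

disc_mask <- function(n, centers, radii) {
  xs <- matrix(seq_len(n), n, n)
  ys <- matrix(seq_len(n), n, n, byrow = TRUE)
  m <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(centers)))
    m <- m | ((xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= radii[i]^2)
  m
}

# Build a structure_function object from a bare (tau, S) table, for fitting
# tests on analytic curves.
make_sf <- function(tau_um, S_tau, Sq, pixel_scale = 1) {
  out <- data.frame(tau_um = tau_um, S_tau = S_tau)
  attr(out, "Sq") <- Sq
  attr(out, "pixel_scale") <- pixel_scale
  class(out) <- c("structure_function", class(out))
  out
}
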