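# Independent oracles used to cross-check the analytic scattering code.
# They share no code with the package internals beyond the public
# form-factor accessor.

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# construction of the Jacobi matrix.
gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# Numerical orientational average of |sum_i F_i exp(i q k . r_i)|^2 over
# the sphere of scattering directions k: Gauss-Legendre in cos(theta)
# (80 nodes) and a uniform (spectrally convergent) grid in phi.
orient_avg_oracle <- function(g, qs, sigma = dw_params(), n_ct = 80, n_ph = 128) {
  xyz <- solute_coords(g)
  gl <- gauss_legendre(n_ct)
  ph <- seq(0, 2 * pi, length.out = n_ph + 1)[-(n_ph + 1)]
  vapply(qs, function(q) {
    Fi <- atomic_form_factor(q, "I") * exp(-q^2 * sigma^2 / 2)
    tot <- 0
    for (m in seq_len(n_ct)) {
      ct <- gl$x[m]; st <- sqrt(1 - ct^2)
      kx <- st * cos(ph); ky <- st * sin(ph); kz <- ct
      A <- 0 + 0i
      for (i in 1:3) {
        A <- A + Fi[i] * exp(1i * q * (kx * xyz[i, 1] + ky * xyz[i, 2] +
                                         kz * xyz[i, 3]))
      }
      tot <- tot + gl$w[m] * mean(Mod(A)^2)
    }
    tot / 2
  }, numeric(1))
}

# Direct term-by-term evaluation of the P2-weighted anisotropic sum,
# written independently of the package's vectorized implementation.
aniso_direct_oracle <- function(g, q, dipole, sigma = dw_params(), c2 = 1) {
  xyz <- solute_coords(g)
  j2 <- function(x) ifelse(abs(x) < 1e-6, x^2 / 15,
                           (3 / x^3 - 1 / x) * sin(x) - 3 * cos(x) / x^2)
  total <- numeric(length(q))
  for (i in 1:3) {
    for (j in 1:3) {
      if (i == j) next
      v <- xyz[i, ] - xyz[j, ]
      d <- sqrt(sum(v^2))
      cz <- sum(v * dipole) / d
      Fi <- atomic_form_factor(q, "I") * exp(-q^2 * sigma[i]^2 / 2)
      Fj <- atomic_form_factor(q, "I") * exp(-q^2 * sigma[j]^2 / 2)
      total <- total + Fi * Fj * 0.5 * (3 * cz^2 - 1) * j2(q * d)
    }
  }
  c2 * total
}

# Fine-grid quadrature of the cage cross-term integral for an analytic
# (g - 1) profile: plain trapezoid at 4x the resolution the package uses.
cross_term_oracle <- function(gm1_fun, q, rho, type, r_max = 30, dr = 5e-4) {
  r <- seq(0, r_max, by = dr)
  h <- gm1_fun(r)
  vapply(q, function(qi) {
    s <- ifelse(qi * r < 1e-12, 1, sin(qi * r) / (qi * r))
    integrand <- r^2 * h * s
    int <- (sum(integrand) - (integrand[1] + integrand[length(r)]) / 2) * dr
    atomic_form_factor(qi, "I") * atomic_form_factor(qi, type) * 4 * pi * rho * int
  }, numeric(1))
}

# Independent trilinear interpolation from explicit corner weights.
trilinear_oracle <- function(x, y, z, ax, ay, az, values) {
  ix <- max(min(findInterval(x, ax), length(ax) - 1), 1)
  iy <- max(min(findInterval(y, ay), length(ay) - 1), 1)
  iz <- max(min(findInterval(z, az), length(az) - 1), 1)
  fx <- (x - ax[ix]) / (ax[ix + 1] - ax[ix])
  fy <- (y - ay[iy]) / (ay[iy + 1] - ay[iy])
  fz <- (z - az[iz]) / (az[iz + 1] - az[iz])
  out <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    out <- out + w * values[ix + dx, iy + dy, iz + dz, ]
  }
  out
}
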