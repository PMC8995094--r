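# Independent oracles used across the suite. These deliberately avoid the
# package's internal geometry code paths: curves are densely point-sampled
# and distances are point-to-point minima, brute force.

# Densify a polyline at a fixed arc-length step by linear interpolation.
dense_points <- function(xy, step) {
  xy <- as.matrix(xy)
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  at <- seq(0, s[length(s)], by = step)
  cbind(approx(s, xy[, 1], xout = at)$y, approx(s, xy[, 2], xout = at)$y)
}

# Brute-force mean nearest-point distance from the ER curve to the PM curve,
# both sampled at `step` nm, chunked to bound memory.
oracle_gap <- function(pm, er, step = 0.01, chunk = 400L) {
  pmd <- dense_points(pm, step)
  erd <- dense_points(er, step)
  mins <- numeric(nrow(erd))
  i <- 1L
  while (i <= nrow(erd)) {
    j <- min(i + chunk - 1L, nrow(erd))
    dx <- outer(erd[i:j, 1], pmd[, 1], "-")
    dy <- outer(erd[i:j, 2], pmd[, 2], "-")
    mins[i:j] <- sqrt(apply(dx * dx + dy * dy, 1, min))
    i <- j + 1L
  }
  mean(mins)
}

# Per-segment hypotenuse summation, written independently of cer_length().
oracle_polyline_length <- function(xy) {
  xy <- as.matrix(xy)
  tot <- 0
  for (i in seq_len(nrow(xy) - 1)) {
    tot <- tot + sqrt((xy[i + 1, 1] - xy[i, 1])^2 + (xy[i + 1, 2] - xy[i, 2])^2)
  }
  unname(tot)
}

# Cylinder volume by numerical quadrature of the disc cross-section:
# V = g * 2 * integral of sqrt((L/2)^2 - x^2) over [-L/2, L/2].
oracle_cylinder_volume <- function(gap, len) {
  r <- len / 2
  disc <- integrate(function(x) 2 * sqrt(pmax(r^2 - x^2, 0)), -r, r,
                    rel.tol = 1e-10)$value
  disc * gap
}

# A curved PM/ER fixture: circular PM arc with a gentle sinusoidal
# perturbation, ER as the curve offset inward along the local normal by
# `gap`. Returns pm/er vertex matrices (the estimator's input) at `spacing`.
make_curved_fixture <- function(gap, length_er, curvature, wave_amp = 0,
                                wave_n = 2, spacing = 2) {
  r_pm <- 1 / curvature
  r_er <- r_pm - gap
  th_er <- length_er / r_er
  th_pm <- (length_er + 30) / r_pm
  a_pm <- pi / 2 + seq(-th_pm / 2, th_pm / 2,
                       length.out = ceiling((length_er + 30) / spacing) + 1)
  a_er <- pi / 2 + seq(-th_er / 2, th_er / 2,
                       length.out = ceiling(length_er / spacing) + 1)
  wob <- function(a) wave_amp * sin(wave_n * (a - pi / 2) / (th_pm / 2) * pi)
  pm <- cbind((r_pm + wob(a_pm)) * cos(a_pm), (r_pm + wob(a_pm)) * sin(a_pm))
  er <- cbind((r_er + wob(a_er)) * cos(a_er), (r_er + wob(a_er)) * sin(a_er))
  list(pm = pm, er = er)
}

# Rotate + translate a vertex matrix (rigid transform).
rigid_transform <- function(xy, theta, shift) {
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(as.matrix(xy) %*% t(rot), 2, shift, "+")
}
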