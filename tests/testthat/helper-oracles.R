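# Independent numerical oracles used to validate closed-form implementations.

# Brute-force 2D quadrature of the Coulomb kernel over a charged rectangle.
# points in mm, sigma in T; returns mT.
oracle_sheet_field <- function(points, sheet, n = 400) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  xs <- seq(sheet$xlim[1], sheet$xlim[2], length.out = n)
  ys <- seq(sheet$ylim[1], sheet$ylim[2], length.out = n)
  # midpoint rule on cell centres
  xs <- (xs[-1] + xs[-n]) / 2
  ys <- (ys[-1] + ys[-n]) / 2
  dA <- diff(sheet$xlim) * diff(sheet$ylim) / (n - 1)^2
  G <- expand.grid(x = xs, y = ys)
  t(apply(p, 1, function(q) {
    rx <- q[1] - G$x; ry <- q[2] - G$y; rz <- q[3] - sheet$z0
    R3 <- (rx^2 + ry^2 + rz^2)^1.5
    sheet$sigma / (4 * pi) * c(sum(rx / R3), sum(ry / R3), sum(rz / R3)) *
      dA * 1e3
  }))
}

# Brute-force self-intersection scan of a sampled closed curve: checks all
# non-adjacent segment pairs for proper crossings.
curve_self_intersects <- function(xy) {
  n <- nrow(xy) - 1
  seg <- function(i) rbind(as.numeric(xy[i, c("x", "y")]),
                           as.numeric(xy[i + 1, c("x", "y")]))
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) -
    (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p1, p2, p3, p4) {
    d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
    d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    s1 <- seg(i)
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next # sharing the closure point
      s2 <- seg(j)
      if (intersects(s1[1, ], s1[2, ], s2[1, ], s2[2, ])) return(TRUE)
    }
  }
  FALSE
}

# shared small fixtures
default_assembly <- magnet_assembly()
default_bead <- bead_model()

quiet_camera <- camera_model(sigma_z = 0, sigma_xy = 0)
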