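# shared geometric fixtures, built in code

unit_square <- function() {
  planar_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

# kite with LD endpoints A(-1,0), B(2,0) and PD endpoints C(0,1), D(0,-1)
kite_contour <- function() {
  planar_contour(rbind(c(-1, 0), c(0, -1), c(2, 0), c(0, 1)))
}

# random feasible bi-ellipse parameters (caller seeds the RNG)
random_biellipse_params <- function(rotation = runif(1, 0, 180)) {
  c_ax <- runif(1, 1.5, 5)
  a2 <- c_ax * runif(1, 1, 2.2)
  a1 <- a2 * runif(1, 1, 2.2)
  biellipse_params(a1, a2, c_ax, rotation = rotation)
}

# independent O(n^2) double-loop farthest-pair oracle
brute_force_diameter <- function(v) {
  n <- nrow(v)
  best <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((v[i, ] - v[j, ])^2))
      if (d > best) best <- d
    }
  }
  best
}

rotate_contour <- function(contour, degrees, shift = c(0, 0)) {
  phi <- degrees * pi / 180
  r <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  v <- as.matrix(contour) %*% t(r)
  planar_contour(sweep(v, 2, shift, "+"))
}

mk_chord <- function(p1, p2) ggnshape:::new_chord(p1, p2)
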