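# Geometric fixtures built in code.

# Unit square in the z = z0 plane, two triangles.
square_mesh <- function(z0 = 0) {
  tooth_mesh(rbind(c(0, 0, z0), c(1, 0, z0), c(1, 1, z0), c(0, 1, z0)),
             rbind(c(1, 2, 3), c(1, 3, 4)), up_axis = "z")
}

# Hemisphere of radius r tessellated in spherical coordinates (pole up).
hemisphere_mesh <- function(r = 3, n_theta = 96L, n_phi = 48L) {
  phi <- (seq_len(n_phi) / n_phi) * (pi / 2)
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  ring_x <- as.vector(t(outer(r * sin(phi), cos(theta))))
  ring_y <- as.vector(t(outer(r * sin(phi), sin(theta))))
  ring_z <- as.vector(t(outer(r * cos(phi), rep(1, n_theta))))
  V <- rbind(c(0, 0, r), cbind(ring_x, ring_y, ring_z))
  rid <- function(i, j) 1L + (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  j <- seq_len(n_theta)
  faces <- list(cbind(1L, rid(1L, j), rid(1L, j + 1L)))
  for (i in seq_len(n_phi - 1L)) {
    a <- rid(i, j); b <- rid(i, j + 1L)
    c_ <- rid(i + 1L, j); d <- rid(i + 1L, j + 1L)
    faces[[i + 1L]] <- rbind(cbind(a, c_, d), cbind(a, d, b))
  }
  tooth_mesh(V, do.call(rbind, faces), up_axis = "z")
}

# Rigid rotation of a mesh about its up axis by `angle` radians.
rotate_mesh_up <- function(mesh, angle) {
  ord <- axis_order_test(mesh$up_axis)
  V <- mesh$vertices
  x <- V[, ord[1]]; y <- V[, ord[2]]
  V[, ord[1]] <- cos(angle) * x - sin(angle) * y
  V[, ord[2]] <- sin(angle) * x + cos(angle) * y
  tooth_mesh(V, mesh$faces, mesh$up_axis)
}

axis_order_test <- function(up_axis) {
  switch(up_axis, z = c(1L, 2L, 3L), y = c(1L, 3L, 2L), x = c(2L, 3L, 1L))
}

scale_mesh <- function(mesh, k) {
  tooth_mesh(mesh$vertices * k, mesh$faces, mesh$up_axis)
}
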