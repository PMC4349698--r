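# Dental topographic metrics: total 3D crown surface area (TSA), projected
# planometric area (PSA), Relief Index (RFI), basin-plane cropping, and
# Occlusal Relief (OR).

#' Total 3D surface area of a crown mesh
#'
#' Sum over faces of half the cross-product magnitude. Degenerate faces
#' contribute zero; duplicated faces are counted as stored (no repair).
#'
#' @param mesh A [tooth_mesh()].
#' @return Area in mm^2.
#' @export
total_surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "tooth_mesh"))
  if (nrow(mesh$faces) == 0L) stop_input("mesh has no faces")
  sum(triangle_areas(mesh))
}

# 2D signed areas of projected triangles (columns ax..cy).
signed_area_2d <- function(ax, ay, bx, by, cx, cy) {
  0.5 * ((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))
}

# Length of the union of 1-D intervals [lo, hi].
interval_union_length <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  cm <- cummax(hi)
  prev <- c(-Inf, cm[-length(cm)])
  sum(pmax(0, cm - pmax(lo, prev)))
}

# Exact area of the union of 2D triangles by vertical slab decomposition:
# slab boundaries at every vertex x and every interior edge crossing; within
# a slab the union cross-section length is linear in x, so the midpoint
# value integrates it exactly.
union_area_exact <- function(tri) {
  # tri: list with ax, ay, bx, by, cx, cy vectors (one entry per triangle)
  keep <- abs(signed_area_2d(tri$ax, tri$ay, tri$bx, tri$by,
                             tri$cx, tri$cy)) > 0
  if (!any(keep)) return(0)
  tri <- lapply(tri, `[`, keep)
  m <- length(tri$ax)
  # segment table: 3 edges per triangle, oriented with x1 <= x2
  x1 <- c(tri$ax, tri$bx, tri$cx); y1 <- c(tri$ay, tri$by, tri$cy)
  x2 <- c(tri$bx, tri$cx, tri$ax); y2 <- c(tri$by, tri$cy, tri$ay)
  swap <- x1 > x2
  tmp <- x1[swap]; x1[swap] <- x2[swap]; x2[swap] <- tmp
  tmp <- y1[swap]; y1[swap] <- y2[swap]; y2[swap] <- tmp
  events <- c(x1, x2)
  # interior pairwise crossings, bounding-box pruned via an x-sorted sweep
  E <- length(x1)
  o <- order(x1)
  sx1 <- x1[o]; sx2 <- x2[o]; sy1 <- y1[o]; sy2 <- y2[o]
  hi_y <- pmax(sy1, sy2); lo_y <- pmin(sy1, sy2)
  for (i in seq_len(E - 1L)) {
    jmax <- i
    xi2 <- sx2[i]
    # candidates: segments starting before this one ends
    while (jmax < E && sx1[jmax + 1L] <= xi2) jmax <- jmax + 1L
    if (jmax == i) next
    j <- (i + 1L):jmax
    j <- j[hi_y[j] >= lo_y[i] & lo_y[j] <= hi_y[i]]
    if (!length(j)) next
    rx <- sx2[i] - sx1[i]; ry <- sy2[i] - sy1[i]
    sxv <- sx2[j] - sx1[j]; syv <- sy2[j] - sy1[j]
    den <- rx * syv - ry * sxv
    qpx <- sx1[j] - sx1[i]; qpy <- sy1[j] - sy1[i]
    ok <- den != 0
    t_ <- ifelse(ok, (qpx * syv - qpy * sxv) / den, NA_real_)
    u_ <- ifelse(ok, (qpx * ry - qpy * rx) / den, NA_real_)
    hit <- ok & t_ > 1e-12 & t_ < 1 - 1e-12 & u_ > 1e-12 & u_ < 1 - 1e-12
    if (any(hit)) events <- c(events, sx1[i] + t_[hit] * rx)
  }
  events <- sort(unique(events))
  txmin <- pmin(tri$ax, tri$bx, tri$cx)
  txmax <- pmax(tri$ax, tri$bx, tri$cx)
  area <- 0
  for (s in seq_len(length(events) - 1L)) {
    w <- events[s + 1L] - events[s]
    if (w <= 0) next
    xm <- events[s] + w / 2
    act <- which(txmin < xm & txmax > xm)
    if (!length(act)) next
    # y-interval of each active triangle at x = xm
    ylo <- rep(Inf, length(act)); yhi <- rep(-Inf, length(act))
    ex1 <- cbind(tri$ax[act], tri$bx[act], tri$cx[act])
    ey1 <- cbind(tri$ay[act], tri$by[act], tri$cy[act])
    ex2 <- cbind(tri$bx[act], tri$cx[act], tri$ax[act])
    ey2 <- cbind(tri$by[act], tri$cy[act], tri$ay[act])
    for (k in 1:3) {
      spans <- (pmin(ex1[, k], ex2[, k]) < xm) & (pmax(ex1[, k], ex2[, k]) > xm)
      yk <- ey1[, k] + (xm - ex1[, k]) * (ey2[, k] - ey1[, k]) /
        (ex2[, k] - ex1[, k])
      ylo[spans] <- pmin(ylo[spans], yk[spans])
      yhi[spans] <- pmax(yhi[spans], yk[spans])
    }
    good <- is.finite(ylo) & is.finite(yhi) & yhi > ylo
    if (any(good)) area <- area + w * interval_union_length(ylo[good], yhi[good])
  }
  area
}

# Rasterization estimate of the union area at pixel-center sampling.
union_area_raster <- function(tri, resolution = 2048L) {
  keep <- abs(signed_area_2d(tri$ax, tri$ay, tri$bx, tri$by,
                             tri$cx, tri$cy)) > 0
  if (!any(keep)) return(0)
  tri <- lapply(tri, `[`, keep)
  xmin <- min(tri$ax, tri$bx, tri$cx); xmax <- max(tri$ax, tri$bx, tri$cx)
  ymin <- min(tri$ay, tri$by, tri$cy); ymax <- max(tri$ay, tri$by, tri$cy)
  px <- max(xmax - xmin, ymax - ymin) / resolution
  if (px == 0) return(0)
  nx <- ceiling((xmax - xmin) / px); ny <- ceiling((ymax - ymin) / px)
  covered <- matrix(FALSE, nx, ny)
  xc <- xmin + (seq_len(nx) - 0.5) * px
  yc <- ymin + (seq_len(ny) - 0.5) * px
  for (t in seq_along(tri$ax)) {
    ax <- tri$ax[t]; ay <- tri$ay[t]; bx <- tri$bx[t]; by <- tri$by[t]
    cx <- tri$cx[t]; cy <- tri$cy[t]
    i <- which(xc >= min(ax, bx, cx) - px & xc <= max(ax, bx, cx) + px)
    j <- which(yc >= min(ay, by, cy) - px & yc <= max(ay, by, cy) + px)
    if (!length(i) || !length(j)) next
    X <- matrix(xc[i], length(i), length(j))
    Y <- matrix(yc[j], length(i), length(j), byrow = TRUE)
    d1 <- (bx - ax) * (Y - ay) - (by - ay) * (X - ax)
    d2 <- (cx - bx) * (Y - by) - (cy - by) * (X - bx)
    d3 <- (ax - cx) * (Y - cy) - (ay - cy) * (X - cx)
    inside <- (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
    covered[i, j] <- covered[i, j] | inside
  }
  sum(covered) * px^2
}

# Project mesh faces along the up axis into 2D triangle columns.
project_triangles <- function(mesh) {
  ord <- axis_order(mesh$up_axis)
  V <- mesh$vertices[, ord, drop = FALSE]
  F <- mesh$faces
  list(ax = V[F[, 1], 1], ay = V[F[, 1], 2],
       bx = V[F[, 2], 1], by = V[F[, 2], 2],
       cx = V[F[, 3], 1], cy = V[F[, 3], 2])
}

#' Projected (planometric) occlusal area
#'
#' Area of the planar union of all faces projected along the mesh's up
#' axis — overlapping projections are counted once, so a crown whose sides
#' fold under its outline still yields the occlusal-outline area.
#'
#' The default exact method decomposes the projected arrangement into
#' vertical slabs (boundaries at every projected vertex and every interior
#' edge crossing) and integrates the union cross-section, which is linear
#' within each slab. A rasterization estimator is available for very large
#' or pathological meshes.
#'
#' @param mesh A [tooth_mesh()].
#' @param method `"union"` (exact; default for meshes up to
#'   `max_union_edges` edges), `"raster"`, or `"auto"`.
#' @param resolution Raster grid size along the longer bounding-box side.
#' @param max_union_edges Edge-count threshold above which `"auto"` falls
#'   back to rasterization.
#' @return Area in mm^2.
#' @export
projected_area <- function(mesh, method = c("auto", "union", "raster"),
                           resolution = 2048L, max_union_edges = 30000L) {
  stopifnot(inherits(mesh, "tooth_mesh"))
  method <- match.arg(method)
  tri <- project_triangles(mesh)
  if (all(abs(signed_area_2d(tri$ax, tri$ay, tri$bx, tri$by,
                             tri$cx, tri$cy)) == 0)) {
    stop_input("degenerate projection: every face projects to zero area ",
               "(mesh is a vertical sheet along the up axis?)")
  }
  if (method == "auto") {
    method <- if (3L * nrow(mesh$faces) <= max_union_edges) "union" else "raster"
  }
  switch(method,
         union = union_area_exact(tri),
         raster = union_area_raster(tri, resolution))
}

#' Relief Index
#'
#' `RFI = ln(sqrt(TSA) / sqrt(PSA)) = 0.5 * ln(TSA / PSA)`: the log ratio
#' of 3D crown area to its occlusal-projection area. Zero for a flat
#' surface; grows with crown relief.
#'
#' @param tsa Total 3D surface area (mm^2), `> 0`.
#' @param psa Projected planometric area (mm^2), `> 0`.
#' @return Dimensionless index.
#' @export
relief_index <- function(tsa, psa) {
  if (!is.numeric(tsa) || !is.numeric(psa) || any(tsa <= 0) || any(psa <= 0)) {
    stop_domain("tsa and psa must be positive")
  }
  if (any(tsa < psa)) {
    warning("TSA < PSA: physically impossible for a height-field crown; ",
            "check mesh orientation or cropping", call. = FALSE)
  }
  0.5 * log(tsa / psa)
}

# --- basin cropping -------------------------------------------------------

# Ray-casting point-in-polygon (polygon as closed x/y vertex vectors).
points_in_polygon <- function(px, py, polyx, polyy) {
  n <- length(polyx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((polyy[i] > py) != (polyy[j] > py)) &
      (px < (polyx[j] - polyx[i]) * (py - polyy[i]) /
         (polyy[j] - polyy[i]) + polyx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Vertex adjacency list from the face table.
vertex_neighbors <- function(mesh) {
  F <- mesh$faces
  edges <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  split(edges[, 2], edges[, 1])
}

# Auto-detect the talonid-basin point: the lowest vertex whose projection
# lies strictly inside the convex hull of the cusp tips (local height
# maxima above the 75th height percentile). Ties -> lowest vertex index.
auto_basin_vertex <- function(mesh) {
  h <- mesh_heights(mesh)
  nbrs <- vertex_neighbors(mesh)
  thr <- stats::quantile(h, 0.75, names = FALSE)
  ids <- as.integer(names(nbrs))
  is_max <- vapply(seq_along(nbrs),
                   function(k) all(h[ids[k]] >= h[nbrs[[k]]]),
                   logical(1))
  tips <- ids[is_max & h[ids] > thr]
  if (length(tips) < 2L) {
    stop_input("basin auto-detection needs >= 2 cusp tips, found ",
               length(tips), "; pass basin_point explicitly")
  }
  ord <- axis_order(mesh$up_axis)
  P <- mesh$vertices[, ord[1:2], drop = FALSE]
  if (length(tips) == 2L) {
    # two cusps: search the strip between the tips for the saddle
    d <- P[tips[2], ] - P[tips[1], ]
    len2 <- sum(d^2)
    rel <- sweep(P, 2, P[tips[1], ])
    t_par <- (rel %*% d) / len2
    perp <- sqrt(pmax(0, rowSums(rel^2) - (t_par^2) * len2))
    inside <- t_par > 0.1 & t_par < 0.9 & perp < 0.2 * sqrt(len2)
    inside <- as.vector(inside)
  } else {
    hull <- tips[grDevices::chull(P[tips, 1], P[tips, 2])]
    inside <- points_in_polygon(P[, 1], P[, 2], P[hull, 1], P[hull, 2])
    inside[hull] <- FALSE
  }
  if (!any(inside)) {
    stop_input("no vertex projects strictly inside the cusp-tip hull; ",
               "pass basin_point explicitly")
  }
  cand <- which(inside)
  cand[which.min(h[cand])]       # which.min takes the first (lowest index) tie
}

# Clip a triangle (rows of 3x3 matrix) against height >= h; returns a list
# of triangles (possibly empty). `height` extracts the up coordinate.
clip_triangle_above <- function(tri, h, up_col) {
  z <- tri[, up_col]
  above <- z >= h
  n_above <- sum(above)
  if (n_above == 3L) return(list(tri))
  if (n_above == 0L) return(list())
  interp <- function(p, q) {
    t <- (h - p[up_col]) / (q[up_col] - p[up_col])
    p + t * (q - p)
  }
  idx <- order(!above)   # above vertices first, preserving order within
  if (n_above == 1L) {
    a <- tri[which(above), ]
    b <- tri[which(!above)[1], ]; c <- tri[which(!above)[2], ]
    list(rbind(a, interp(a, b), interp(a, c)))
  } else {
    a <- tri[which(above)[1], ]; b <- tri[which(above)[2], ]
    c <- tri[which(!above), ]
    ac <- interp(a, c); bc <- interp(b, c)
    list(rbind(a, b, bc), rbind(a, bc, ac))
  }
}

#' Crop a crown mesh at the talonid-basin plane
#'
#' Passes a horizontal plane (perpendicular to the up axis) through the
#' basin point and retains the portion of the mesh at or above it,
#' splitting straddling triangles exactly at the plane. When `basin_point`
#' is omitted the basin is auto-detected as the lowest vertex projecting
#' strictly inside the convex hull of the cusp tips.
#'
#' @param mesh A [tooth_mesh()].
#' @param basin_point A vertex index, a length-3 coordinate on the mesh, or
#'   `NULL` for auto-detection.
#' @return A list with `mesh` (the cropped [tooth_mesh()]) and
#'   `crop_height` (the plane height in mm).
#' @export
basin_crop <- function(mesh, basin_point = NULL) {
  stopifnot(inherits(mesh, "tooth_mesh"))
  up_col <- axis_order(mesh$up_axis)[3]
  h_all <- mesh_heights(mesh)
  if (is.null(basin_point)) {
    v <- auto_basin_vertex(mesh)
    h <- h_all[v]
  } else if (length(basin_point) == 1L) {
    v <- as.integer(basin_point)
    if (is.na(v) || v < 1L || v > nrow(mesh$vertices)) {
      stop_input("basin_point vertex index out of range")
    }
    h <- h_all[v]
  } else if (length(basin_point) == 3L) {
    d2 <- colSums((t(mesh$vertices) - as.numeric(basin_point))^2)
    if (min(d2) > (1e-6 * max(1, diff(range(h_all))))^2) {
      stop_input("basin_point coordinate does not lie on the mesh")
    }
    h <- basin_point[up_col]
  } else {
    stop_input("basin_point must be a vertex index or length-3 coordinate")
  }
  if (h <= min(h_all)) {
    warning("basin point is the global minimum of the mesh; nothing cropped",
            call. = FALSE)
    return(list(mesh = mesh, crop_height = h))
  }
  V <- mesh$vertices; F <- mesh$faces
  zf <- cbind(h_all[F[, 1]], h_all[F[, 2]], h_all[F[, 3]])
  all_above <- rowSums(zf >= h) == 3L
  any_above <- rowSums(zf >= h) > 0L
  keep_faces <- F[all_above, , drop = FALSE]
  straddle <- which(any_above & !all_above)
  new_tris <- list()
  for (fi in straddle) {
    tri <- V[F[fi, ], , drop = FALSE]
    new_tris <- c(new_tris, clip_triangle_above(tri, h, up_col))
  }
  # assemble: existing vertices + new clipped triangles' vertices
  if (length(new_tris)) {
    newV <- do.call(rbind, new_tris)
    nV <- rbind(V, newV)
    start <- nrow(V)
    addF <- matrix(start + seq_len(nrow(newV)), ncol = 3, byrow = TRUE)
    allF <- rbind(keep_faces, addF)
  } else {
    nV <- V
    allF <- keep_faces
  }
  if (nrow(allF) == 0L) stop_input("crop plane removed the entire mesh")
  used <- sort(unique(as.integer(allF)))
  remap <- integer(nrow(nV)); remap[used] <- seq_along(used)
  cropped <- tooth_mesh(nV[used, , drop = FALSE],
                        matrix(remap[allF], ncol = 3), mesh$up_axis)
  list(mesh = cropped, crop_height = h)
}

#' Occlusal Relief
#'
#' `OR = TSA(cropped) / PSA(cropped)`: the ratio of 3D to projected 2D area
#' of the crown portion above the talonid-basin plane. 1 for a flat
#' surface; 2 for a hemisphere cropped at its equator.
#'
#' @param cropped A [tooth_mesh()] already cropped at the basin plane (see
#'   [basin_crop()]).
#' @param ... Passed to [projected_area()].
#' @return Dimensionless ratio `>= 1` up to tessellation error.
#' @export
occlusal_relief <- function(cropped, ...) {
  total_surface_area(cropped) / projected_area(cropped, ...)
}

#' All topographic metrics for one crown mesh
#'
#' Computes TSA, PSA and RFI on the mesh as given (assumed pre-cropped at
#' the cemento-enamel junction), and — when `compute_or` is `TRUE` — crops
#' at the talonid-basin plane and computes OR. Mirroring standard practice,
#' OR is intended for lower molars; set `compute_or = TRUE` explicitly for
#' other teeth.
#'
#' @param mesh A [tooth_mesh()].
#' @param basin_point Passed to [basin_crop()] when `compute_or` is `TRUE`.
#' @param compute_or Whether to crop and compute occlusal relief.
#' @param ... Passed to [projected_area()].
#' @return A list: `tsa`, `psa`, `rfi`, `or_value` (or `NA`), `crop_height`
#'   (or `NA`).
#' @export
topography_metrics <- function(mesh, basin_point = NULL, compute_or = FALSE,
                               ...) {
  tsa <- total_surface_area(mesh)
  psa <- projected_area(mesh, ...)
  out <- list(tsa = tsa, psa = psa, rfi = relief_index(tsa, psa),
              or_value = NA_real_, crop_height = NA_real_)
  if (compute_or) {
    cr <- basin_crop(mesh, basin_point)
    out$or_value <- occlusal_relief(cr$mesh, ...)
    out$crop_height <- cr$crop_height
  }
  out
}
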