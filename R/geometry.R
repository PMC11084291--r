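#' Idealised aorta model
#'
#' A Type-I "candy-cane" centerline in right-handed patient coordinates:
#' the axial axis is +z, the coronal plane is x-z and the sagittal plane is
#' y-z. The ascending aorta runs from the ventriculo-arterial junction
#' (AVJ, at the origin) straight up +z, the arch is a semicircle in the
#' coronal plane, and the descending aorta runs straight down. Units mm.
#' An idealised model is used because patient imaging is not part of the
#' package's inputs; every geometric operation is defined against the
#' model's own axial axis.
#'
#' @param ascending_length Length of the ascending segment (mm).
#' @param arch_radius Arch centerline radius (mm).
#' @param descending_length Length of the descending segment (mm).
#' @param lumen_radius Aortic lumen radius (mm), constant along the vessel.
#' @param spacing Approximate centerline point spacing (mm).
#' @return Object of class `aorta_model` with fields `centerline` (n x 3),
#'   `radius`, `segment` (per-point label), `branch_ostia` (named 3-column
#'   matrix of outlet landmarks) and `axial_axis`.
#' @export
aorta_model <- function(ascending_length = 90, arch_radius = 30,
                        descending_length = 120, lumen_radius = 12.5,
                        spacing = 2.5) {
  if (lumen_radius <= 0) stop("'lumen_radius' must be positive")
  n_asc <- max(2L, ceiling(ascending_length / spacing) + 1L)
  asc <- cbind(0, 0, seq(0, ascending_length, length.out = n_asc))
  n_arc <- max(8L, ceiling(pi * arch_radius / spacing))
  th <- seq(0, pi, length.out = n_arc + 1L)[-1L]
  arc <- cbind(-arch_radius + arch_radius * cos(th), 0,
               ascending_length + arch_radius * sin(th))
  n_des <- max(2L, ceiling(descending_length / spacing))
  des <- cbind(-2 * arch_radius, 0,
               seq(ascending_length, ascending_length - descending_length,
                   length.out = n_des + 1L)[-1L])
  centerline <- rbind(asc, arc, des)
  segment <- c(rep("ascending", nrow(asc)), rep("arch", nrow(arc)),
               rep("descending", nrow(des)))
  top_z <- ascending_length + arch_radius
  ostia <- rbind(
    right_coronary = c(lumen_radius, 0, 5),
    left_coronary = c(-lumen_radius, 0, 5),
    right_subclavian = c(-arch_radius + arch_radius * cos(pi / 5), lumen_radius,
                         ascending_length + arch_radius * sin(pi / 5)),
    right_common_carotid = c(-arch_radius + arch_radius * cos(2 * pi / 5),
                             lumen_radius,
                             ascending_length + arch_radius * sin(2 * pi / 5)),
    left_common_carotid = c(-arch_radius, lumen_radius, top_z),
    left_subclavian = c(-arch_radius + arch_radius * cos(3 * pi / 5),
                        lumen_radius,
                        ascending_length + arch_radius * sin(3 * pi / 5)),
    descending_aorta = c(-2 * arch_radius, 0,
                         ascending_length - descending_length))
  colnames(ostia) <- c("x", "y", "z")
  structure(list(centerline = centerline,
                 radius = rep(lumen_radius, nrow(centerline)),
                 segment = segment, branch_ostia = ostia,
                 axial_axis = c(0, 0, 1),
                 ascending_length = ascending_length),
            class = "aorta_model")
}

#' Anastomosis placement parameters
#'
#' One outflow-graft placement: distance `d` from the AVJ measured along
#' the axial axis (between two parallel axial planes, one through the AVJ
#' and one through the graft ostium center), the cardinal `side` of the
#' aorta the graft attaches to, and the angle between the graft axis and
#' that side's anatomical plane.
#'
#' @param d AVJ-to-graft distance (mm), in `[40, 60]`.
#' @param side `"coronal"` or `"sagittal"`.
#' @param angle Degrees; coronal placements admit `[35, 55]`, sagittal
#'   `[45, 55]`.
#' @param og_diameter Graft diameter (mm), default 14 (the HMIII outflow
#'   graft).
#' @return Object of class `anastomosis_params`.
#' @export
anastomosis_params <- function(d, side = c("coronal", "sagittal"), angle,
                               og_diameter = 14) {
  side <- match.arg(side)
  if (d < 40 || d > 60) {
    stop(sprintf("distance d = %.1f mm outside the admissible range [40, 60] mm", d))
  }
  rng <- if (side == "coronal") c(35, 55) else c(45, 55)
  if (angle < rng[1] || angle > rng[2]) {
    stop(sprintf("%s angle = %.1f deg outside the admissible range [%g, %g] deg",
                 side, angle, rng[1], rng[2]))
  }
  if (og_diameter <= 0) stop("'og_diameter' must be positive")
  structure(list(d = d, side = side, angle = angle, og_diameter = og_diameter),
            class = "anastomosis_params")
}

#' @export
print.anastomosis_params <- function(x, ...) {
  cat(sprintf("Anastomosis: d = %g mm, %s side, angle = %g deg, OG %g mm\n",
              x$d, x$side, x$angle, x$og_diameter))
  invisible(x)
}

#' Enumerate anastomosis configurations
#'
#' Cartesian product of distances with the coronal angles plus distances
#' with the sagittal angles, in deterministic order: side (coronal first),
#' then distance ascending, then angle ascending. The defaults give the 15
#' configurations of the comparative study design.
#'
#' @param distances Distances d (mm).
#' @param coronal_angles Coronal-side angles (deg); may be empty.
#' @param sagittal_angles Sagittal-side angles (deg); may be empty.
#' @param og_diameter Graft diameter (mm).
#' @return List of [anastomosis_params()], length
#'   `length(distances) * (length(coronal_angles) + length(sagittal_angles))`.
#' @export
#' @examples
#' length(enumerate_configurations()) # 15
enumerate_configurations <- function(distances = c(45, 50, 55),
                                     coronal_angles = c(35, 45, 55),
                                     sagittal_angles = c(45, 55),
                                     og_diameter = 14) {
  if (length(distances) == 0L) stop("'distances' must be non-empty")
  if (length(coronal_angles) + length(sagittal_angles) == 0L) {
    stop("at least one of 'coronal_angles'/'sagittal_angles' must be non-empty")
  }
  out <- list()
  for (side in c("coronal", "sagittal")) {
    angles <- if (side == "coronal") coronal_angles else sagittal_angles
    for (d in sort(distances)) {
      for (a in sort(angles)) {
        out[[length(out) + 1L]] <- anastomosis_params(d, side, a, og_diameter)
      }
    }
  }
  out
}

# parallel-transported orthonormal frames along a polyline
.transport_frames <- function(pts) {
  n <- nrow(pts)
  tang <- matrix(0, n, 3)
  tang[1L, ] <- pts[2L, ] - pts[1L, ]
  tang[n, ] <- pts[n, ] - pts[n - 1L, ]
  if (n > 2L) tang[2:(n - 1L), ] <- pts[3:n, ] - pts[1:(n - 2L), ]
  tang <- tang / sqrt(rowSums(tang^2))
  e1 <- matrix(0, n, 3)
  ref <- c(1, 0, 0)
  if (abs(sum(ref * tang[1L, ])) > 0.9) ref <- c(0, 1, 0)
  v <- ref - sum(ref * tang[1L, ]) * tang[1L, ]
  e1[1L, ] <- v / sqrt(sum(v^2))
  for (i in 2:n) {
    v <- e1[i - 1L, ] - sum(e1[i - 1L, ] * tang[i, ]) * tang[i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) v <- e1[i - 1L, ] else v <- v / nv
    e1[i, ] <- v
  }
  e2 <- cbind(tang[, 2] * e1[, 3] - tang[, 3] * e1[, 2],
              tang[, 3] * e1[, 1] - tang[, 1] * e1[, 3],
              tang[, 1] * e1[, 2] - tang[, 2] * e1[, 1])
  list(tangent = tang, e1 = e1, e2 = e2)
}

# triangulate consecutive closed rings of `res` vertices starting at offset
.ring_faces <- function(n_rings, res, offset = 0L) {
  faces <- matrix(0L, nrow = 2L * res * (n_rings - 1L), ncol = 3L)
  k <- 1L
  for (i in seq_len(n_rings - 1L)) {
    i0 <- offset + (i - 1L) * res
    i1 <- i0 + res
    for (j in seq_len(res)) {
      jn <- if (j == res) 1L else j + 1L
      faces[k, ] <- c(i0 + j, i0 + jn, i1 + j); k <- k + 1L
      faces[k, ] <- c(i0 + jn, i1 + jn, i1 + j); k <- k + 1L
    }
  }
  faces
}

#' Build the anastomosis surface mesh
#'
#' Sweeps the aortic tube along the model centerline with
#' parallel-transported frames and attaches an open graft cylinder whose
#' ostium center sits on the aortic surface at axial height `d` on the
#' requested cardinal side. The graft axis lies in the transverse plane,
#' tilted out of the side's anatomical plane by the requested angle (so the
#' angle between the axis line and that plane equals the parameter); this
#' axis convention is the package's documented choice. No boolean union is
#' performed: the junction is emitted as two labelled open tubes.
#'
#' @param aorta An [aorta_model()].
#' @param params An [anastomosis_params()].
#' @param resolution Segments per tube circumference (default 48).
#' @param og_length Emitted graft length (mm), default 40.
#' @return Object of class `surface_mesh`: `vertices` (n x 3, mm), `faces`
#'   (m x 3 vertex indices), `label` (per-vertex `"aorta"`/`"og"`), and
#'   ring metadata used by [measure_parameters()].
#' @export
build_geometry <- function(aorta, params, resolution = 48, og_length = 40) {
  stopifnot(inherits(aorta, "aorta_model"),
            inherits(params, "anastomosis_params"))
  if (resolution < 8) stop("'resolution' must be at least 8")
  if (params$d > aorta$ascending_length) {
    stop(sprintf("OG placement d = %g mm beyond the ascending centerline extent (%g mm)",
                 params$d, aorta$ascending_length))
  }
  cl <- aorta$centerline
  fr <- .transport_frames(cl)
  res <- as.integer(resolution)
  ang <- 2 * pi * (seq_len(res) - 1L) / res
  n_cl <- nrow(cl)
  averts <- matrix(0, n_cl * res, 3)
  for (i in seq_len(n_cl)) {
    ring <- cl[rep(i, res), ] +
      aorta$radius[i] * (cos(ang) %o% fr$e1[i, ] + sin(ang) %o% fr$e2[i, ])
    averts[((i - 1L) * res + 1L):(i * res), ] <- ring
  }
  Ra <- aorta$radius[1L]
  theta <- params$angle * pi / 180
  if (params$side == "coronal") {
    ostium <- c(Ra, 0, params$d)
    u <- c(cos(theta), sin(theta), 0)
  } else {
    ostium <- c(0, Ra, params$d)
    u <- c(sin(theta), cos(theta), 0)
  }
  # orthonormal frame perpendicular to the graft axis
  w1 <- c(-u[2], u[1], 0)
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- c(u[2] * w1[3] - u[3] * w1[2], u[3] * w1[1] - u[1] * w1[3],
          u[1] * w1[2] - u[2] * w1[1])
  og_r <- params$og_diameter / 2
  n_og <- max(2L, ceiling(og_length / 2.5) + 1L)
  tpos <- seq(0, og_length, length.out = n_og)
  overts <- matrix(0, n_og * res, 3)
  for (i in seq_len(n_og)) {
    ring <- matrix(ostium + tpos[i] * u, res, 3, byrow = TRUE) +
      og_r * (cos(ang) %o% w1 + sin(ang) %o% w2)
    overts[((i - 1L) * res + 1L):(i * res), ] <- ring
  }
  vertices <- rbind(averts, overts)
  faces <- rbind(.ring_faces(n_cl, res, 0L),
                 .ring_faces(n_og, res, n_cl * res))
  label <- c(rep("aorta", nrow(averts)), rep("og", nrow(overts)))
  ring <- c(rep(seq_len(n_cl), each = res), rep(seq_len(n_og), each = res))
  seg <- c(rep(aorta$segment, each = res), rep(NA_character_, nrow(overts)))
  structure(list(vertices = vertices, faces = faces, label = label,
                 ring = ring, segment = seg, resolution = res),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d triangles (%d graft vertices)\n",
              nrow(x$vertices), nrow(x$faces), sum(x$label == "og")))
  invisible(x)
}

#' Apply a rigid motion to a surface mesh
#'
#' @param mesh A `surface_mesh`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (mm).
#' @return The transformed mesh (labels and ring metadata preserved).
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "surface_mesh"))
  mesh$vertices <- mesh$vertices %*% t(rotation) +
    matrix(translation, nrow(mesh$vertices), 3, byrow = TRUE)
  mesh
}

# least-squares cylinder fit: PCA axis then Gauss-Newton-free refinement of
# the radial-distance spread over axis direction and center
.fit_cylinder <- function(pts) {
  ctr <- colMeans(pts)
  pc <- prcomp(pts, center = TRUE)
  axis0 <- pc$rotation[, 1L]
  obj <- function(par) {
    # par: two rotation angles perturbing the axis, two in-plane center shifts
    b1 <- pc$rotation[, 2L]; b2 <- pc$rotation[, 3L]
    u <- axis0 + par[1] * b1 + par[2] * b2
    u <- u / sqrt(sum(u^2))
    c0 <- ctr + par[3] * b1 + par[4] * b2
    rel <- sweep(pts, 2, c0)
    proj <- rel %*% u
    radial <- rel - proj %*% t(u)
    r <- sqrt(rowSums(radial^2))
    sum((r - mean(r))^2)
  }
  fit <- stats::optim(c(0, 0, 0, 0), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 200))
  b1 <- pc$rotation[, 2L]; b2 <- pc$rotation[, 3L]
  u <- axis0 + fit$par[1] * b1 + fit$par[2] * b2
  u <- u / sqrt(sum(u^2))
  c0 <- ctr + fit$par[3] * b1 + fit$par[4] * b2
  rel <- sweep(pts, 2, c0)
  proj <- as.numeric(rel %*% u)
  radial <- rel - proj %*% t(u)
  list(axis = u, center = c0, radius = mean(sqrt(rowSums(radial^2))),
       proj_range = range(proj))
}

#' Recover anastomosis parameters from a mesh
#'
#' Re-derives the anatomical frame from the aorta vertices (axial axis from
#' the ascending ring centroids, coronal-plane normal from the arch-plane
#' fit), least-squares fits a cylinder to the labelled graft vertices, and
#' reports the recovered distance, side, angle and graft diameter. Because
#' the frame is estimated from the mesh itself, the recovered parameters
#' are invariant under rigid motions of the mesh. A straight-tube aorta
#' leaves the arch plane (hence the cardinal side) undefined; the side is
#' then reported as `"ambiguous"`.
#'
#' @param mesh A `surface_mesh` from [build_geometry()] (labels retained).
#' @return List with `d` (mm), `side`, `angle` (deg), `og_diameter` (mm).
#' @export
#' @examples
#' m <- build_geometry(aorta_model(), anastomosis_params(50, "coronal", 45))
#' measure_parameters(m)
measure_parameters <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(mesh$label) || !any(mesh$label == "og")) {
    stop("mesh has no labelled graft ('og') vertex subset")
  }
  a_idx <- mesh$label == "aorta"
  averts <- mesh$vertices[a_idx, , drop = FALSE]
  aring <- mesh$ring[a_idx]
  aseg <- mesh$segment[a_idx]
  rings <- sort(unique(aring))
  centroids <- t(vapply(rings, function(r) {
    colMeans(averts[aring == r, , drop = FALSE])
  }, numeric(3)))
  ring_seg <- vapply(rings, function(r) aseg[aring == r][1L], character(1))
  asc <- centroids[ring_seg == "ascending", , drop = FALSE]
  if (nrow(asc) < 2L) stop("no ascending segment found in mesh metadata")
  zhat <- asc[nrow(asc), ] - asc[1L, ]
  zhat <- zhat / sqrt(sum(zhat^2))
  avj <- asc[1L, ]
  # arch plane from all centerline centroids; degenerate for a straight tube
  pc <- prcomp(centroids, center = TRUE)
  planar_ok <- pc$sdev[2L] > 1e-6 * pc$sdev[1L]
  yhat <- pc$rotation[, 3L]
  xhat <- c(yhat[2] * zhat[3] - yhat[3] * zhat[2],
            yhat[3] * zhat[1] - yhat[1] * zhat[3],
            yhat[1] * zhat[2] - yhat[2] * zhat[1])
  xhat <- xhat / sqrt(sum(xhat^2))

  cyl <- .fit_cylinder(mesh$vertices[mesh$label == "og", , drop = FALSE])
  ends <- rbind(cyl$center + cyl$proj_range[1L] * cyl$axis,
                cyl$center + cyl$proj_range[2L] * cyl$axis)
  # ostium = cylinder end nearer the ascending axis line
  dist_axis <- function(p) {
    rel <- p - avj
    perp <- rel - sum(rel * zhat) * zhat
    sqrt(sum(perp^2))
  }
  ostium <- ends[which.min(c(dist_axis(ends[1L, ]), dist_axis(ends[2L, ]))), ]
  d_rec <- abs(sum((ostium - avj) * zhat))
  rel <- ostium - avj
  radial <- rel - sum(rel * zhat) * zhat
  side <- "ambiguous"
  angle <- NA_real_
  if (planar_ok && sqrt(sum(radial^2)) > 1e-9) {
    px <- abs(sum(radial * xhat))
    py <- abs(sum(radial * yhat))
    if (max(px, py) > 1.02 * min(px, py)) {
      side <- if (px > py) "coronal" else "sagittal"
      nrm <- if (side == "coronal") yhat else xhat
      angle <- asin(min(1, abs(sum(cyl$axis * nrm)))) * 180 / pi
    }
  }
  list(d = d_rec, side = side, angle = angle, og_diameter = 2 * cyl$radius)
}

#' Write a surface mesh as ASCII STL
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path (`.stl`).
#' @param name Solid name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "graftflow") {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  block <- sprintf(paste0(
    " facet normal %.9g %.9g %.9g\n  outer loop\n",
    "   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n",
    "   vertex %.9g %.9g %.9g\n  endloop\n endfacet"),
    nrm[, 1], nrm[, 2], nrm[, 3],
    p1[, 1], p1[, 2], p1[, 3], p2[, 1], p2[, 2], p2[, 3],
    p3[, 1], p3[, 2], p3[, 3])
  writeLines(block, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
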