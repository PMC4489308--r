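# Star-shaped envelope around the solute, built from a subdivided icosahedron.
#
# The envelope separates the solute plus its hydration shell from bulk
# solvent: vertices of an icosphere are pushed radially outward until every
# vertex is at least a distance d from every solute atom of every build frame.
# The same envelope is reused for the whole downstream calculation.

#' Build an icosphere by recursive subdivision
#'
#' Starts from a regular icosahedron and recursively subdivides each
#' triangular face into four, projecting new vertices onto the unit sphere.
#'
#' @param depth Number of subdivision rounds (0 = the icosahedron itself).
#'   Vertex count is `10 * 4^depth + 2`, face count `20 * 4^depth`.
#' @return A `swx_icosphere`: list with `vertices` (V x 3 unit vectors) and
#'   `faces` (F x 3 integer matrix, outward-oriented).
#' @export
build_icosphere <- function(depth = 4) {
  if (depth < 0) stop("depth must be non-negative")
  if (depth > 8) stop("depth > 8 refused (resource guard)")
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (iter in seq_len(depth)) {
    edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    # midpoint vertex index per unique edge
    e1 <- edge_key(f[, 1], f[, 2])
    e2 <- edge_key(f[, 2], f[, 3])
    e3 <- edge_key(f[, 3], f[, 1])
    keys <- unique(c(e1, e2, e3))
    mid_idx <- setNames(nrow(v) + seq_along(keys), keys)
    pair <- do.call(rbind, strsplit(keys, " "))
    i <- as.integer(pair[, 1]); j <- as.integer(pair[, 2])
    mids <- (v[i, , drop = FALSE] + v[j, , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m1 <- mid_idx[e1]; m2 <- mid_idx[e2]; m3 <- mid_idx[e3]
    f <- rbind(
      cbind(f[, 1], m1, m3),
      cbind(f[, 2], m2, m1),
      cbind(f[, 3], m3, m2),
      cbind(m1, m2, m3)
    )
  }
  # enforce outward orientation (positive signed volume per face)
  s <- .swx_face_signed_volumes(v, f)
  flip <- s < 0
  if (any(flip)) f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  dimnames(f) <- NULL
  structure(list(vertices = v, faces = f), class = "swx_icosphere")
}

.swx_face_signed_volumes <- function(vertices, faces) {
  p1 <- vertices[faces[, 1], , drop = FALSE]
  p2 <- vertices[faces[, 2], , drop = FALSE]
  p3 <- vertices[faces[, 3], , drop = FALSE]
  (p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
   p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
   p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Build the envelope around the solute
#'
#' The envelope center is the mean solute position over all frames.  Each
#' icosphere vertex direction `u` is assigned the largest distance at which
#' the ray from the center along `u` exits the union of atom-centered spheres
#' of radius `d`, over all solute atoms of all frames: for an atom at
#' along-ray coordinate `t` and perpendicular distance `rho < d` the exit is
#' at `t + sqrt(d^2 - rho^2)`.  This guarantees every vertex is at least a
#' distance `d` from every solute atom of every frame.
#'
#' @param solute_frames List of (n_solute x 3) coordinate matrices (or a
#'   `swx_trajectory` restricted to solute atoms).
#' @param d Envelope distance from the solute in Angstrom (default 7).
#' @param depth Icosphere subdivision depth (default 4: 2562 vertices).
#' @param min_radius Floor for rays no atom constrains (degenerate cases).
#' @return A `swx_envelope`: list with `center`, `directions`, `radii`,
#'   `faces`, `build_distance`, plus face-lookup tables.
#' @export
build_envelope <- function(solute_frames, d = 7, depth = 4,
                           min_radius = 1e-3) {
  if (inherits(solute_frames, "swx_trajectory")) {
    solute_frames <- solute_frames$coords
  }
  if (is.matrix(solute_frames)) solute_frames <- list(solute_frames)
  if (!length(solute_frames)) stop("no solute frames")
  if (d <= 0) stop("envelope distance d must be positive")
  ico <- build_icosphere(depth)
  all_xyz <- do.call(rbind, solute_frames)
  center <- colMeans(all_xyz)
  rel <- sweep(all_xyz, 2, center)
  u <- ico$vertices
  radii <- rep(-Inf, nrow(u))
  block <- max(1L, floor(4e6 / nrow(u)))
  for (s in seq(1, nrow(rel), by = block)) {
    e <- min(s + block - 1L, nrow(rel))
    relb <- rel[s:e, , drop = FALSE]
    # t = rel . u  (atoms x vertices), rho^2 = |rel|^2 - t^2
    tmat <- relb %*% t(u)
    disc <- d^2 - pmax(sweep(-tmat^2, 1, rowSums(relb^2), "+"), 0)
    exit <- tmat + sqrt(pmax(disc, 0))
    exit[disc < 0] <- -Inf
    radii <- pmax(radii, apply(exit, 2, max))
  }
  radii <- pmax(radii, min_radius)
  env <- structure(list(
    center = center,
    directions = u,
    radii = radii,
    faces = ico$faces,
    build_distance = d,
    depth = depth
  ), class = "swx_envelope")
  env$vertex_faces <- .swx_vertex_face_index(env)
  env$face_inverses <- .swx_face_inverses(env)
  env
}

# faces adjacent to each vertex (list), for the nearest-vertex face lookup
.swx_vertex_face_index <- function(env) {
  nf <- nrow(env$faces)
  split(rep(seq_len(nf), 3), as.vector(env$faces))
}

# per-face inverse of the [v1 v2 v3] matrix, for barycentric solves
.swx_face_inverses <- function(env) {
  lapply(seq_len(nrow(env$faces)), function(i) {
    m <- t(env$directions[env$faces[i, ], ])
    solve(m)
  })
}

#' @export
print.swx_envelope <- function(x, ...) {
  cat(sprintf(
    "<swx_envelope> %d vertices, %d faces, d = %g A, radii [%.2f, %.2f] A\n",
    nrow(x$directions), nrow(x$faces), x$build_distance,
    min(x$radii), max(x$radii)))
  invisible(x)
}

# Surface radius of the envelope along unit direction(s) u (rows).
# Barycentric interpolation of the vertex radii on the face the direction
# falls in; the face is located via the nearest vertex with a brute-force
# fallback for the rare miss.
.swx_surface_radius <- function(env, u) {
  if (!is.matrix(u)) u <- matrix(u, ncol = 3)
  n <- nrow(u)
  out <- numeric(n)
  nearest <- integer(n)
  block <- max(1L, floor(4e6 / nrow(env$directions)))
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1L, n)
    dots <- u[s:e, , drop = FALSE] %*% t(env$directions)
    nearest[s:e] <- max.col(dots, ties.method = "first")
  }
  eps <- -1e-12
  for (i in seq_len(n)) {
    cand <- env$vertex_faces[[nearest[i]]]
    hit <- FALSE
    for (fi in cand) {
      w <- env$face_inverses[[fi]] %*% u[i, ]
      if (all(w >= eps)) {
        w <- pmax(w, 0)
        r_int <- sum(w * env$radii[env$faces[fi, ]]) / sum(w)
        out[i] <- r_int
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      # brute force over all faces (numerically marginal directions)
      best <- -Inf; best_r <- env$radii[nearest[i]]
      for (fi in seq_len(nrow(env$faces))) {
        w <- env$face_inverses[[fi]] %*% u[i, ]
        score <- min(w)
        if (score > best) {
          best <- score
          ww <- pmax(w, 0)
          best_r <- sum(ww * env$radii[env$faces[fi, ]]) / sum(ww)
        }
      }
      out[i] <- best_r
    }
  }
  out
}

#' Point-in-envelope test
#'
#' A point is inside iff its radial distance from the center does not exceed
#' the surface radius interpolated (barycentrically) on the face its
#' direction falls in.  The center itself is inside; boundary ties resolve
#' to inside.
#'
#' @param envelope A `swx_envelope`.
#' @param points A 3-vector or an n x 3 matrix (Angstrom).
#' @return Logical vector, one per point.
#' @export
envelope_contains <- function(envelope, points) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  rel <- sweep(points, 2, envelope$center)
  r <- sqrt(rowSums(rel^2))
  out <- logical(nrow(points))
  zero <- r < 1e-12
  out[zero] <- TRUE
  if (any(!zero)) {
    u <- rel[!zero, , drop = FALSE] / r[!zero]
    out[!zero] <- r[!zero] <= .swx_surface_radius(envelope, u)
  }
  out
}

#' Select the atoms of a frame inside the envelope
#'
#' Atom-wise selection: each atom is in or out individually, so water
#' molecules may be split by the boundary (the intensity decomposition
#' partitions density, not molecules).  `whole_molecule = TRUE` instead keeps
#' or drops entire molecules by the position of their first atom (for water,
#' the oxygen).
#'
#' @param envelope A `swx_envelope`.
#' @param frame n_atoms x 3 coordinate matrix in the envelope's frame.
#' @param structure The matching `swx_structure` (needed for
#'   `whole_molecule`).
#' @param whole_molecule Select whole molecules by their first atom.
#' @return Integer vector of selected atom indices.
#' @export
select_inside <- function(envelope, frame, structure = NULL,
                          whole_molecule = FALSE) {
  if (whole_molecule) {
    if (is.null(structure)) stop("whole_molecule selection needs a structure")
    mol <- structure$molecules
    first <- which(!duplicated(mol))
    inside_first <- envelope_contains(envelope, frame[first, , drop = FALSE])
    keep_mol <- mol[first][inside_first]
    which(mol %in% keep_mol)
  } else {
    which(envelope_contains(envelope, frame))
  }
}

#' Envelope diameter
#'
#' Maximum pairwise distance between envelope surface vertices; used as the
#' scale D in the quadrature-size rule `J_q = max(100, 0.2 (qD)^2)`.
#'
#' @param envelope A `swx_envelope`.
#' @return Diameter in Angstrom.
#' @export
envelope_diameter <- function(envelope) {
  pts <- envelope$directions * envelope$radii
  # vertices on the convex hull of directions suffice; V is small enough
  # for the direct O(V^2) scan at the default depth
  d2 <- 0
  n <- nrow(pts)
  block <- 512L
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1L, n)
    cross <- pts[s:e, , drop = FALSE] %*% t(pts)
    r2a <- rowSums(pts[s:e, , drop = FALSE]^2)
    r2b <- rowSums(pts^2)
    dd <- outer(r2a, r2b, "+") - 2 * cross
    d2 <- max(d2, max(dd))
  }
  sqrt(max(d2, 0))
}

#' Envelope volume
#'
#' Sum of signed tetrahedra spanned by the center and each surface triangle.
#'
#' @param envelope A `swx_envelope`.
#' @return Volume in Angstrom^3.
#' @export
envelope_volume <- function(envelope) {
  pts <- envelope$directions * envelope$radii
  sum(.swx_face_signed_volumes(pts, envelope$faces))
}

#' Export the envelope surface as an OBJ mesh
#'
#' @param envelope A `swx_envelope`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envelope_obj <- function(envelope, path) {
  pts <- sweep(envelope$directions * envelope$radii, 2, envelope$center, "+")
  lines <- c(
    "# solvaxs envelope mesh",
    sprintf("v %.4f %.4f %.4f", pts[, 1], pts[, 2], pts[, 3]),
    sprintf("f %d %d %d", envelope$faces[, 1], envelope$faces[, 2],
            envelope$faces[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}
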