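# Synthetic solute + water systems: rigid 3-site waters placed by
# dart-throwing, frames drawn independently (the scattering code needs
# configurational statistics, not dynamics), plus the run-length
# configuration calculators.

.SWX_OH_LENGTH <- 0.9572    # Angstrom
.SWX_HOH_ANGLE <- 104.52    # degrees
.SWX_E_PER_WATER <- 10

# run code with a locally seeded RNG, restoring the caller's RNG state
.swx_with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv())
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

.swx_random_rotation <- function() {
  # uniform rotation from a random unit quaternion
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# rigid water site offsets: O at origin, hydrogens in a plane
.swx_water_template <- function() {
  a <- .SWX_HOH_ANGLE * pi / 180
  r <- .SWX_OH_LENGTH
  rbind(c(0, 0, 0),
        r * c(sin(a / 2), 0, cos(a / 2)),
        r * c(-sin(a / 2), 0, cos(a / 2)))
}

# Dart-throw n oxygen positions in the box with a minimum O-O distance,
# rejecting positions within excl_radius of any row of excl_centers.
# Uses the current RNG stream.
.swx_place_oxygens <- function(box, n, min_dist, excl_centers = NULL,
                               excl_radius = 0, max_attempts = 500L * n) {
  acc <- matrix(NA_real_, n, 3)
  got <- 0L
  attempts <- 0L
  min2 <- min_dist^2
  ex2 <- excl_radius^2
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("water packing failed after ", max_attempts,
           " attempts (density or min_dist too high)")
    }
    p <- runif(3) * box
    if (!is.null(excl_centers) &&
        any(colSums((t(excl_centers) - p)^2) < ex2)) next
    if (got > 0L &&
        any(colSums((t(acc[seq_len(got), , drop = FALSE]) - p)^2) < min2)) {
      next
    }
    got <- got + 1L
    acc[got, ] <- p
  }
  acc
}

# full 3-site coordinates for a set of oxygen positions, random orientations
.swx_water_coords <- function(oxy) {
  tmpl <- .swx_water_template()
  n <- nrow(oxy)
  out <- matrix(NA_real_, 3L * n, 3)
  for (i in seq_len(n)) {
    rot <- .swx_random_rotation()
    out[(3 * i - 2):(3 * i), ] <- sweep(tmpl %*% t(rot), 2, oxy[i, ], "+")
  }
  out
}

.swx_water_atoms <- function(n_water, serial0 = 0L, resid0 = 0L) {
  tibble::tibble(
    serial = serial0 + seq_len(3L * n_water),
    name = rep(c("O", "H1", "H2"), n_water),
    name_raw = rep(c(" O  ", " H1 ", " H2 "), n_water),
    resname = "HOH",
    resid = resid0 + rep(seq_len(n_water), each = 3L),
    chain = "W",
    element = rep(c("O", "H", "H"), n_water),
    x = 0, y = 0, z = 0, hetero = TRUE
  )
}

.swx_structure_from_atoms <- function(atoms, molecules, box) {
  structure(list(atoms = atoms, molecules = as.integer(molecules),
                 box = box), class = "swx_structure")
}

#' Generate a random water box
#'
#' Rigid 3-site waters (O-H 0.9572 Angstrom, H-O-H 104.52 degrees) with
#' random orientations, oxygen positions dart-thrown with a minimum O-O
#' distance.  The number of molecules is chosen so the electron density
#' (10 e per water) matches `density` within rounding.
#'
#' @param box Box edge lengths in Angstrom (scalar for a cube, or 3-vector).
#' @param density Electron density in e nm^-3 (334 corresponds to pure
#'   water).
#' @param min_dist Minimum O-O distance in Angstrom.
#' @param seed Integer RNG seed; identical seeds give identical coordinates.
#' @return A list with `structure` (`swx_structure`) and `frame` (the n x 3
#'   coordinate matrix, identical to the structure's coordinates).
#' @export
generate_water_box <- function(box = c(40, 40, 40), density = 334,
                               min_dist = 2.4, seed = 1) {
  if (length(box) == 1L) box <- rep(box, 3)
  if (density <= 0) stop("density must be positive")
  n_water <- round(density * prod(box) / 1000 / .SWX_E_PER_WATER)
  if (n_water < 1) stop("box too small for a single water at this density")
  .swx_with_seed(seed, {
    oxy <- .swx_place_oxygens(box, n_water, min_dist)
    xyz <- .swx_water_coords(oxy)
    atoms <- .swx_water_atoms(n_water)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    st <- .swx_structure_from_atoms(atoms, rep(seq_len(n_water), each = 3L),
                                    box)
    list(structure = st, frame = xyz)
  })
}

.swx_solute_coords <- function(model = c("single-atom", "sphere-cluster",
                                         "helix"),
                               n = 1, R = 10, rise = 1.5, radius = 5,
                               box = c(40, 40, 40)) {
  model <- match.arg(model)
  center <- box / 2
  if (model == "single-atom") {
    return(matrix(center, 1, 3))
  }
  if (model == "sphere-cluster") {
    # uniform points in a ball of radius R
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- R * runif(n)^(1 / 3)
    return(sweep(u * r, 2, center, "+"))
  }
  k <- seq_len(n)
  turn <- 2 * pi / 3.6  # ~3.6 atoms per turn
  xyz <- cbind(radius * cos(k * turn), radius * sin(k * turn),
               rise * k - rise * (n + 1) / 2)
  sweep(xyz, 2, center, "+")
}

#' Generate a matched solute + pure-water system pair
#'
#' Emulates the paired simulation systems the method consumes: a solute
#' embedded in water and a companion pure-water box of the same size and
#' density.  Frames are independent draws (solvent configurations written
#' every 0.5 ps are treated as uncorrelated): the solute gets per-frame
#' Gaussian positional jitter of width `jitter_sigma`, waters are resampled
#' independently each frame.  In the solute system, waters are excluded from
#' the union of solute-atom spheres of radius `excl_radius`, and the water
#' count targets the bulk density in the remaining free volume, so the
#' density far from the solute matches the pure-water box.
#'
#' @param solute_model `"single-atom"`, `"sphere-cluster"` or `"helix"`.
#' @param n_solute Number of solute atoms (cluster/helix models).
#' @param R Cluster radius in Angstrom.
#' @param box Box edge lengths in Angstrom (scalar or 3-vector).
#' @param density Water electron density in e nm^-3.
#' @param n_frames Frames per system (>= 2 for buffer subtraction).
#' @param jitter_sigma Per-frame Gaussian jitter of solute positions
#'   (Angstrom); 0.3 mimics thermal fluctuation under backbone restraints.
#' @param excl_radius Solvent-exclusion radius around solute atoms
#'   (Angstrom).
#' @param min_dist Minimum O-O distance (Angstrom).
#' @param solute_element Element of the solute atoms.
#' @param seed Integer RNG seed.
#' @param dt Frame spacing in ps.
#' @return A list with `swx_system` members `solute` and `water`.
#' @export
generate_system_pair <- function(solute_model = "sphere-cluster",
                                 n_solute = 20, R = 6, box = c(40, 40, 40),
                                 density = 334, n_frames = 10,
                                 jitter_sigma = 0.3, excl_radius = 2.8,
                                 min_dist = 2.4, solute_element = "C",
                                 seed = 1, dt = 0.5) {
  if (length(box) == 1L) box <- rep(box, 3)
  if (n_frames < 1) stop("need at least one frame")
  .swx_with_seed(seed, {
    base <- .swx_solute_coords(solute_model, n = n_solute, R = R, box = box)
    ns <- nrow(base)
    # free volume via Monte-Carlo estimate of the excluded union
    probe <- matrix(runif(3 * 20000), ncol = 3) %*% diag(box)
    near <- vapply(seq_len(nrow(probe)), function(i) {
      any(colSums((t(base) - probe[i, ])^2) < excl_radius^2)
    }, logical(1))
    v_free <- prod(box) * (1 - mean(near))
    n_water <- round(density * v_free / 1000 / .SWX_E_PER_WATER)
    n_water_pure <- round(density * prod(box) / 1000 / .SWX_E_PER_WATER)
    if (n_water < 1 || n_water_pure < 1) stop("box too small for water")

    sol_frames <- vector("list", n_frames)
    wat_frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      sol_xyz <- base + matrix(rnorm(3 * ns, sd = jitter_sigma), ns, 3)
      oxy <- .swx_place_oxygens(box, n_water, min_dist,
                                excl_centers = sol_xyz,
                                excl_radius = excl_radius)
      sol_frames[[f]] <- rbind(sol_xyz, .swx_water_coords(oxy))
      oxy_p <- .swx_place_oxygens(box, n_water_pure, min_dist)
      wat_frames[[f]] <- .swx_water_coords(oxy_p)
    }

    sol_atoms <- tibble::tibble(
      serial = seq_len(ns),
      name = paste0(solute_element, seq_len(ns)),
      name_raw = formatC(paste0(" ", solute_element, seq_len(ns) %% 100),
                         width = -4),
      resname = "SLT", resid = 1L, chain = "A",
      element = solute_element,
      x = base[, 1], y = base[, 2], z = base[, 3], hetero = FALSE
    )
    wat_atoms <- .swx_water_atoms(n_water, serial0 = ns, resid0 = 1L)
    first <- sol_frames[[1]]
    all_atoms <- rbind(sol_atoms, wat_atoms)
    all_atoms$x <- first[, 1]; all_atoms$y <- first[, 2]
    all_atoms$z <- first[, 3]
    sol_struct <- .swx_structure_from_atoms(
      all_atoms, c(rep(1L, ns), 1L + rep(seq_len(n_water), each = 3L)), box)

    pw_atoms <- .swx_water_atoms(n_water_pure)
    pw1 <- wat_frames[[1]]
    pw_atoms$x <- pw1[, 1]; pw_atoms$y <- pw1[, 2]; pw_atoms$z <- pw1[, 3]
    wat_struct <- .swx_structure_from_atoms(
      pw_atoms, rep(seq_len(n_water_pure), each = 3L), box)

    times <- (seq_len(n_frames) - 1) * dt
    list(
      solute = swx_system(sol_struct,
                          new_trajectory(sol_frames, times, box = box)),
      water = swx_system(wat_struct,
                         new_trajectory(wat_frames, times, box = box)),
      n_solute_atoms = ns
    )
  })
}

#' Recommended number of trajectory frames
#'
#' The convergence of the frame average degrades slowly with solute size:
#' the total number of frames is `N_fr = 2e5 / N_A^0.77` with `N_A` the
#' solute atom count.  The convergence setting scales this: `quick` is four
#' times fewer frames, `thorough` five times more.
#'
#' @param n_solute_atoms Number of solute atoms, >= 1.
#' @param convergence `"quick"`, `"normal"` or `"thorough"`.
#' @return Integer frame count (at least 2).
#' @export
recommended_frames <- function(n_solute_atoms,
                               convergence = c("normal", "quick",
                                               "thorough")) {
  convergence <- match.arg(convergence)
  if (n_solute_atoms < 1) stop("need at least one solute atom")
  normal <- 2e5 / n_solute_atoms^0.77
  out <- switch(convergence,
                normal = round(normal),
                quick = round(normal / 4),
                thorough = round(5 * normal))
  max(2L, as.integer(out))
}

#' Equilibration time to discard
#'
#' 5% of the total simulation time, but not shorter than 3 ps, capped at the
#' total time.
#'
#' @param total_time Total simulation time in ps, > 0.
#' @return Discard time in ps.
#' @export
equilibration_split <- function(total_time) {
  if (total_time <= 0) stop("total time must be positive")
  min(max(0.05 * total_time, 3), total_time)
}
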