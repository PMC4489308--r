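# Per-frame scattering amplitudes, the three-term net intensity, and the
# orientational average over spiral-quadrature q-vectors.

#' Number of quadrature vectors for a q shell
#'
#' The orientational average converges when the number of directions grows
#' like (qD)^2, D being the maximum diameter of the scattering volume; the
#' rule used is `J_q = max(100, 0.2 * (qD)^2)` (quadratic branch rounded up).
#'
#' @param q Scattering-vector magnitude (1/Angstrom), >= 0.
#' @param D Maximum diameter in Angstrom, > 0.
#' @return Integer number of directions.
#' @export
jq_count <- function(q, D) {
  if (any(q < 0)) stop("q must be non-negative")
  if (D <= 0) stop("D must be positive")
  pmax(100L, as.integer(ceiling(0.2 * (q * D)^2)))
}

#' Spiral points on the unit sphere
#'
#' Deterministic generalized (golden-angle) Fibonacci spiral: `J`
#' approximately uniform unit vectors.
#'
#' @param J Number of points, >= 1.
#' @return J x 3 matrix of unit vectors.
#' @export
spiral_directions <- function(J) {
  if (J < 1) stop("J must be >= 1")
  k <- seq_len(J)
  z <- (2 * k - 1) / J - 1
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Scattering amplitude of a set of atoms
#'
#' `A(q) = sum_j f_j(|q|) exp(-i q . r_j)` with Cromer-Mann form factors.
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param elements Table keys aligned with `coords` rows (element symbols,
#'   `OW`/`HW` for water atoms).
#' @param table A `swx_fftable`.
#' @param qvec A single 3-vector or a J x 3 matrix of q-vectors (1/Angstrom).
#' @return Complex amplitude(s) in electrons, one per q-vector.
#' @export
amplitude <- function(coords, elements, table, qvec) {
  if (!is.matrix(qvec)) qvec <- matrix(qvec, ncol = 3)
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3)
  if (length(elements) != nrow(coords)) {
    stop("coords and elements are not aligned")
  }
  qmag <- sqrt(rowSums(qvec^2))
  out <- complex(nrow(qvec))
  # form factors depend only on |q|; group q-vectors by magnitude
  for (m in unique(qmag)) {
    idx <- which(qmag == m)
    fv <- .swx_form_factors_at(table, elements, m)
    out[idx] <- .sw_amplitudes_cpp(coords, fv,
                                   qvec[idx, , drop = FALSE])
  }
  if (length(out) == 1L) out[[1]] else out
}

#' Uniform q grid
#' @param qmax Maximum q in 1/Angstrom (default 1).
#' @param nq Number of points including 0 (default 101).
#' @return Numeric vector of q magnitudes.
#' @export
qgrid <- function(qmax = 1, nq = 101) {
  if (qmax <= 0 || nq < 2) stop("need qmax > 0 and nq >= 2")
  seq(0, qmax, length.out = nq)
}

#' Bundle a structure and its trajectory
#' @param structure A `swx_structure`.
#' @param trajectory The matching `swx_trajectory`.
#' @return A `swx_system` list.
#' @export
swx_system <- function(structure, trajectory) {
  if (n_atoms(structure) != nrow(trajectory$coords[[1]])) {
    stop("structure and trajectory atom counts differ")
  }
  structure(list(structure = structure, trajectory = trajectory),
            class = "swx_system")
}

# contiguous block ids for jackknife resampling
.swx_block_ids <- function(n, nb) ceiling(seq_len(n) * nb / n)

# Per-system, per-frame envelope selections (atom index + coords + keys).
.swx_frame_selections <- function(system, envelope, whole_molecule) {
  keys <- water_aware_keys(system$structure)
  lapply(system$trajectory$coords, function(xyz) {
    sel <- if (is.null(envelope)) {
      seq_len(nrow(xyz))
    } else {
      select_inside(envelope, xyz, system$structure,
                    whole_molecule = whole_molecule)
    }
    list(coords = xyz[sel, , drop = FALSE], keys = keys[sel])
  })
}

# Accumulate per-block sums of A and |A|^2 over frames for one q shell.
.swx_shell_sums <- function(sels, table, q, qvecs, block_ids, nb) {
  J <- nrow(qvecs)
  sumA <- matrix(complex(real = 0), nb, J)
  sumA2 <- matrix(0, nb, J)
  cnt <- integer(nb)
  for (i in seq_along(sels)) {
    s <- sels[[i]]
    fv <- .swx_form_factors_at(table, s$keys, q)
    a <- .sw_amplitudes_cpp(s$coords, fv, qvecs)
    b <- block_ids[i]
    sumA[b, ] <- sumA[b, ] + a
    sumA2[b, ] <- sumA2[b, ] + Re(a * Conj(a))
    cnt[b] <- cnt[b] + 1L
  }
  list(sumA = sumA, sumA2 = sumA2, cnt = cnt)
}

# D(q) per direction from frame means of the two systems.
.swx_three_term <- function(meanA, meanA2, meanB = NULL, meanB2 = NULL) {
  if (is.null(meanB)) return(meanA2)
  meanA2 - meanB2 + 2 * Re(-Conj(meanB) * (meanA - meanB))
}

#' Compute the buffer-subtracted scattering curve
#'
#' For every q magnitude, `J_q` q-vectors are spread on the sphere of radius q
#' (spiral quadrature).  Per q-vector, frame averages of the amplitudes of the
#' envelope-selected atoms are accumulated for the solute system (A) and the
#' pure-water system (B), and combined as
#' `D(q) = <|A|^2> - <|B|^2> + 2 Re[-<B>* (<A> - <B>)]`;
#' the intensity is the mean of `D` over the shell's directions.  This
#' realizes the total buffer-subtraction scheme; see [apply_subtraction()]
#' for the reduced scheme.  With `water = NULL` (vacuum mode) the curve is
#' the orientationally averaged `<|A|^2>`.
#'
#' @param solute A `swx_system` (solute + solvent simulation system).
#' @param water A `swx_system` for the matched pure-water system, or NULL for
#'   vacuum mode.
#' @param envelope A `swx_envelope`, or NULL (vacuum mode only) to use all
#'   atoms.
#' @param q Vector of q magnitudes (1/Angstrom), e.g. [qgrid()].
#' @param table A `swx_fftable` (with any water/density corrections already
#'   applied).
#' @param equilibrate Discard equilibration frames first (5% of the total
#'   time, at least 3 ps) via [discard_equilibration()].
#' @param jq_multiplier Multiplies the `J_q` rule (convergence checks).
#' @param n_blocks Number of contiguous frame blocks for the jackknife error
#'   estimate (default 10; reduced when there are fewer frames).
#' @param whole_molecule Envelope selection by whole molecules instead of
#'   atom-wise.
#' @param keep_components Store per-direction frame averages per shell in the
#'   metadata (for diagnostics; memory grows with J).
#' @return A `swx_curve` with columns `q`, `I`, `sigma` and metadata
#'   including the per-q buffer term `buffer_I` (mean `<|B|^2>`).
#' @export
calc_intensity <- function(solute, water = NULL, envelope = NULL, q = qgrid(),
                           table = load_form_factor_table(),
                           equilibrate = FALSE, jq_multiplier = 1,
                           n_blocks = 10, whole_molecule = FALSE,
                           keep_components = FALSE) {
  if (is.null(envelope) && !is.null(water)) {
    stop("an envelope is required unless running in vacuum mode")
  }
  if (equilibrate) {
    solute$trajectory <- discard_equilibration(solute$trajectory)
    if (!is.null(water)) {
      water$trajectory <- discard_equilibration(water$trajectory)
    }
  }
  if (!is.null(water)) {
    .swx_check_envelope_in_box(envelope, water)
    if (n_frames(solute$trajectory) < 2 || n_frames(water$trajectory) < 2) {
      stop("need >= 2 frames per system for buffer subtraction")
    }
  }
  D <- if (!is.null(envelope)) {
    envelope_diameter(envelope)
  } else {
    .swx_max_extent(solute$trajectory)
  }
  selsA <- .swx_frame_selections(solute, envelope, whole_molecule)
  selsB <- if (!is.null(water)) {
    .swx_frame_selections(water, envelope, whole_molecule)
  }
  nA <- length(selsA)
  nB <- if (is.null(selsB)) nA else length(selsB)
  nb <- max(1L, min(n_blocks, nA, nB))
  blkA <- .swx_block_ids(nA, nb)
  blkB <- .swx_block_ids(nB, nb)

  I <- sigma <- buffer <- buffer_fluct <- numeric(length(q))
  comps <- if (keep_components) vector("list", length(q))
  for (iq in seq_along(q)) {
    J <- max(100L, as.integer(ceiling(jq_count(q[iq], D) * jq_multiplier)))
    qvecs <- q[iq] * spiral_directions(J)
    sa <- .swx_shell_sums(selsA, table, q[iq], qvecs, blkA, nb)
    meanA <- colSums(sa$sumA) / nA
    meanA2 <- colSums(sa$sumA2) / nA
    if (is.null(selsB)) {
      Dj <- .swx_three_term(meanA, meanA2)
      buffer[iq] <- 0
      sb <- NULL
    } else {
      sb <- .swx_shell_sums(selsB, table, q[iq], qvecs, blkB, nb)
      meanB <- colSums(sb$sumA) / nB
      meanB2 <- colSums(sb$sumA2) / nB
      Dj <- .swx_three_term(meanA, meanA2, meanB, meanB2)
      buffer[iq] <- mean(meanB2)
      buffer_fluct[iq] <- mean(meanB2 - Re(meanB * Conj(meanB)))
    }
    I[iq] <- mean(Dj)
    sigma[iq] <- .swx_jackknife_se(sa, sb, nb)
    if (keep_components) {
      comps[[iq]] <- list(
        q = q[iq], qvecs = qvecs,
        meanA = meanA, meanA2 = meanA2,
        meanB = if (!is.null(sb)) meanB, meanB2 = if (!is.null(sb)) meanB2
      )
    }
  }
  meta <- list(
    envelope_distance = if (!is.null(envelope)) envelope$build_distance,
    envelope_volume = if (!is.null(envelope)) envelope_volume(envelope),
    diameter = D,
    n_frames_solute = nA,
    n_frames_water = if (!is.null(selsB)) nB,
    subtraction = if (is.null(selsB)) "vacuum" else "total",
    buffer_I = buffer,
    buffer_fluct = buffer_fluct
  )
  if (keep_components) meta$components <- comps
  new_curve(tibble::tibble(q = q, I = I, sigma = sigma), meta = meta)
}

# leave-one-block-out jackknife standard error of the shell intensity
.swx_jackknife_se <- function(sa, sb, nb) {
  if (nb < 2L) return(0)
  vals <- numeric(nb)
  totA <- colSums(sa$sumA); totA2 <- colSums(sa$sumA2); cntA <- sum(sa$cnt)
  if (!is.null(sb)) {
    totB <- colSums(sb$sumA); totB2 <- colSums(sb$sumA2); cntB <- sum(sb$cnt)
  }
  for (b in seq_len(nb)) {
    mA <- (totA - sa$sumA[b, ]) / (cntA - sa$cnt[b])
    mA2 <- (totA2 - sa$sumA2[b, ]) / (cntA - sa$cnt[b])
    if (is.null(sb)) {
      vals[b] <- mean(.swx_three_term(mA, mA2))
    } else {
      mB <- (totB - sb$sumA[b, ]) / (cntB - sb$cnt[b])
      mB2 <- (totB2 - sb$sumA2[b, ]) / (cntB - sb$cnt[b])
      vals[b] <- mean(.swx_three_term(mA, mA2, mB, mB2))
    }
  }
  sqrt((nb - 1) / nb * sum((vals - mean(vals))^2))
}

.swx_max_extent <- function(trajectory) {
  d <- 0
  for (xyz in trajectory$coords) {
    rng <- apply(xyz, 2, range)
    d <- max(d, sqrt(sum((rng[2, ] - rng[1, ])^2)))
  }
  max(d, 1)
}

# The envelope must fit inside the water box in every frame, otherwise the
# excluded-solvent region cannot be filled.
.swx_check_envelope_in_box <- function(envelope, water) {
  pts <- sweep(envelope$directions * envelope$radii, 2, envelope$center, "+")
  box <- water$trajectory$box %||% water$structure$box
  tol <- 1e-6
  if (!is.null(box)) {
    lo <- rep(0, 3); hi <- box
  } else {
    allc <- do.call(rbind, water$trajectory$coords)
    lo <- apply(allc, 2, min) - 1.5
    hi <- apply(allc, 2, max) + 1.5
  }
  if (any(sweep(pts, 2, lo) < -tol) || any(sweep(pts, 2, hi, "-") > tol)) {
    stop("envelope does not fit inside the water box; enlarge the box or ",
         "reduce the envelope distance")
  }
  invisible(TRUE)
}
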