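# Fixtures are built in code: point-atom structures, tiny PDB texts and
# synthetic systems.  No binary data anywhere.

make_structure <- function(xyz, element = "C", resname = "SLT",
                           chain = "A", resid = 1L, hetero = FALSE,
                           molecules = NULL, box = NULL) {
  xyz <- if (!is.matrix(xyz)) matrix(xyz, ncol = 3) else xyz
  n <- nrow(xyz)
  element <- rep_len(element, n)
  atoms <- tibble::tibble(
    serial = seq_len(n),
    name = paste0(element, seq_len(n)),
    name_raw = formatC(paste0(" ", element, seq_len(n) %% 10), width = -4),
    resname = rep_len(resname, n),
    resid = rep_len(as.integer(resid), n),
    chain = rep_len(chain, n),
    element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    hetero = rep_len(hetero, n)
  )
  if (is.null(molecules)) molecules <- rep(1L, n)
  solvaxs:::.swx_structure_from_atoms(atoms, molecules, box)
}

# combine several structures into one (concatenating molecules)
bind_structures <- function(...) {
  parts <- list(...)
  atoms <- do.call(rbind, lapply(parts, function(s) s$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  mols <- integer(0)
  off <- 0L
  for (s in parts) {
    mols <- c(mols, s$molecules + off)
    off <- off + max(s$molecules)
  }
  solvaxs:::.swx_structure_from_atoms(atoms, mols, parts[[1]]$box)
}

vacuum_system <- function(xyz, element = "C") {
  st <- make_structure(xyz, element = element)
  swx_system(st, new_trajectory(list(st |> coords())))
}

# uniform points in a ball (deterministic given seed)
ball_points <- function(n, R, seed) {
  solvaxs:::.swx_with_seed(seed, {
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    u * R * runif(n)^(1 / 3)
  })
}

# small polymer stand-in: a grid of non-hetero carbon atoms
polymer_grid <- function(spacing = 3, nside = 3, origin = c(0, 0, 0)) {
  g <- expand.grid(x = seq_len(nside), y = seq_len(nside),
                   z = seq_len(nside))
  xyz <- sweep(as.matrix(g) * spacing, 2, origin, "+")
  make_structure(xyz, element = "C", resname = "GLY", chain = "A",
                 hetero = FALSE)
}

# shared small solvated fixture (built once per test run)
solvated_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pair <- generate_system_pair(solute_model = "sphere-cluster",
                                   n_solute = 20, R = 6, box = 36,
                                   density = 334, n_frames = 4, seed = 1)
      env <- build_envelope(
        lapply(pair$solute$trajectory$coords,
               function(x) x[seq_len(20), , drop = FALSE]),
        d = 7, depth = 3)
      tab <- apply_water_correction(load_form_factor_table())
      tab <- solvent_density_correction(tab, pair$water$structure,
                                        pair$water$trajectory, 334)
      cache <<- list(pair = pair, env = env, tab = tab)
    }
    cache
  }
})
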