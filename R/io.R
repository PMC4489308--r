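# Structure / trajectory / curve input-output.
#
# The native trajectory dialect is multi-model PDB so that every fixture can
# be a small text file; coordinates are carried in Angstrom and q in 1/Angstrom
# everywhere inside the package, with unit conversion only at the IO boundary.

.swx_parse_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  lines[rec %in% c("ATOM  ", "HETATM") | grepl("^(ATOM|HETATM)", rec)]
}

.swx_num <- function(x) suppressWarnings(as.numeric(x))

.swx_parse_atoms <- function(atom_lines) {
  n <- length(atom_lines)
  if (n == 0L) stop("no ATOM/HETATM records found")
  atom_lines <- formatC(atom_lines, width = -80)  # left-justified pad
  f <- function(a, b) substr(atom_lines, a, b)
  serial <- .swx_num(f(7, 11))
  name_raw <- f(13, 16)
  resname <- trimws(f(18, 21))
  chain <- trimws(f(22, 22))
  resid <- .swx_num(f(23, 26))
  x <- .swx_num(f(31, 38)); y <- .swx_num(f(39, 46)); z <- .swx_num(f(47, 54))
  elem_col <- trimws(f(77, 78))
  hetero <- grepl("^HETATM", atom_lines)
  element <- .swx_normalize_element(elem_col)
  missing_el <- element == "" | !(element %in% .SWX_KNOWN_ELEMENTS)
  if (any(missing_el)) {
    element[missing_el] <- infer_element(name_raw[missing_el],
                                         resname[missing_el])
  }
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(z)
  if (any(bad)) {
    stop("non-numeric coordinates at atom record ", which(bad)[1])
  }
  tibble::tibble(
    serial = as.integer(serial), name = trimws(name_raw),
    name_raw = name_raw, resname = resname, resid = as.integer(resid),
    chain = chain, element = element, x = x, y = y, z = z, hetero = hetero
  )
}

# Union-find over atoms: same residue always bonded; consecutive residues of
# standard polymer type within a chain bonded (residue-level fallback when no
# CONECT records are present); CONECT records merge anything they name.
.swx_molecules <- function(atoms, conect) {
  n <- nrow(atoms)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  res_key <- paste(atoms$chain, atoms$resid, atoms$resname, sep = "|")
  first_of_res <- !duplicated(res_key)
  res_index <- cumsum(first_of_res)
  # same residue -> one molecule
  for (r in split(seq_len(n), res_index)) {
    if (length(r) > 1L) for (k in r[-1]) union2(r[1], k)
  }
  # consecutive polymer residues in a chain
  res_first <- which(first_of_res)
  if (length(res_first) > 1L) {
    for (i in seq_len(length(res_first) - 1L)) {
      a <- res_first[i]; b <- res_first[i + 1L]
      if (atoms$chain[a] == atoms$chain[b] &&
          .swx_is_polymer_resname(atoms$resname[a]) &&
          .swx_is_polymer_resname(atoms$resname[b]) &&
          abs(atoms$resid[b] - atoms$resid[a]) == 1L) {
        union2(a, b)
      }
    }
  }
  if (length(conect)) {
    serial_to_idx <- setNames(seq_len(n), atoms$serial)
    for (cn in conect) {
      ids <- as.character(cn)
      idx <- serial_to_idx[ids]
      idx <- idx[!is.na(idx)]
      if (length(idx) > 1L) for (k in idx[-1]) union2(idx[1], k)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

.swx_parse_conect <- function(lines) {
  cl <- lines[grepl("^CONECT", lines)]
  lapply(cl, function(l) {
    l <- formatC(l, width = -31)
    ids <- c(substr(l, 7, 11), substr(l, 12, 16), substr(l, 17, 21),
             substr(l, 22, 26), substr(l, 27, 31))
    ids <- .swx_num(ids)
    as.integer(ids[is.finite(ids)])
  })
}

.swx_parse_cryst1 <- function(lines) {
  cl <- lines[grepl("^CRYST1", lines)]
  if (!length(cl)) return(NULL)
  l <- cl[1]
  box <- .swx_num(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33)))
  if (any(!is.finite(box)) || any(box <= 0)) return(NULL)
  box
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records in file order.  Elements come from the element
#' column when present, otherwise from the atom name via [infer_element()].
#' Molecules are derived from CONECT records plus a residue-level fallback
#' (atoms of one residue are one molecule; consecutive standard polymer
#' residues of a chain are joined).  Only the first MODEL is used; see
#' [read_trajectory()] for multi-model files.
#'
#' @param path Path to a PDB file.
#' @return A `swx_structure`: list with `atoms` (tibble), `molecules`
#'   (integer molecule id per atom) and `box` (3 lengths in Angstrom or NULL).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # restrict to first model if models present
  m1 <- which(grepl("^MODEL", lines))
  if (length(m1)) {
    e1 <- which(grepl("^ENDMDL", lines))
    if (!length(e1)) stop("MODEL without ENDMDL in ", path)
    body <- lines[seq(m1[1] + 1L, e1[1] - 1L)]
    outside <- lines[-seq(m1[1], tail(e1, 1))]
    atom_lines <- .swx_parse_pdb_lines(body)
    conect <- .swx_parse_conect(c(outside, body))
  } else {
    atom_lines <- .swx_parse_pdb_lines(lines)
    conect <- .swx_parse_conect(lines)
  }
  if (!length(atom_lines)) stop("zero atoms in ", path)
  atoms <- .swx_parse_atoms(atom_lines)
  structure(list(
    atoms = atoms,
    molecules = .swx_molecules(atoms, conect),
    box = .swx_parse_cryst1(lines)
  ), class = "swx_structure")
}

#' @export
print.swx_structure <- function(x, ...) {
  cat("<swx_structure> ", nrow(x$atoms), " atoms, ",
      max(x$molecules), " molecules",
      if (!is.null(x$box)) sprintf(", box %.1f x %.1f x %.1f A",
                                   x$box[1], x$box[2], x$box[3]),
      "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure A `swx_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinates of a structure as a matrix
#' @param structure A `swx_structure`.
#' @return Numeric matrix (atoms x 3), Angstrom.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Read a multi-model PDB trajectory
#'
#' One frame per MODEL record (a file without MODEL records is a single
#' frame).  Frame times are assigned at a uniform 0.5 ps spacing (the frame
#' interval the method assumes for uncorrelated solvent configurations)
#' unless `dt` is given.
#'
#' @param path Path to a (multi-model) PDB file.
#' @param structure The matching `swx_structure`; atom counts must agree.
#' @param dt Frame spacing in ps (default 0.5).
#' @return A `swx_trajectory`: list with `coords` (list of atoms x 3
#'   matrices), `times` (ps) and `box`.
#' @export
read_trajectory <- function(path, structure, dt = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(grepl("^MODEL", lines))
  frames <- list()
  if (!length(starts)) {
    atoms <- .swx_parse_atoms(.swx_parse_pdb_lines(lines))
    frames[[1]] <- unname(as.matrix(atoms[, c("x", "y", "z")]))
  } else {
    ends <- which(grepl("^ENDMDL", lines))
    if (length(ends) != length(starts)) {
      stop("unbalanced MODEL/ENDMDL records in ", path)
    }
    for (i in seq_along(starts)) {
      body <- lines[seq(starts[i] + 1L, ends[i] - 1L)]
      al <- .swx_parse_pdb_lines(body)
      if (length(al) != n_atoms(structure)) {
        stop("model ", i, " has ", length(al), " atoms, expected ",
             n_atoms(structure))
      }
      atoms <- .swx_parse_atoms(al)
      frames[[i]] <- unname(as.matrix(atoms[, c("x", "y", "z")]))
    }
  }
  if (!length(frames)) stop("zero frames in ", path)
  if (nrow(frames[[1]]) != n_atoms(structure)) {
    stop("trajectory has ", nrow(frames[[1]]), " atoms, structure has ",
         n_atoms(structure))
  }
  new_trajectory(frames, times = (seq_along(frames) - 1) * dt,
                 box = .swx_parse_cryst1(lines))
}

#' Construct a trajectory object from in-memory frames
#' @param frames List of atoms x 3 coordinate matrices (Angstrom).
#' @param times Frame time stamps in ps; strictly increasing.
#' @param box Box lengths in Angstrom (3-vector) or NULL.
#' @return A `swx_trajectory`.
#' @export
new_trajectory <- function(frames, times = (seq_along(frames) - 1) * 0.5,
                           box = NULL) {
  stopifnot(length(frames) >= 1L)
  nat <- vapply(frames, nrow, integer(1))
  if (length(unique(nat)) != 1L) stop("frames have differing atom counts")
  if (length(times) != length(frames) ||
      (length(times) > 1 && any(diff(times) <= 0))) {
    stop("times must be strictly increasing, one per frame")
  }
  structure(list(coords = frames, times = as.numeric(times), box = box),
            class = "swx_trajectory")
}

#' @export
print.swx_trajectory <- function(x, ...) {
  cat("<swx_trajectory> ", length(x$coords), " frames, ",
      nrow(x$coords[[1]]), " atoms, t = ", x$times[1], "...",
      tail(x$times, 1), " ps\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `swx_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$coords)

#' Discard equilibration frames
#'
#' Removes the leading frames covering `max(0.05 * total_time, 3 ps)` (capped
#' at the total time), the equilibration rule applied before collecting
#' frames for the scattering calculation.
#'
#' @param trajectory A `swx_trajectory`.
#' @return The trimmed `swx_trajectory` (at least one frame is kept).
#' @export
discard_equilibration <- function(trajectory) {
  tt <- trajectory$times
  total <- tail(tt, 1) - tt[1]
  if (total <= 0) return(trajectory)
  cut <- tt[1] + equilibration_split(total)
  keep <- which(tt >= cut)
  if (!length(keep)) keep <- length(tt)
  new_trajectory(trajectory$coords[keep], times = tt[keep],
                 box = trajectory$box)
}

.swx_format_atom_line <- function(rec, serial, name_raw, resname, chain,
                                  resid, x, y, z, element) {
  nm <- name_raw
  fix <- nchar(nm) != 4L
  if (any(fix)) {
    short <- nchar(nm[fix]) <= 3L & nchar(element[fix]) == 1L
    nm[fix][short] <- formatC(paste0(" ", nm[fix][short]), width = -4)
    nm[fix][!short] <- formatC(nm[fix][!short], width = -4)
    nm[fix] <- substr(nm[fix], 1, 4)
  }
  sprintf("%-6s%5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial %% 100000L, nm, substr(resname, 1, 4),
          substr(paste0(chain, " "), 1, 1), resid %% 10000L,
          x, y, z, 1.0, 0.0, formatC(element, width = 2))
}

#' Write a structure (optionally with a trajectory) as PDB
#'
#' @param structure A `swx_structure`.
#' @param path Output path.
#' @param trajectory Optional `swx_trajectory`; each frame becomes one MODEL.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, trajectory = NULL) {
  a <- structure$atoms
  rec <- ifelse(a$hetero, "HETATM", "ATOM")
  lines <- character(0)
  box <- if (!is.null(trajectory) && !is.null(trajectory$box)) {
    trajectory$box
  } else {
    structure$box
  }
  if (!is.null(box)) {
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      box[1], box[2], box[3], 90, 90, 90))
  }
  emit_frame <- function(xyz) {
    .swx_format_atom_line(rec, a$serial, a$name_raw, a$resname, a$chain,
                          a$resid, xyz[, 1], xyz[, 2], xyz[, 3], a$element)
  }
  if (is.null(trajectory)) {
    lines <- c(lines, emit_frame(coords(structure)), "END")
  } else {
    for (i in seq_along(trajectory$coords)) {
      lines <- c(lines, sprintf("MODEL     %4d", i),
                 emit_frame(trajectory$coords[[i]]), "ENDMDL")
    }
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an experimental scattering curve
#'
#' Whitespace- or comma-separated text with 2 or 3 numeric columns
#' (q, I, optional sigma); lines starting with `#` are comments.  No unit
#' conversion happens at read time; the declared units/convention travel with
#' the curve and are resolved by [convert_q()] at fit time.
#'
#' @param path Path to the curve file.
#' @param q_units `"A^-1"` or `"nm^-1"`.
#' @param convention `"q"` (4 pi sin(theta)/lambda) or `"s"`
#'   (2 sin(theta)/lambda).
#' @return A `swx_curve` tibble with columns `q`, `I` and (if present)
#'   `sigma`, and attributes `q_units`, `convention`.
#' @export
read_curve <- function(path, q_units = c("A^-1", "nm^-1"),
                       convention = c("q", "s")) {
  q_units <- match.arg(q_units)
  convention <- match.arg(convention)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data rows in ", path)
  sep_comma <- grepl(",", lines[1])
  fields <- strsplit(trimws(lines), if (sep_comma) "\\s*,\\s*" else "\\s+")
  ncol <- unique(vapply(fields, length, integer(1)))
  if (length(ncol) != 1L || ncol < 2L) {
    stop("curve file must have a constant 2 or 3 numeric columns")
  }
  vals <- matrix(.swx_num(unlist(fields)), ncol = ncol[1], byrow = TRUE)
  if (any(!is.finite(vals[, 1:2]))) stop("non-numeric rows in ", path)
  if (any(diff(vals[, 1]) <= 0)) stop("q values must be strictly increasing")
  cur <- tibble::tibble(q = vals[, 1], I = vals[, 2])
  if (ncol[1] >= 3L) {
    s3 <- vals[, 3]
    if (any(!is.finite(s3))) stop("non-numeric sigma column in ", path)
    if (all(s3 == 0)) {
      # a written curve with no statistical errors; treat sigma as absent
    } else if (any(s3 <= 0)) {
      stop("sigma column must be strictly positive")
    } else {
      cur$sigma <- s3
    }
  }
  new_curve(cur, q_units = q_units, convention = convention)
}

#' Construct a scattering-curve object
#' @param df Data frame with columns `q`, `I` and optionally `sigma`.
#' @param q_units,convention Units metadata (see [read_curve()]).
#' @param meta Named list of provenance metadata.
#' @return A `swx_curve` tibble.
#' @export
new_curve <- function(df, q_units = "A^-1", convention = "q", meta = list()) {
  out <- tibble::as_tibble(df)
  stopifnot(all(c("q", "I") %in% names(out)))
  attr(out, "q_units") <- q_units
  attr(out, "convention") <- convention
  attr(out, "meta") <- meta
  class(out) <- c("swx_curve", class(tibble::tibble()))
  out
}

#' Write a scattering curve to a text file
#'
#' Emits three columns (q, I, sigma; sigma written as 0 when absent) plus
#' `#`-prefixed provenance header lines (envelope distance, frame counts,
#' subtraction scheme) taken from the curve metadata.
#'
#' @param curve A `swx_curve`.
#' @param path Output path.
#' @param out_units `"A^-1"` or `"nm^-1"`; q is converted on output only.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, out_units = c("A^-1", "nm^-1")) {
  out_units <- match.arg(out_units)
  if (nrow(curve) == 0L) stop("refusing to write an empty curve")
  q <- curve$q
  if (identical(attr(curve, "q_units"), "A^-1") && out_units == "nm^-1") {
    q <- q * 10
  } else if (identical(attr(curve, "q_units"), "nm^-1") &&
             out_units == "A^-1") {
    q <- q / 10
  }
  sigma <- if ("sigma" %in% names(curve)) curve$sigma else rep(0, nrow(curve))
  meta <- attr(curve, "meta")
  hdr <- c(
    sprintf("# solvaxs scattering curve (q in %s, q convention)", out_units),
    if (!is.null(meta$envelope_distance)) {
      sprintf("# envelope distance: %g A", meta$envelope_distance)
    },
    if (!is.null(meta$n_frames_solute)) {
      sprintf("# frames: solute %d, water %s", meta$n_frames_solute,
              if (is.null(meta$n_frames_water)) "none (vacuum)" else
                as.character(meta$n_frames_water))
    },
    if (!is.null(meta$subtraction)) {
      sprintf("# subtraction scheme: %s", meta$subtraction)
    },
    "# columns: q I sigma_stat"
  )
  body <- sprintf("%.8g %.8g %.8g", q, curve$I, sigma)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @export
print.swx_curve <- function(x, ...) {
  cat("<swx_curve> ", nrow(x), " points, q in [",
      min(x$q), ", ", max(x$q), "] ", attr(x, "q_units") %||% "A^-1",
      "\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
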