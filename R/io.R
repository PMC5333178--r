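# Readers and writers.
#
# Multi-model PDB is the baseline trajectory dialect; parsing goes through
# bio3d rather than a hand-rolled parser. PQR supplies per-atom partial
# charges (occupancy column) and radii. Tunnel sphere profiles are plain CSV
# with a frame,x,y,z,r header (CAVER-style export). Active-site specs are
# YAML or JSON lists of {chain, resid}.

#' Load a protein + ligand trajectory
#'
#' Reads a multi-model PDB trajectory, splits off the ligand, and returns
#' the protein context together with the ligand's reference-point
#' trajectory. Frames and atoms are never reordered: time index `i` in all
#' downstream tables refers to input MODEL `i` (0-based).
#'
#' @param trajectory_path Path to a multi-model PDB file (MODEL/ENDMDL).
#' @param ligand_selector Either a residue name (e.g. `"LIG"`) or a
#'   `"chain:resid"` string; must match exactly one residue.
#' @param charges_path Optional PQR file carrying per-atom partial charges
#'   (occupancy column) and radii; matched to the PDB by atom order, either
#'   over all atoms or over the protein atoms alone.
#' @param reference `"geometry"` (default) takes the unweighted mean of the
#'   ligand atoms as its reference point; `"mass"` uses the mass-weighted
#'   centre.
#' @param dt Frame spacing in femtoseconds (default 2).
#' @return A list with elements `frames` (protein [frame_set()], ligand
#'   excluded), `ligand` ([ligand_trajectory()] of reference points) and
#'   `ligand_atoms` (a `frame_set` of the ligand's own atoms).
#' @export
load_frameset <- function(trajectory_path, ligand_selector,
                          charges_path = NULL,
                          reference = c("geometry", "mass"), dt = 2) {
  reference <- match.arg(reference)
  if (!file.exists(trajectory_path))
    abort(paste0("trajectory file not found: ", trajectory_path))
  pdb <- tryCatch(
    bio3d::read.pdb(trajectory_path, multi = TRUE, verbose = FALSE),
    error = function(e) abort(paste0("cannot parse PDB '", trajectory_path,
                                     "': ", conditionMessage(e)))
  )
  atoms <- pdb_atoms(pdb)
  nf <- nrow(pdb$xyz)
  na <- nrow(atoms)

  lig_idx <- match_ligand(atoms, ligand_selector)
  prot_idx <- setdiff(seq_len(na), lig_idx)
  if (length(prot_idx) == 0) abort("no protein atoms left after removing the ligand")

  if (!is.null(charges_path)) {
    chg <- read_pqr_charges(charges_path)
    if (nrow(chg) == na) {
      atoms$charge <- chg$charge
      atoms$radius <- chg$radius
    } else if (nrow(chg) == length(prot_idx)) {
      atoms$charge[prot_idx] <- chg$charge
      atoms$radius[prot_idx] <- chg$radius
    } else {
      abort(paste0("PQR atom count (", nrow(chg),
                   ") matches neither all atoms (", na,
                   ") nor protein atoms (", length(prot_idx), ")"))
    }
  }

  coords_all <- lapply(seq_len(nf), function(i) {
    matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
  })

  frames <- frame_set(atoms[prot_idx, ],
                      lapply(coords_all, function(m) m[prot_idx, , drop = FALSE]),
                      dt = dt)
  lig_atoms <- frame_set(atoms[lig_idx, ],
                         lapply(coords_all, function(m) m[lig_idx, , drop = FALSE]),
                         dt = dt)
  ligand <- ligand_trajectory(
    t(vapply(lig_atoms$coords, function(m) reference_point(m, lig_atoms$atoms$element, reference),
             numeric(3))))
  list(frames = frames, ligand = ligand, ligand_atoms = lig_atoms)
}

# ligand reference point from its atom coordinates
reference_point <- function(m, elements, reference = "geometry") {
  if (reference == "mass") {
    w <- atomic_mass(elements)
    colSums(m * w) / sum(w)
  } else {
    colMeans(m)
  }
}

pdb_atoms <- function(pdb) {
  a <- pdb$atom
  element <- a$elesy
  fallback <- is.na(element) | trimws(element) == ""
  if (any(fallback)) element[fallback] <- element_from_name(a$elety[fallback])
  tibble(
    name = a$elety, element = toupper(trimws(element)),
    resname = a$resid, resid = as.integer(a$resno),
    chain = ifelse(is.na(a$chain), "A", a$chain),
    charge = NA_real_, radius = vdw_radius(element)
  )
}

# derive the element symbol from an atom name: strip digits/primes, take the
# leading letter (two letters only for halogens spelled out, e.g. CL1)
element_from_name <- function(name) {
  core <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(core, 1, 2)
  ifelse(two %in% c("CL", "BR"), two, substr(core, 1, 1))
}

match_ligand <- function(atoms, selector) {
  keys <- paste0(atoms$chain, ":", atoms$resid)
  if (grepl(":", selector, fixed = TRUE)) {
    idx <- which(keys == selector)
  } else {
    idx <- which(atoms$resname == selector)
  }
  if (length(idx) == 0)
    abort(paste0("ligand selector '", selector, "' matches no residue"))
  n_res <- length(unique(keys[idx]))
  if (n_res > 1)
    abort(paste0("ligand selector '", selector, "' matches ", n_res,
                 " residues; it must match exactly one"))
  idx
}

read_pqr_charges <- function(path) {
  if (!file.exists(path)) abort(paste0("PQR file not found: ", path))
  pqr <- tryCatch(bio3d::read.pqr(path),
                  error = function(e) abort(paste0("cannot parse PQR '", path,
                                                   "': ", conditionMessage(e))))
  tibble(charge = as.numeric(pqr$atom$o), radius = as.numeric(pqr$atom$b))
}

#' Load a tunnel sphere profile
#'
#' Reads a CAVER-style CSV of tunnel spheres with the required header
#' `frame,x,y,z,r`. Frames with no spheres are allowed (they are simply
#' absent from the table).
#'
#' @param path Path to the CSV file.
#' @return A [tunnel_profile()] with source `"imported"`.
#' @export
load_tunnel_profile <- function(path) {
  if (!file.exists(path)) abort(paste0("tunnel file not found: ", path))
  tab <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_double())))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0)
    abort(paste0("non-numeric cell in tunnel CSV at row ", probs$row[1],
                 ", column ", probs$col[1]))
  req <- c("frame", "x", "y", "z", "r")
  if (!all(req %in% names(tab)))
    abort("tunnel CSV must have header frame,x,y,z,r")
  tunnel_profile(tab, source = "imported")
}

#' Load an active-site specification
#'
#' Reads a YAML or JSON file containing a list of `{chain, resid}` records
#' identifying the residues that define the active site.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [active_site_spec()].
#' @export
load_active_site <- function(path) {
  if (!file.exists(path)) abort(paste0("active-site file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    abort("active-site spec must be a .yaml/.yml or .json file")
  }
  if (is.data.frame(raw)) {
    residues <- raw
  } else {
    residues <- purrr::map_dfr(raw, function(r) {
      tibble(chain = as.character(r$chain %||% "A"), resid = as.integer(r$resid))
    })
  }
  active_site_spec(residues)
}

#' Write an attribute table
#'
#' One row per time step, columns: time index, every derived attribute, and
#' the positional category. CSV preserves full double precision; JSON writes
#' one record per step.
#'
#' @param table An attribute table from [derive_attributes()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_attribute_table <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(table) || nrow(table) == 0)
    abort("attribute table must be a non-empty data frame")
  if (format == "csv") {
    readr::write_csv(table, path)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read an attribute table written by [write_attribute_table()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return A tibble.
#' @export
read_attribute_table <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
}

#' Write a ligand trajectory
#'
#' Writes either a multi-model PDB with a single pseudo-atom per frame, or
#' a plain CSV with one `step,x,y,z` row per point.
#'
#' @param traj A [ligand_trajectory()].
#' @param path Output file path.
#' @param format `"pdb"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "csv")) {
  format <- match.arg(format)
  m <- traj_matrix(traj)
  if (format == "csv") {
    readr::write_csv(tibble(step = traj$step, x = m[, 1], y = m[, 2], z = m[, 3]),
                     path)
  } else {
    bio3d::write.pdb(file = path, xyz = m, resno = 1L, resid = "LIG",
                     elety = "C1", chain = "A")
  }
  invisible(path)
}

#' Write a frame set (plus optional ligand) as a multi-model PDB
#'
#' @param frames A [frame_set()].
#' @param path Output path.
#' @param ligand_atoms Optional `frame_set` of ligand atoms appended after
#'   the protein atoms in every MODEL.
#' @return `path`, invisibly.
#' @export
write_frameset_pdb <- function(frames, path, ligand_atoms = NULL) {
  atoms <- frames$atoms
  nf <- frames$n_frames
  get_xyz <- function(f) {
    m <- frame_coords(frames, f)
    if (!is.null(ligand_atoms)) m <- rbind(m, frame_coords(ligand_atoms, f))
    as.vector(t(m))
  }
  if (!is.null(ligand_atoms)) atoms <- bind_rows(atoms, ligand_atoms$atoms)
  xyz <- t(vapply(0:(nf - 1), get_xyz, numeric(3 * nrow(atoms))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = atoms$resid, resid = atoms$resname,
                   elety = atoms$name, chain = atoms$chain)
  invisible(path)
}

#' Write a PQR file carrying per-atom charges and radii
#'
#' Single-model PQR using the occupancy column for the partial charge and
#' the B column for the radius, matching the loader's convention.
#'
#' @param frames A [frame_set()] whose atoms carry a `charge` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(frames, path) {
  atoms <- frames$atoms
  chg <- ifelse(is.na(atoms$charge), 0, atoms$charge)
  m <- frame_coords(frames, 0)
  bio3d::write.pqr(file = path, xyz = as.vector(t(m)),
                   resno = atoms$resid, resid = atoms$resname,
                   elety = atoms$name, chain = atoms$chain,
                   o = chg, b = atoms$radius)
  invisible(path)
}

#' Write an active-site specification as YAML
#'
#' @param spec An [active_site_spec()].
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_active_site <- function(spec, path) {
  recs <- purrr::pmap(list(spec$chain, spec$resid),
                      function(ch, rs) list(chain = ch, resid = rs))
  yaml::write_yaml(recs, path)
  invisible(path)
}
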