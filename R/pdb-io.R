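# PDB reading/writing sits on bio3d; this file adapts its atom table to the
# package's tibble containers, resolves altlocs, and verifies trajectory
# topology (bio3d does not diagnose mismatched MODEL blocks itself).

.water_resnames <- c("HOH", "WAT", "TIP", "TIP3", "SOL")

# Resolve alternate locations: keep, per (chain, resno, resname, atom name),
# the record with the highest occupancy; ties keep the first record.
resolve_altloc_idx <- function(atom) {
  key <- paste(atom$chain, atom$resno, atom$resid, atom$elety, sep = "|")
  occ <- atom$o
  occ[is.na(occ)] <- 1
  keep <- tapply(seq_len(nrow(atom)), key, function(i) i[which.max(occ[i])])
  sort(unlist(keep, use.names = FALSE))
}

# Convert a (filtered) bio3d atom table + one xyz row into a complex_model.
bio3d_atoms_to_tibble <- function(atom) {
  element <- toupper(trimws(ifelse(is.na(atom$elesy), "", atom$elesy)))
  blank <- element == ""
  element[blank] <- infer_element(atom$elety[blank])
  tibble(
    serial = atom$eleno,
    name = atom$elety,
    element = element,
    resno = atom$resno,
    resname = atom$resid,
    chain = atom$chain,
    x = atom$x, y = atom$y, z = atom$z
  )
}

read_pdb_bio3d <- function(path, multi = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read PDB file: '%s' does not exist", path),
          class = "mdcontact_io_error")
  }
  p <- tryCatch(
    suppressWarnings(
      bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
    ),
    error = function(e) {
      abort(sprintf("failed to parse PDB file '%s': %s", path,
                    conditionMessage(e)),
            class = "mdcontact_io_error")
    }
  )
  if (is.null(p$atom) || nrow(p$atom) == 0) {
    abort(sprintf("empty structure: no ATOM records in '%s'", path),
          class = "mdcontact_empty_structure")
  }
  p
}

filter_bio3d_atoms <- function(atom, keep_hetatm = FALSE) {
  keep <- atom$type == "ATOM" | (keep_hetatm & atom$type == "HETATM")
  keep <- keep & !(atom$resid %in% .water_resnames)
  atom_kept <- atom[keep, , drop = FALSE]
  if (nrow(atom_kept) == 0) {
    abort("empty structure: no polymer ATOM records after filtering",
          class = "mdcontact_empty_structure")
  }
  idx <- resolve_altloc_idx(atom_kept)
  list(atom = atom_kept[idx, , drop = FALSE],
       xyz_idx = which(keep)[idx])
}

#' Read a single-model PDB file
#'
#' Parses ATOM records (fixed-column PDB convention, via bio3d) into a
#' [as_complex_model()] tibble. Alternate locations are resolved by keeping
#' the highest-occupancy record (ties keep the first); waters and, by
#' default, all other HETATM records are excluded. Elements come from the
#' PDB element column when present, otherwise from the atom name.
#'
#' @param path Path to a PDB file.
#' @param model_id Model label; defaults to the file name without extension.
#' @param keep_hetatm Keep non-water HETATM records? Default `FALSE`.
#' @return A `complex_model` tibble.
#' @export
read_pdb <- function(path, model_id = NULL, keep_hetatm = FALSE) {
  p <- read_pdb_bio3d(path, multi = FALSE)
  f <- filter_bio3d_atoms(p$atom, keep_hetatm = keep_hetatm)
  if (is.null(model_id)) model_id <- sub("\\.[^.]*$", "", basename(path))
  as_complex_model(bio3d_atoms_to_tibble(f$atom), model_id = model_id)
}

# topology signature lines for each MODEL block, from the raw file text;
# columns 13-27 cover atom name, altloc, residue name, chain and residue
# number. Used only to diagnose per-frame topology mismatches.
frame_keys_from_lines <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) return(NULL)
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    rec <- block[grepl("^(ATOM  |HETATM)", block)]
    substr(rec, 13, 27)
  })
}

#' Read a multi-model PDB trajectory
#'
#' Reads a trajectory stored as a multi-model PDB file (MODEL/ENDMDL blocks)
#' into an `md_trajectory`: a long tibble with one row per atom per frame and
#' a `frame` column, carrying `replicate_id` and `topology_key` attributes.
#' Every frame must share an identical atom topology; the first offending
#' frame is named in the error otherwise.
#'
#' @param path Path to a (multi-model) PDB file.
#' @param replicate_id Replicate label; defaults to the file name without
#'   extension.
#' @param keep_hetatm Keep non-water HETATM records? Default `FALSE`.
#' @return An `md_trajectory` tibble.
#' @export
read_trajectory <- function(path, replicate_id = NULL, keep_hetatm = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read PDB file: '%s' does not exist", path),
          class = "mdcontact_io_error")
  }
  keys <- frame_keys_from_lines(readLines(path, warn = FALSE))
  if (!is.null(keys) && length(keys) > 1) {
    ref <- keys[[1]]
    for (i in seq_along(keys)[-1]) {
      if (!identical(keys[[i]], ref)) {
        abort(sprintf(
          "topology mismatch at frame %d of '%s' (expected %d atoms matching frame 1, found %d or differing records)",
          i, path, length(ref), length(keys[[i]])
        ), class = "mdcontact_topology_error")
      }
    }
  }
  p <- read_pdb_bio3d(path, multi = TRUE)
  f <- filter_bio3d_atoms(p$atom, keep_hetatm = keep_hetatm)
  topo <- bio3d_atoms_to_tibble(f$atom)
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_fr <- nrow(xyz)
  cols <- as.vector(rbind(3 * f$xyz_idx - 2, 3 * f$xyz_idx - 1, 3 * f$xyz_idx))
  xyz <- xyz[, cols, drop = FALSE]
  if (is.null(replicate_id)) {
    replicate_id <- sub("\\.[^.]*$", "", basename(path))
  }
  frames <- lapply(seq_len(n_fr), function(i) {
    fr <- topo
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    fr$x <- m[, 1]; fr$y <- m[, 2]; fr$z <- m[, 3]
    fr$frame <- i
    fr
  })
  new_trajectory(dplyr::bind_rows(frames), replicate_id = replicate_id)
}

new_trajectory <- function(atoms, replicate_id) {
  atoms <- as_tibble(atoms)
  frame <- atoms$frame
  validated <- as_tibble(as_complex_model(atoms, model_id = replicate_id))
  validated$frame <- frame
  atoms <- validated
  key <- with(atoms[atoms$frame == atoms$frame[1], ],
              paste(chain, resno, resname, name, sep = "|"))
  structure(as_tibble(atoms),
    replicate_id = replicate_id,
    topology_key = key,
    class = c("md_trajectory", class(tibble())))
}

#' Trajectory accessors
#'
#' @param traj An `md_trajectory`.
#' @param i Frame index (1-based, file order).
#' @return `n_frames()` the number of frames; `replicate_id()` the replicate
#'   label; `topology_key()` the canonical per-atom
#'   `chain|resno|resname|name` strings; `get_frame()` one frame as a
#'   `complex_model`.
#' @export
n_frames <- function(traj) max(traj$frame)

#' @rdname n_frames
#' @export
replicate_id <- function(traj) attr(traj, "replicate_id")

#' @rdname n_frames
#' @export
topology_key <- function(traj) attr(traj, "topology_key")

#' @rdname n_frames
#' @export
get_frame <- function(traj, i) {
  fr <- as_tibble(traj)[traj$frame == i, model_cols]
  if (nrow(fr) == 0) abort(sprintf("no frame %s in trajectory", i))
  as_complex_model(fr, model_id = sprintf("%s_frame%d", replicate_id(traj), i))
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "<md_trajectory '%s'> %d frames x %d atoms, chains: %s\n",
    replicate_id(x), n_frames(x), sum(x$frame == x$frame[1]),
    paste(sort(unique(x$chain)), collapse = ", ")
  ))
  NextMethod()
}

write_pdb_atoms <- function(atoms, xyz, path) {
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = rep("ATOM", nrow(atoms)),
    eleno = atoms$serial,
    elety = atoms$name,
    resid = atoms$resname,
    chain = atoms$chain,
    resno = atoms$resno,
    o = rep(1, nrow(atoms)),
    b = rep(0, nrow(atoms)),
    elesy = atoms$element
  )
  invisible(path)
}

#' Write models and trajectories as (multi-model) PDB
#'
#' Coordinates are serialised at the standard 3-decimal PDB precision;
#' trajectories are written as MODEL/ENDMDL blocks in frame order, so that
#' generated fixtures round-trip through [read_pdb()]/[read_trajectory()].
#'
#' @param model A `complex_model`.
#' @param traj An `md_trajectory`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_pdb <- function(model, path) {
  write_pdb_atoms(model, as.vector(t(xyz_matrix(model))), path)
}

#' @rdname write_pdb
#' @export
write_trajectory <- function(traj, path) {
  fr1 <- as_tibble(traj)[traj$frame == 1, ]
  ord <- order(traj$frame)
  xyz <- matrix(as.vector(t(xyz_matrix(as_tibble(traj)[ord, ]))),
                nrow = n_frames(traj), byrow = TRUE)
  write_pdb_atoms(fr1, xyz, path)
}
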