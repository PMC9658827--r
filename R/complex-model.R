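# Atomic masses (Da) for the elements the package resolves. Unknown elements
# are a hard error: every distance statistic downstream is mass-weighted.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, P = 30.974, SE = 78.971
)

#' Atomic mass lookup
#'
#' Resolves element symbols against the package's internal element-mass table
#' (H, C, N, O, S, P, Se).
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of masses in daltons.
#' @examples
#' element_mass(c("C", "N", "O"))
#' @export
element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  unname(m)
}

# Infer an element symbol from a PDB atom name, used when the element column
# is blank. Leading digits (e.g. "1HB") are stripped; two-letter elements in
# the mass table ("SE") are preferred over their first letter.
infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% names(.element_masses), two, one)
}

model_cols <- c(
  "serial", "name", "element", "resno", "resname", "chain",
  "x", "y", "z", "mass", "is_hydrogen"
)

#' Build a two-chain complex model from an atom table
#'
#' A `complex_model` is a tibble of atoms (one row per atom) carrying the
#' columns `serial`, `name`, `element`, `resno`, `resname`, `chain`, `x`,
#' `y`, `z`, `mass` and `is_hydrogen`, plus a `model_id` attribute. Masses
#' and the hydrogen flag are filled in from the element column when missing.
#'
#' @param atoms Data frame of atom records with at least `name`, `element`,
#'   `resno`, `resname`, `chain` and Cartesian coordinates `x`, `y`, `z`
#'   in Angstroms.
#' @param model_id Label for the model (string or integer).
#' @return A `complex_model` tibble.
#' @examples
#' atoms <- tibble::tibble(
#'   name = c("N", "O"), element = c("N", "O"),
#'   resno = c(1, 2), resname = "GLY", chain = c("A", "B"),
#'   x = c(0, 2.9), y = 0, z = 0
#' )
#' as_complex_model(atoms, model_id = "demo")
#' @export
as_complex_model <- function(atoms, model_id = "model") {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0) {
    abort("empty structure: no atoms", class = "mdcontact_empty_structure")
  }
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  atoms$element <- toupper(atoms$element)
  unknown <- !(atoms$element %in% names(.element_masses))
  if (any(unknown)) {
    i <- which(unknown)[1]
    abort(
      sprintf(
        "cannot resolve element for atom serial %s (name '%s', element '%s')",
        atoms$serial[i], atoms$name[i], atoms$element[i]
      ),
      class = "mdcontact_element_error"
    )
  }
  atoms$mass <- element_mass(atoms$element)
  atoms$is_hydrogen <- atoms$element == "H"
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    abort(sprintf(
      "non-finite coordinates for atom serial %s", atoms$serial[which(bad)[1]]
    ))
  }
  atoms <- atoms[, model_cols]
  structure(atoms,
    model_id = model_id,
    class = c("complex_model", class(tibble())))
}

#' @export
print.complex_model <- function(x, ...) {
  heavy <- sum(!x$is_hydrogen)
  cat(sprintf(
    "<complex_model '%s'> %d atoms (%d heavy), %d residues, chains: %s\n",
    model_id(x), nrow(x), heavy,
    nrow(dplyr::distinct(as_tibble(x)[, c("chain", "resno")])),
    paste(chain_ids(x), collapse = ", ")
  ))
  NextMethod()
}

#' Model and chain accessors
#'
#' @param model A `complex_model`.
#' @return `model_id()` returns the model label; `chain_ids()` the sorted
#'   distinct chain identifiers.
#' @export
model_id <- function(model) attr(model, "model_id")

#' @rdname model_id
#' @export
chain_ids <- function(model) sort(unique(model$chain))

assert_two_chains <- function(model) {
  ch <- chain_ids(model)
  if (length(ch) != 2) {
    abort(
      sprintf("expected exactly 2 chains, found %d (%s)",
              length(ch), paste(ch, collapse = ", ")),
      class = "mdcontact_chain_error"
    )
  }
  ch
}

#' Residue label in the conventional RESNAME+number form
#'
#' @param resname 3-letter residue names.
#' @param resno Residue numbers (author numbering).
#' @return Character vector such as `"GLY256"`.
#' @examples
#' residue_label("GLY", 256)
#' @export
residue_label <- function(resname, resno) {
  paste0(toupper(resname), resno)
}

#' Apply a rigid-body transform to a model or trajectory
#'
#' Rotates every atom by `rotation` and then translates by `translation`.
#' All interface, hydrogen-bond and contact statistics in this package are
#' invariant under such transforms, which the test-suite asserts.
#'
#' @param x A `complex_model` or `md_trajectory`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric translation vector (Angstroms).
#' @return Object of the same class with transformed coordinates.
#' @export
transform_coords <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- xyz_matrix(x) %*% t(rotation)
  x$x <- xyz[, 1] + translation[1]
  x$y <- xyz[, 2] + translation[2]
  x$z <- xyz[, 3] + translation[3]
  x
}
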