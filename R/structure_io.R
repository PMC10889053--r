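#' @keywords internal
"_PACKAGE"

# Elements the featurization scheme knows about, with Pauling electronegativities
# (used by the default hyperedge orientation rule).
.PTHL_ELECTRONEGATIVITY <- c(
  H = 2.20, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
  P = 2.19, S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66
)

.PROTEIN_ELEMENTS <- c("C", "N", "O", "S")
.LIGAND_ELEMENTS  <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
.WATER_RESIDUES   <- c("HOH", "WAT", "DOD", "H2O", "SOL", "TIP", "TIP3", "TIP4")

#' Normalize a chemical element symbol
#'
#' Upper-cases the first letter and lower-cases the rest, after stripping
#' whitespace, digits and SYBYL atom-type suffixes (`"C.3"` -> `"C"`,
#' `"CL"` -> `"Cl"`).
#'
#' @param x Character vector of raw element symbols or atom types.
#' @return Character vector of normalized symbols (`""` where empty).
#' @export
normalize_element <- function(x) {
  x <- sub("\\..*$", "", trimws(as.character(x)))
  x <- gsub("[0-9+-]", "", x)
  bad <- is.na(x) | x == ""
  x[bad] <- ""
  ok <- !bad
  x[ok] <- paste0(toupper(substr(x[ok], 1, 1)),
                  tolower(substr(x[ok], 2, nchar(x[ok]))))
  x
}

# Internal: canonical atom table used everywhere downstream.
atom_table <- function(element, x, y, z, origin) {
  n <- length(element)
  df <- data.frame(
    element = normalize_element(element),
    x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
    z = rep_len(as.numeric(z), n),
    origin = rep_len(origin, n),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("non-finite atomic coordinates")
  rownames(df) <- NULL
  df
}

#' Atom coordinates as a matrix
#'
#' @param atoms Atom table (as returned by [read_protein()], [read_ligand()],
#'   or found in a region / complex).
#' @return Numeric n x 3 matrix of coordinates in Angstrom.
#' @export
atom_coords <- function(atoms) {
  unname(as.matrix(atoms[, c("x", "y", "z")]))
}

#' Read protein heavy atoms from a PDB file
#'
#' Parses a PDB file (via bio3d), keeps heavy atoms only: hydrogens and
#' deuteriums are dropped, water residues are dropped, the first alternate
#' location is kept, and only the first model of multi-model files is used.
#' `HETATM` records are retained when their element belongs to the protein
#' scheme (C, N, O, S), so modified residues survive; ions and cofactors made
#' of other elements do not.
#'
#' @param path Path to a PDB file.
#' @return Atom table (`element`, `x`, `y`, `z`, `origin = "protein"`).
#' @export
read_protein <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no atom records in ", path)
  elem <- normalize_element(at$elesy)
  # fall back on the atom-name column where the element column is absent
  miss <- elem == ""
  if (any(miss)) elem[miss] <- normalize_element(sub("^[0-9']+", "", at$elety[miss]))
  keep <- !(elem %in% c("H", "D")) &
    !(toupper(trimws(at$resid)) %in% .WATER_RESIDUES)
  keep <- keep & (at$type == "ATOM" | elem %in% .PROTEIN_ELEMENTS)
  if (!any(keep)) stop("no heavy atoms found in ", path)
  atom_table(elem[keep], at$x[keep], at$y[keep], at$z[keep], "protein")
}

#' Read ligand heavy atoms from an SDF or MOL2 file
#'
#' Format is inferred from the file extension unless given. Hydrogens are
#' dropped and element symbols normalized (SYBYL types such as `"C.3"` map to
#' `"C"`, `"CL"` to `"Cl"`). All nine heavy elements of the ligand scheme
#' (C, N, O, S, P, F, Cl, Br, I) are retained, as is any other heavy element
#' present in the file.
#'
#' @param path Path to an `.sdf`/`.mol` or `.mol2` file.
#' @param format One of `"auto"`, `"sdf"`, `"mol2"`.
#' @return Atom table with `origin = "ligand"`.
#' @export
read_ligand <- function(path, format = c("auto", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read ligand file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      sdf = "sdf", mol = "sdf", mol2 = "mol2",
      stop("cannot infer ligand format from extension '.", ext,
           "'; pass format = \"sdf\" or \"mol2\"")
    )
  }
  if (format == "sdf") {
    sdf <- withCallingHandlers(
      ChemmineR::read.SDFset(path),
      warning = function(w) {
        # bond-free minimal SDFs are flagged invalid; only atoms are consumed
        if (grepl("invalid SDF", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }
    )
    ab <- ChemmineR::atomblock(sdf[[1]])
    elem <- normalize_element(sub("_.*$", "", rownames(ab)))
    xyz <- ab[, 1:3, drop = FALSE]
  } else {
    mol <- suppressWarnings(bio3d::read.mol2(path))
    at <- mol$atom
    elem <- normalize_element(at$elety)
    xyz <- cbind(at$x, at$y, at$z)
  }
  keep <- !(elem %in% c("H", "D", ""))
  if (!any(keep)) stop("no heavy atoms found in ", path)
  atom_table(elem[keep], xyz[keep, 1], xyz[keep, 2], xyz[keep, 3], "ligand")
}

#' Assemble a protein-ligand complex
#'
#' @param identifier Character id for the complex (e.g. a PDB code).
#' @param protein_atoms Atom table with origin `"protein"`.
#' @param ligand_atoms Atom table with origin `"ligand"` (at least one atom).
#' @return An object of class `"molecular_complex"`.
#' @export
molecular_complex <- function(identifier, protein_atoms, ligand_atoms) {
  stopifnot(is.character(identifier), length(identifier) == 1)
  if (nrow(ligand_atoms) < 1) stop("complex must contain at least one ligand atom")
  if (nrow(protein_atoms) > 0 && !all(protein_atoms$origin == "protein"))
    stop("protein_atoms must all have origin 'protein'")
  if (!all(ligand_atoms$origin == "ligand"))
    stop("ligand_atoms must all have origin 'ligand'")
  structure(
    list(identifier = identifier,
         protein_atoms = protein_atoms,
         ligand_atoms = ligand_atoms),
    class = "molecular_complex"
  )
}

#' @export
print.molecular_complex <- function(x, ...) {
  cat("<molecular_complex> ", x$identifier, ": ",
      nrow(x$protein_atoms), " protein / ",
      nrow(x$ligand_atoms), " ligand heavy atoms\n", sep = "")
  invisible(x)
}

#' Extract the protein-ligand interaction region
#'
#' Keeps every ligand heavy atom together with exactly those protein atoms
#' whose minimum Euclidean distance to any ligand atom is `<= cutoff`
#' (closed threshold). The two preset analysis domains use 20 A and 12 A.
#'
#' @param complex A [molecular_complex()], or an existing region (idempotent).
#' @param cutoff Positive distance cutoff in Angstrom.
#' @return Object of class `"complex_region"`: list with `atoms`, `cutoff`,
#'   `source_id`.
#' @export
extract_region <- function(complex, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  if (inherits(complex, "complex_region")) {
    atoms <- complex$atoms
    complex <- molecular_complex(
      complex$source_id,
      atoms[atoms$origin == "protein", , drop = FALSE],
      atoms[atoms$origin == "ligand", , drop = FALSE]
    )
  }
  stopifnot(inherits(complex, "molecular_complex"))
  lig <- complex$ligand_atoms
  pro <- complex$protein_atoms
  if (nrow(pro) > 0) {
    dmin <- min_cross_distance(atom_coords(pro), atom_coords(lig))
    pro <- pro[dmin <= cutoff, , drop = FALSE]
  }
  if (nrow(pro) == 0)
    warning("no protein atom within ", cutoff, " A of the ligand; ",
            "region contains the ligand only")
  atoms <- rbind(pro, lig)
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, cutoff = cutoff, source_id = complex$identifier),
    class = "complex_region"
  )
}

#' @export
print.complex_region <- function(x, ...) {
  cat("<complex_region> ", x$source_id, " @ ", x$cutoff, " A: ",
      sum(x$atoms$origin == "protein"), " protein + ",
      sum(x$atoms$origin == "ligand"), " ligand atoms\n", sep = "")
  invisible(x)
}

# Minimum distance from each row of `a` to any row of `b`.
min_cross_distance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  sqrt(pmax(apply(d2, 1, min), 0))
}
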