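# Seeded synthetic-data generators: canonical point shapes with known Betti
# numbers, random clouds, synthetic protein-ligand complexes written to
# minimal PDB/SDF, and benchmark tables with known ground truth.

#' Canonical point shapes with reference Betti numbers
#'
#' Small analytic point sets used as topology oracles. Each shape comes with
#' a reference filtration threshold and the Betti numbers `(b0, b1)` of its
#' Vietoris-Rips complex at that threshold (with `max_dim` as stated).
#'
#' @param name One of `"pair"`, `"path3"`, `"triangle"`, `"filled_triangle"`,
#'   `"circle_8"`, `"tetrahedron"`, `"two_clusters"`.
#' @param scale Edge length scale in Angstrom.
#' @return List with `points` (n x 3 matrix), `eta` (reference threshold),
#'   `max_dim`, and `betti` (named vector `b0`, `b1`).
#' @export
canonical_shape <- function(name = c("pair", "path3", "triangle",
                                     "filled_triangle", "circle_8",
                                     "tetrahedron", "two_clusters"),
                            scale = 1) {
  name <- match.arg(name)
  z <- function(m) cbind(m, 0)
  # reference thresholds sit exactly on an edge length; a hair of relative
  # margin keeps the closed threshold robust to coordinate roundoff (the
  # nearest excluded pairwise distance is far larger in every shape)
  nudge <- function(e) e * (1 + 1e-9)
  switch(name,
    pair = list(
      points = z(rbind(c(0, 0), c(scale, 0))),
      eta = scale / 2, max_dim = 1, betti = c(b0 = 2, b1 = 0)
    ),
    path3 = list(
      points = z(rbind(c(0, 0), c(scale, 0), c(2 * scale, 0))),
      eta = nudge(scale), max_dim = 1, betti = c(b0 = 1, b1 = 0)
    ),
    triangle = list(
      points = z(scale * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))),
      eta = nudge(scale), max_dim = 1, betti = c(b0 = 1, b1 = 1)
    ),
    filled_triangle = list(
      points = z(scale * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))),
      eta = nudge(scale), max_dim = 2, betti = c(b0 = 1, b1 = 0)
    ),
    circle_8 = {
      th <- 2 * pi * (0:7) / 8
      r <- scale
      list(
        points = z(r * cbind(cos(th), sin(th))),
        # adjacent chord length; diagonals are strictly longer
        eta = nudge(2 * r * sin(pi / 8)), max_dim = 1, betti = c(b0 = 1, b1 = 1)
      )
    },
    tetrahedron = list(
      # regular tetrahedron with edge length `scale`, 1-skeleton only:
      # b1 = |E| - |V| + 1 = 6 - 4 + 1 = 3
      points = (scale / (2 * sqrt(2))) * rbind(
        c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
      eta = nudge(scale), max_dim = 1, betti = c(b0 = 1, b1 = 3)
    ),
    two_clusters = list(
      # two collinear triads far apart: loop-free, two components
      points = z(rbind(
        cbind(scale * c(0, 1, 2), 0),
        cbind(10 * scale + scale * c(0, 1, 2), 0)
      )),
      eta = 1.5 * scale, max_dim = 1, betti = c(b0 = 2, b1 = 0)
    )
  )
}

#' Seeded random point cloud
#'
#' @param n Number of points.
#' @param box Box side length in Angstrom (points uniform in `[0, box]^3`).
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return n x 3 coordinate matrix.
#' @export
random_cloud <- function(n, box = 10, seed = 1) {
  stopifnot(n >= 0)
  withr_seed(seed)
  matrix(stats::runif(3 * n, 0, box), ncol = 3)
}

# Deterministic seeding for the generators (integer-state Mersenne twister).
withr_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  set.seed(as.integer(seed))
  invisible(NULL)
}

#' Generate a synthetic protein-ligand complex
#'
#' Places protein and ligand heavy atoms uniformly in a box (ligand atoms in
#' the central third so a binding region always exists), samples elements
#' from the requested alphabets, and optionally writes a minimal PDB (protein)
#' and SDF (ligand) pair that [read_protein()] / [read_ligand()] round-trip
#' exactly. Conformations are not physically realistic; only geometry and
#' composition are emulated.
#'
#' @param n_protein,n_ligand Atom counts (`>= 1`).
#' @param protein_elements Elements sampled for the protein (subset of
#'   C, N, O, S), or a length-`n_protein` vector taken verbatim.
#' @param ligand_elements Elements sampled for the ligand (subset of the
#'   9-element ligand scheme), or a length-`n_ligand` vector taken verbatim.
#' @param box Box side length in Angstrom.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, `protein.pdb` and `ligand.sdf`
#'   are written there.
#' @return A [molecular_complex()]; when `dir` is given, with attribute
#'   `"files"` (named paths).
#' @export
synthetic_complex <- function(n_protein, n_ligand,
                              protein_elements = .PROTEIN_ELEMENTS,
                              ligand_elements = .LIGAND_ELEMENTS,
                              box = 20, seed = 1, dir = NULL) {
  stopifnot(n_protein >= 1, n_ligand >= 1)
  withr_seed(seed)
  pe <- if (length(protein_elements) == n_protein) protein_elements
        else sample(protein_elements, n_protein, replace = TRUE)
  le <- if (length(ligand_elements) == n_ligand) ligand_elements
        else sample(ligand_elements, n_ligand, replace = TRUE)
  pxyz <- matrix(stats::runif(3 * n_protein, 0, box), ncol = 3)
  lxyz <- matrix(stats::runif(3 * n_ligand, box / 3, 2 * box / 3), ncol = 3)
  cx <- molecular_complex(
    sprintf("synthetic-%d", seed),
    atom_table(pe, pxyz[, 1], pxyz[, 2], pxyz[, 3], "protein"),
    atom_table(le, lxyz[, 1], lxyz[, 2], lxyz[, 3], "ligand")
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(protein = file.path(dir, "protein.pdb"),
               ligand = file.path(dir, "ligand.sdf"))
    write_pdb(cx$protein_atoms, files[["protein"]])
    write_sdf(cx$ligand_atoms, files[["ligand"]], title = cx$identifier)
    attr(cx, "files") <- files
  }
  cx
}

#' Write atoms as a minimal PDB file
#'
#' Emits only `ATOM` records (with the element column populated) and `END`:
#' the smallest dialect common parsers accept. Coordinates are written at
#' PDB precision (0.001 A).
#'
#' @param atoms Atom table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    el <- atoms$element[i]
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, substr(paste0(el, i), 1, 4), "", "GLY", "A", i,
            atoms$x[i], atoms$y[i], atoms$z[i], 1, 0, toupper(el))
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write atoms as a minimal SDF (V2000) file
#'
#' Atom block only (no bonds); coordinates at 0.0001 A precision.
#'
#' @param atoms Atom table.
#' @param path Output path.
#' @param title Molecule title line.
#' @return The path, invisibly.
#' @export
write_sdf <- function(atoms, path, title = "LIG") {
  n <- nrow(atoms)
  lines <- c(
    title, "  pthl", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0),
    vapply(seq_len(n), function(i) {
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i])
    }, character(1)),
    "M  END", "$$$$"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write atoms as a minimal MOL2 file
#'
#' TRIPOS `MOLECULE`/`ATOM` records only, with plain element atom types.
#'
#' @inheritParams write_sdf
#' @return The path, invisibly.
#' @export
write_mol2 <- function(atoms, path, title = "LIG") {
  n <- nrow(atoms)
  lines <- c(
    "@<TRIPOS>MOLECULE", title,
    sprintf(" %d 0 0 0 0", n), "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    vapply(seq_len(n), function(i) {
      sprintf("%7d %-8s%10.4f%10.4f%10.4f %-5s%4d  LIG1%14.4f",
              i, paste0(toupper(atoms$element[i]), i),
              atoms$x[i], atoms$y[i], atoms$z[i],
              atoms$element[i], 1, 0)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic benchmark tables with known ground truth
#'
#' Emulates the shape of CASF-style evaluation inputs: affinity clusters of
#' uniform size, ligands with scored poses (one sub-2-A native pose each),
#' and per-target candidate lists with a fixed number of true binders.
#' Predictions are the ground truth plus Gaussian noise of standard
#' deviation `noise`, so every metric has a computable expected value
#' (at `noise = 0` all powers are perfect).
#'
#' @param n_clusters,cluster_size Ranking table shape (e.g. 65 x 3 or 57 x 5).
#' @param n_ligands,n_poses Docking table shape (e.g. 195 ligands x 100 poses).
#' @param n_targets Screening targets; each gets `n_binders` true binders
#'   among `n_candidates` candidates.
#' @param n_binders,n_candidates Screening table shape (defaults 3 and 100).
#' @param noise Prediction noise standard deviation (affinity units).
#' @param seed Integer seed.
#' @return List with `clusters`, `poses`, `screens` data frames matching the
#'   evaluation-module CSV schemas.
#' @export
benchmark_tables <- function(n_clusters = 65, cluster_size = 3,
                             n_ligands = 20, n_poses = 100,
                             n_targets = 10, n_binders = 3,
                             n_candidates = 100, noise = 0, seed = 1) {
  stopifnot(n_clusters >= 1, cluster_size >= 2, n_ligands >= 1,
            n_poses >= 1, n_targets >= 1, n_binders >= 1,
            n_candidates >= n_binders)
  withr_seed(seed)

  # ranking clusters: distinct experimental affinities per cluster
  expt <- as.numeric(replicate(n_clusters,
            sort(stats::runif(cluster_size, 2, 12), decreasing = TRUE)))
  clusters <- data.frame(
    cluster_id = rep(seq_len(n_clusters), each = cluster_size),
    complex_id = sprintf("cpx-%03d-%d",
                         rep(seq_len(n_clusters), each = cluster_size),
                         rep(seq_len(cluster_size), n_clusters)),
    expt = expt,
    pred = expt + stats::rnorm(n_clusters * cluster_size, 0, noise)
  )

  # docking poses: pose 1 is native (RMSD < 2), the rest spread 0-10 A;
  # the true score decreases with RMSD, so noise-free scoring is perfect
  poses <- do.call(rbind, lapply(seq_len(n_ligands), function(lg) {
    rmsd <- c(stats::runif(1, 0, 1.8), stats::runif(n_poses - 1, 0, 10))
    score <- 10 - rmsd + stats::rnorm(n_poses, 0, noise)
    data.frame(ligand_id = sprintf("lig-%03d", lg),
               pose_id = seq_len(n_poses), rmsd = rmsd, score = score)
  }))

  # screening: per target, binders have the highest true affinity
  screens <- do.call(rbind, lapply(seq_len(n_targets), function(tg) {
    affinity <- stats::runif(n_candidates, 2, 10)
    is_binder <- logical(n_candidates)
    is_binder[order(affinity, decreasing = TRUE)[seq_len(n_binders)]] <- TRUE
    s1 <- affinity + stats::rnorm(n_candidates, 0, noise)
    s2 <- stats::plogis((affinity - stats::median(affinity)) / 2 +
                          stats::rnorm(n_candidates, 0, noise))
    data.frame(target_id = sprintf("tgt-%02d", tg),
               ligand_id = sprintf("lig-%03d", seq_len(n_candidates)),
               is_binder = is_binder, affinity = affinity,
               s1 = s1, s2 = s2)
  }))

  list(clusters = clusters, poses = poses, screens = screens)
}
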