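# Element-specific multiscale topological sequence embedding:
# filtration steps x 143 element combinations x 6 spectral statistics.

.PTHL_SCHEME_VERSION <- "pthl-es-11x13-1"

#' The element-specific combination scheme
#'
#' Protein atoms are described by 11 element sets over \{C, N, O, S\}
#' (4 singletons, 6 pairs, and the full set); ligand atoms by 13 sets over
#' the 9 ligand heavy elements (the 10 CNOS singletons and pairs, the
#' phosphorus/halogen group \{P, F, Cl, Br, I\}, its union with nitrogen, and
#' the full 9-element set). Their product gives the 143 protein-ligand
#' combinations, ordered protein-major: combination index
#' `(p - 1) * 13 + l` for protein set `p` and ligand set `l`.
#'
#' @return Object of class `"element_scheme"`: list with `protein` (11 sets),
#'   `ligand` (13 sets), `version`.
#' @export
element_scheme <- function() {
  protein <- list(
    "C", "N", "O", "S",
    c("C", "N"), c("C", "O"), c("C", "S"),
    c("N", "O"), c("N", "S"), c("O", "S"),
    c("C", "N", "O", "S")
  )
  ligand <- list(
    "C", "N", "O", "S",
    c("C", "N"), c("C", "O"), c("C", "S"),
    c("N", "O"), c("N", "S"), c("O", "S"),
    c("P", "F", "Cl", "Br", "I"),
    c("N", "P", "F", "Cl", "Br", "I"),
    c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  )
  structure(list(protein = protein, ligand = ligand,
                 version = .PTHL_SCHEME_VERSION),
            class = "element_scheme")
}

#' Labels for the element combinations
#'
#' @param scheme An [element_scheme()].
#' @return Character vector of length 143, protein-major order, e.g.
#'   `"protein:C|ligand:C"`.
#' @export
combo_labels <- function(scheme = element_scheme()) {
  out <- character(0)
  for (p in scheme$protein)
    for (l in scheme$ligand)
      out <- c(out, paste0("protein:", paste(p, collapse = ","),
                           "|ligand:", paste(l, collapse = ",")))
  out
}

#' Filtration schedule
#'
#' The grid follows the half-open convention `(start, stop]`: values
#' `start + i * step` for `i = 1..N` with `N = round((stop - start) / step)`,
#' which yields exactly 100 steps for 0 to 10 A at 0.1 A and 50 steps for 2
#' to 12 A at 0.2 A.
#'
#' @param start,stop,step Filtration range and increment in Angstrom.
#' @return Object of class `"filtration_schedule"`: list with `start`, `stop`,
#'   `step`, `grid`.
#' @export
filtration_schedule <- function(start, stop, step) {
  stopifnot(stop > start, step > 0)
  n <- round((stop - start) / step)
  grid <- start + seq_len(n) * step
  if (abs(grid[n] - stop) > 1e-9)
    stop("(stop - start) must be an integer multiple of step")
  structure(list(start = start, stop = stop, step = step, grid = grid),
            class = "filtration_schedule")
}

#' Analysis presets
#'
#' The large preset analyses protein atoms within 20 A of the ligand over a
#' filtration from 0 to 10 A in 0.1 A increments (topological sequence of
#' length 100); the small preset uses a 12 A cutoff and a 2 to 12 A filtration
#' in 0.2 A increments (length 50).
#'
#' @param name `"large"` or `"small"`.
#' @return List with `cutoff` (Angstrom) and `schedule`
#'   (a [filtration_schedule()]).
#' @export
preset <- function(name = c("large", "small")) {
  name <- match.arg(name)
  if (name == "large")
    list(name = "large", cutoff = 20,
         schedule = filtration_schedule(0, 10, 0.1))
  else
    list(name = "small", cutoff = 12,
         schedule = filtration_schedule(2, 12, 0.2))
}

#' Element-specific cross-distance matrix
#'
#' Restricts a region to the atoms whose element belongs to the active set on
#' their side (protein set for protein atoms, ligand set for ligand atoms)
#' and returns the pairwise distance matrix in which only protein-ligand
#' pairs carry their Euclidean distance; same-origin pairs and the diagonal
#' are `+Inf`, so that only cross interactions create topology.
#'
#' @param region A `"complex_region"`.
#' @param pset Character vector: active protein elements.
#' @param lset Character vector: active ligand elements.
#' @return List with `D` (m x m symmetric matrix), `origin` (length-m factor
#'   of `"protein"`/`"ligand"`), `atoms` (the selected atom rows).
#' @export
cross_distance_matrix <- function(region, pset, lset) {
  stopifnot(inherits(region, "complex_region"))
  a <- region$atoms
  sel <- (a$origin == "protein" & a$element %in% pset) |
         (a$origin == "ligand"  & a$element %in% lset)
  a <- a[sel, , drop = FALSE]
  m <- nrow(a)
  if (m == 0) {
    return(list(D = matrix(numeric(), 0, 0),
                origin = character(), atoms = a))
  }
  D <- as.matrix(stats::dist(atom_coords(a)))
  same <- outer(a$origin, a$origin, "==")
  D[same] <- Inf
  diag(D) <- Inf
  list(D = D, origin = a$origin, atoms = a)
}

# Graph Laplacian D - A of the threshold graph on a cross-distance matrix.
threshold_l0 <- function(D, d) {
  if (nrow(D) == 0) return(matrix(numeric(), 0, 0))
  A <- (D <= d) * 1
  diag(A) <- 0
  diag(rowSums(A), nrow = nrow(A)) - A
}

#' Embed a complex region as a topological sequence
#'
#' For every filtration value `d` in the schedule and every element
#' combination, the cross-distance threshold graph (edges where the
#' protein-ligand distance is `<= d`; this is the dimension-<=1
#' Vietoris-Rips hyperdigraph on the masked distance matrix, whose
#' 0-Laplacian is orientation-independent) is assembled and the six
#' spectral statistics of `L_0` are recorded, giving a tensor of shape
#' `(T, 143, 6)`. Combinations with no matching atoms yield all-zero rows.
#'
#' @param region A `"complex_region"` (see [extract_region()]).
#' @param schedule A [filtration_schedule()]; defaults to the preset matching
#'   a 12 A cutoff.
#' @param scheme An [element_scheme()].
#' @param zero_tol Relative zero threshold for the spectra.
#' @return Object of class `"topo_sequence"`: list with `tensor`
#'   (`T x 143 x 6` array), `schedule`, `cutoff`, `scheme_version`,
#'   `source_id`.
#' @export
embed_complex <- function(region, schedule = preset("small")$schedule,
                          scheme = element_scheme(), zero_tol = 1e-8) {
  stopifnot(inherits(region, "complex_region"),
            inherits(schedule, "filtration_schedule"))
  labels <- combo_labels(scheme)
  grid <- schedule$grid
  tensor <- array(0, dim = c(length(grid), length(labels), 6),
                  dimnames = list(NULL, labels, .SPECTRAL_STAT_NAMES))
  ci <- 0
  for (p in scheme$protein) {
    for (l in scheme$ligand) {
      ci <- ci + 1
      cdm <- cross_distance_matrix(region, p, l)
      if (nrow(cdm$D) == 0) next  # all-zero rows
      finite <- cdm$D[is.finite(cdm$D)]
      prev <- NULL
      for (t in seq_along(grid)) {
        # spectra only change when a new edge enters the threshold graph
        n_edges <- sum(finite <= grid[t]) / 2
        if (!is.null(prev) && prev$n_edges == n_edges) {
          tensor[t, ci, ] <- prev$stats
          next
        }
        L <- threshold_l0(cdm$D, grid[t])
        stats <- spectral_summary(laplacian_spectrum(L, zero_tol))
        tensor[t, ci, ] <- stats
        prev <- list(n_edges = n_edges, stats = stats)
      }
    }
  }
  structure(
    list(tensor = tensor, schedule = schedule, cutoff = region$cutoff,
         scheme_version = scheme$version, source_id = region$source_id),
    class = "topo_sequence"
  )
}

#' @export
print.topo_sequence <- function(x, ...) {
  d <- dim(x$tensor)
  cat("<topo_sequence> ", x$source_id, ": ", d[1], " steps x ", d[2],
      " combos x ", d[3], " stats (cutoff ", x$cutoff, " A, ",
      x$scheme_version, ")\n", sep = "")
  invisible(x)
}

#' Save a topological sequence
#'
#' Writes a JSON container with the flattened tensor (full-precision doubles,
#' so the round-trip through [load_sequence()] is bit-exact), the filtration
#' grid and the metadata (`cutoff`, `scheme_version`, `source_id`).
#'
#' @param seq A `"topo_sequence"`.
#' @param path Output path (conventionally `.json`).
#' @return The path, invisibly.
#' @export
save_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "topo_sequence"))
  obj <- list(
    format = "pthl-topo-sequence-1",
    dim = dim(seq$tensor),
    combos = dimnames(seq$tensor)[[2]],
    stats = dimnames(seq$tensor)[[3]],
    # 17 significant digits round-trip IEEE doubles exactly
    features = sprintf("%.17g", as.numeric(seq$tensor)),
    filtration = seq$schedule$grid,
    schedule = list(start = seq$schedule$start, stop = seq$schedule$stop,
                    step = seq$schedule$step),
    cutoff = seq$cutoff,
    scheme_version = seq$scheme_version,
    source_id = seq$source_id
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a topological sequence saved by [save_sequence()]
#'
#' @param path Path to the JSON container.
#' @return A `"topo_sequence"`.
#' @export
load_sequence <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse sequence file '",
                                           path, "': ", conditionMessage(e)))
  if (!identical(obj$format, "pthl-topo-sequence-1"))
    stop("not a pthl topological-sequence file: ", path)
  tensor <- array(as.numeric(obj$features), dim = obj$dim,
                  dimnames = list(NULL, obj$combos, obj$stats))
  schedule <- filtration_schedule(obj$schedule$start, obj$schedule$stop,
                                  obj$schedule$step)
  structure(
    list(tensor = tensor, schedule = schedule, cutoff = obj$cutoff,
         scheme_version = obj$scheme_version, source_id = obj$source_id),
    class = "topo_sequence"
  )
}

#' Flatten a topological sequence to CSV
#'
#' One row per (filtration step, element combination): columns `step`,
#' `filtration`, `combo_label`, and the six statistics.
#'
#' @param seq A `"topo_sequence"`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
sequence_to_csv <- function(seq, path) {
  stopifnot(inherits(seq, "topo_sequence"))
  d <- dim(seq$tensor)
  labels <- dimnames(seq$tensor)[[2]]
  rows <- expand.grid(combo = seq_len(d[2]), step = seq_len(d[1]))
  mat <- matrix(0, nrow(rows), 6, dimnames = list(NULL, .SPECTRAL_STAT_NAMES))
  for (i in seq_len(nrow(rows)))
    mat[i, ] <- seq$tensor[rows$step[i], rows$combo[i], ]
  df <- cbind(
    data.frame(step = rows$step,
               filtration = seq$schedule$grid[rows$step],
               combo_label = labels[rows$combo]),
    as.data.frame(mat)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
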