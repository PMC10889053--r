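# Vietoris-Rips hyperdigraphs, boundary operators and Omega chain-space bases.
#
# A k-directed hyperedge is an ordered tuple of k+1 distinct vertices; a
# hyperdigraph is a graded collection of such tuples over a vertex set.
# Tuples are stored per dimension as integer matrices (one row per edge,
# k+1 columns, 1-based vertex indices).

#' Create a hyperedge orientation rule
#'
#' A rule assigns every simplex an ordered vertex tuple. The default sorts
#' vertices by descending Pauling electronegativity of their element, breaking
#' ties by ascending vertex index, so that directions encode element
#' differences; the `"index"` rule sorts by vertex index alone.
#'
#' @param type `"electronegativity"` or `"index"`.
#' @param elements Character vector of element symbols per vertex (required
#'   for the electronegativity rule; vertices with unknown elements rank last).
#' @return A function mapping an integer vertex vector to its oriented order.
#' @export
orientation_rule <- function(type = c("electronegativity", "index"),
                             elements = NULL) {
  type <- match.arg(type)
  if (type == "index" || is.null(elements)) {
    return(function(v) sort(v))
  }
  en <- .PTHL_ELECTRONEGATIVITY[normalize_element(elements)]
  en[is.na(en)] <- 0
  function(v) v[order(-en[v], v)]
}

#' Construct a hyperdigraph from explicit edge tuples
#'
#' @param n_vertices Number of vertices (indices `1..n_vertices`).
#' @param edges List of integer matrices; the element at position `k + 1`
#'   holds the k-directed hyperedges as rows of `k + 1` distinct vertex
#'   indices. `NULL` entries mean no edges in that dimension.
#' @return Object of class `"hyperdigraph"`.
#' @export
hyperdigraph <- function(n_vertices, edges = list()) {
  stopifnot(n_vertices >= 0)
  edges <- lapply(seq_along(edges), function(i) {
    m <- edges[[i]]
    if (is.null(m) || length(m) == 0) return(matrix(integer(), 0, i))
    m <- matrix(as.integer(m), ncol = i)
    if (any(m < 1L | m > n_vertices)) stop("vertex index out of range")
    if (any(apply(m, 1, anyDuplicated) > 0)) stop("repeated vertex in a hyperedge")
    m[!duplicated(edge_keys(m)), , drop = FALSE]
  })
  structure(list(n_vertices = as.integer(n_vertices), edges = edges),
            class = "hyperdigraph")
}

edge_keys <- function(m) {
  if (nrow(m) == 0) return(character())
  apply(m, 1, paste, collapse = "-")
}

#' Hyperedges of a given dimension
#'
#' @param hd A hyperdigraph.
#' @param k Dimension (0-directed hyperedges are single vertices).
#' @return Integer matrix with `k + 1` columns, one row per hyperedge.
#' @export
hd_edges <- function(hd, k) {
  stopifnot(inherits(hd, "hyperdigraph"), k >= 0)
  if (k + 1 > length(hd$edges)) return(matrix(integer(), 0, k + 1))
  hd$edges[[k + 1]]
}

#' Number of hyperedges per dimension
#' @param hd A hyperdigraph.
#' @return Integer vector indexed by dimension `0..max`.
#' @export
hd_sizes <- function(hd) {
  vapply(hd$edges, nrow, integer(1))
}

#' @export
print.hyperdigraph <- function(x, ...) {
  cat("<hyperdigraph> ", x$n_vertices, " vertices; edges by dimension: ",
      paste(hd_sizes(x), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Test whether one hyperdigraph is contained in another
#'
#' @param a,b Hyperdigraphs over the same vertex set.
#' @return `TRUE` iff every hyperedge of `a` (as an ordered tuple) is an edge
#'   of `b`.
#' @export
hd_contains <- function(b, a) {
  if (a$n_vertices > b$n_vertices) return(FALSE)
  for (d in seq_along(a$edges)) {
    ka <- edge_keys(a$edges[[d]])
    if (length(ka) == 0) next
    if (d > length(b$edges)) return(FALSE)
    if (!all(ka %in% edge_keys(b$edges[[d]]))) return(FALSE)
  }
  TRUE
}

#' Vietoris-Rips hyperdigraph of a point cloud
#'
#' Includes one directed hyperedge for every vertex subset of size
#' `<= max_dim + 1` whose weight is `<= eta` (closed threshold), oriented by
#' the given rule. The weight of a simplex is its diameter (maximum pairwise
#' distance) by convention; `weight = "radius"` uses half the diameter, i.e.
#' a simplex enters at radius `eta` when its diameter is `<= 2 eta`. All
#' 0-hyperedges are always present and the result is closed under faces.
#'
#' @param points Numeric n x d coordinate matrix (rows are vertices), or a
#'   precomputed symmetric distance matrix via `dist_matrix`.
#' @param eta Filtration threshold in Angstrom (`>= 0`).
#' @param max_dim Maximum hyperedge dimension to build.
#' @param orientation Orientation rule (see [orientation_rule()]); defaults to
#'   the index rule unless `elements` is given.
#' @param elements Optional element symbols per vertex; when supplied the
#'   electronegativity orientation rule is used by default.
#' @param weight `"diameter"` (default) or `"radius"`.
#' @param dist_matrix Optional n x n distance matrix overriding `points`.
#' @return A `"hyperdigraph"`.
#' @export
vr_hyperdigraph <- function(points = NULL, eta, max_dim = 1,
                            orientation = NULL, elements = NULL,
                            weight = c("diameter", "radius"),
                            dist_matrix = NULL) {
  weight <- match.arg(weight)
  stopifnot(eta >= 0, max_dim >= 0)
  if (is.null(dist_matrix)) {
    if (is.null(points) || length(points) == 0)
      return(hyperdigraph(0, list()))
    points <- as.matrix(points)
    stopifnot(all(is.finite(points)))
    dist_matrix <- as.matrix(stats::dist(points))
  }
  n <- nrow(dist_matrix)
  if (n == 0) return(hyperdigraph(0, list()))
  if (is.null(orientation))
    orientation <- orientation_rule(
      if (is.null(elements)) "index" else "electronegativity",
      elements = elements)
  thr <- if (weight == "radius") 2 * eta else eta
  edges <- vector("list", max_dim + 1)
  edges[[1]] <- matrix(seq_len(n), ncol = 1)
  if (max_dim >= 1 && n >= 2) {
    adj <- dist_matrix <= thr
    diag(adj) <- FALSE
    # grow cliques dimension by dimension: a (k+1)-set is a simplex iff its
    # diameter <= thr, i.e. it is a clique of the threshold graph
    prev <- lapply(seq_len(n), function(v) v)
    for (d in 1:max_dim) {
      cur <- list()
      for (s in prev) {
        last <- s[length(s)]
        if (last < n) {
          cand <- (last + 1):n
          cand <- cand[vapply(cand, function(w) all(adj[s, w]), logical(1))]
          for (w in cand) cur[[length(cur) + 1]] <- c(s, w)
        }
      }
      if (length(cur) == 0) break
      m <- do.call(rbind, lapply(cur, function(s) orientation(s)))
      edges[[d + 1]] <- m
      prev <- cur
    }
  }
  hyperdigraph(n, edges)
}

# Faces of the tuples in matrix m (drop position i, order preserved), with
# the alternating sign (-1)^(i-1) of the boundary sum. Returns a list with
# face key matrix-free representation: data.frame(edge, sign, key).
tuple_faces <- function(m) {
  k1 <- ncol(m)
  if (nrow(m) == 0 || k1 < 2)
    return(data.frame(edge = integer(), sign = numeric(), key = character(),
                      stringsAsFactors = FALSE))
  out <- vector("list", k1)
  for (i in seq_len(k1)) {
    f <- m[, -i, drop = FALSE]
    out[[i]] <- data.frame(
      edge = seq_len(nrow(m)),
      sign = (-1)^(i - 1),
      key = edge_keys(f),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Ambient boundary matrix of the tuples in `m` (|keys| x nrow(m)), rows
# indexed by the supplied face keys (entries for faces outside `keys` are
# dropped by the caller's choice of keys).
ambient_boundary <- function(m, keys) {
  B <- matrix(0, length(keys), nrow(m),
              dimnames = list(keys, NULL))
  fc <- tuple_faces(m)
  hit <- fc$key %in% keys
  fc <- fc[hit, , drop = FALSE]
  if (nrow(fc) > 0) {
    idx <- cbind(match(fc$key, keys), fc$edge)
    # distinct vertices per tuple => each (face, edge) pair occurs once
    B[idx] <- B[idx] + fc$sign
  }
  B
}

#' Orthonormal basis of the Omega chain space
#'
#' `Omega_k` is the subspace of formal combinations of k-hyperedges whose
#' boundary stays inside the span of the (k-1)-hyperedges. It is computed as
#' the null space of the boundary composed with the projection off
#' `span(F_{k-1})`. For face-closed hyperdigraphs (e.g. all Vietoris-Rips
#' outputs) this is the whole of `span(F_k)` and the standard edge basis is
#' returned.
#'
#' @param hd A hyperdigraph.
#' @param k Dimension.
#' @param tol Relative tolerance for rank decisions.
#' @return List with `dimension`, `edges` (the ambient `F_k` tuple matrix) and
#'   `basis` (|F_k| x dim Omega_k matrix with orthonormal columns).
#' @export
omega_basis <- function(hd, k, tol = 1e-8) {
  Fk <- hd_edges(hd, k)
  nk <- nrow(Fk)
  if (k == 0 || nk == 0) {
    return(list(dimension = k, edges = Fk, basis = diag(1, nk, nk)))
  }
  Fkm1 <- hd_edges(hd, k - 1)
  keys_prev <- edge_keys(Fkm1)
  fc <- tuple_faces(Fk)
  outside <- unique(fc$key[!(fc$key %in% keys_prev)])
  if (length(outside) == 0) {
    return(list(dimension = k, edges = Fk, basis = diag(1, nk, nk)))
  }
  M <- ambient_boundary(Fk, outside)
  sv <- svd(M, nu = 0, nv = ncol(M))
  s <- c(sv$d, rep(0, ncol(M) - length(sv$d)))
  null_cols <- s < tol * max(1, s[1])
  list(dimension = k, edges = Fk,
       basis = sv$v[, null_cols, drop = FALSE])
}

#' Boundary matrix between Omega chain spaces
#'
#' Matrix of the boundary operator `Omega_k -> Omega_{k-1}` in the orthonormal
#' bases returned by [omega_basis()]. `B_0` is the empty map (a `0 x dim`
#' matrix); for `k` beyond the populated dimensions the matrix has zero
#' columns. The chain-complex identity `B_k B_{k+1} = 0` holds to numerical
#' tolerance.
#'
#' @inheritParams omega_basis
#' @return Numeric matrix of size `dim Omega_{k-1} x dim Omega_k`.
#' @export
boundary_matrix <- function(hd, k, tol = 1e-8) {
  stopifnot(k >= 0)
  ok <- omega_basis(hd, k, tol)
  if (k == 0) return(matrix(0, 0, ncol(ok$basis)))
  okm1 <- omega_basis(hd, k - 1, tol)
  keys_prev <- edge_keys(okm1$edges)
  D <- ambient_boundary(ok$edges, keys_prev)
  crossprod(okm1$basis, D %*% ok$basis)
}

#' Serialize a hyperdigraph to JSON
#'
#' Debugging aid: writes vertex count and per-dimension edge tuples.
#'
#' @param hd A hyperdigraph.
#' @param path Output file path; when `NULL`, the JSON string is returned.
#' @export
hd_to_json <- function(hd, path = NULL) {
  obj <- list(
    n_vertices = hd$n_vertices,
    edges = lapply(hd$edges, function(m) unname(apply(m, 1, c, simplify = FALSE)))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
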