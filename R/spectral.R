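# Combinatorial and persistent hyperdigraph Laplacians and their spectra.

#' Combinatorial hyperdigraph Laplacian
#'
#' Assembles `L_k = B_{k+1} B_{k+1}^T + B_k^T B_k` on the Omega chain space of
#' dimension `k`. For `k = 0` this reduces to `B_1 B_1^T`, which on any
#' 1-dimensional hyperdigraph equals the graph Laplacian `D - A` of the
#' underlying undirected graph, for every orientation rule. The result is
#' symmetric positive semidefinite; its zero-eigenvalue multiplicity is the
#' k-th Betti number and the positive (non-harmonic) spectrum encodes
#' geometry.
#'
#' @param hd A hyperdigraph.
#' @param k Dimension (`>= 0`).
#' @param tol Relative tolerance for the Omega-basis rank decisions.
#' @return Symmetric matrix of size `dim Omega_k` (possibly `0 x 0`).
#' @export
hd_laplacian <- function(hd, k, tol = 1e-8) {
  stopifnot(k >= 0)
  Bk  <- boundary_matrix(hd, k, tol)
  Bk1 <- boundary_matrix(hd, k + 1, tol)
  L <- crossprod(Bk) + tcrossprod(Bk1)
  (L + t(L)) / 2
}

#' Eigenvalue spectrum of a symmetric PSD matrix
#'
#' Eigenvalues are returned in ascending order; values below
#' `zero_tol * max(1, lambda_max)` in magnitude are reported as exactly zero
#' and small negative eigensolver noise is clamped to zero.
#'
#' @param L Symmetric matrix (asymmetry beyond `1e-6 * scale` is an error).
#' @param zero_tol Relative zero threshold.
#' @return Object of class `"laplacian_spectrum"`: list with `values`
#'   (ascending), `n_zero`, `zero_tol`.
#' @export
laplacian_spectrum <- function(L, zero_tol = 1e-8) {
  L <- as.matrix(L)
  if (nrow(L) != ncol(L)) stop("spectrum requires a square matrix")
  if (nrow(L) == 0) {
    return(structure(list(values = numeric(), n_zero = 0L,
                          zero_tol = zero_tol),
                     class = "laplacian_spectrum"))
  }
  scale <- max(1, max(abs(L)))
  if (max(abs(L - t(L))) > 1e-6 * scale)
    stop("matrix is not symmetric to tolerance")
  ev <- sort(eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  thr <- zero_tol * max(1, max(ev, 0))
  if (min(ev) < -thr)
    stop("matrix is not positive semidefinite: min eigenvalue ", min(ev))
  ev[abs(ev) < thr] <- 0
  ev <- pmax(ev, 0)
  structure(list(values = ev, n_zero = sum(ev == 0), zero_tol = zero_tol),
            class = "laplacian_spectrum")
}

#' @export
print.laplacian_spectrum <- function(x, ...) {
  cat("<laplacian_spectrum> n = ", length(x$values),
      ", zero multiplicity = ", x$n_zero, "\n", sep = "")
  invisible(x)
}

.SPECTRAL_STAT_NAMES <- c("n_zero", "mean_pos", "sd_pos",
                          "min_pos", "max_pos", "sum_pos")

#' Six-number spectral summary
#'
#' The statistics that feed the topological embedding: the multiplicity of
#' zero, and the mean, population standard deviation, minimum, maximum and
#' sum of the strictly positive eigenvalues. When no positive eigenvalue
#' exists all five positive statistics are 0, keeping the summary finite for
#' sparse element combinations.
#'
#' @param spec A `"laplacian_spectrum"` or a numeric eigenvalue vector.
#' @return Named numeric vector of length 6
#'   (`n_zero, mean_pos, sd_pos, min_pos, max_pos, sum_pos`).
#' @export
spectral_summary <- function(spec) {
  ev <- if (inherits(spec, "laplacian_spectrum")) spec$values else
    sort(as.numeric(spec))
  pos <- ev[ev > 0]
  out <- if (length(pos) == 0) {
    c(length(ev), 0, 0, 0, 0, 0)
  } else {
    c(sum(ev == 0),
      mean(pos),
      sqrt(mean((pos - mean(pos))^2)),  # population sd
      min(pos), max(pos), sum(pos))
  }
  names(out) <- .SPECTRAL_STAT_NAMES
  out
}

#' Betti number via the harmonic spectrum
#'
#' The k-th Betti number equals the zero-eigenvalue multiplicity of `L_k`:
#' connected components for `k = 0`, independent loops for `k = 1`, cavities
#' for `k = 2`.
#'
#' @inheritParams hd_laplacian
#' @param zero_tol Relative zero threshold for the spectrum.
#' @return Non-negative integer count.
#' @export
betti <- function(hd, k, tol = 1e-8, zero_tol = 1e-8) {
  L <- hd_laplacian(hd, k, tol)
  laplacian_spectrum(L, zero_tol)$n_zero
}

#' Persistent hyperdigraph Laplacian
#'
#' For nested hyperdigraphs `hd_a` (scale a) inside `hd_b` (scale b >= a),
#' assembles the persistent Laplacian on `Omega_k^a`:
#' the persistent chain space `Omega_{k+1}^{a,b}` collects the (k+1)-chains of
#' `b` whose boundary lands in `Omega_k^a`; the persistent boundary restricted
#' to it, together with the internal boundary of `a`, gives
#' `Delta_k^{a,b} = B_{k+1}^{a,b} (B_{k+1}^{a,b})^T + (B_k^a)^T B_k^a`.
#' Its kernel dimension equals the (a,b)-persistent Betti number.
#'
#' @param hd_a,hd_b Hyperdigraphs with `hd_a` contained in `hd_b`.
#' @param k Dimension.
#' @param tol Relative tolerance for rank decisions.
#' @return Symmetric PSD matrix of size `dim Omega_k^a`.
#' @export
persistent_laplacian <- function(hd_a, hd_b, k, tol = 1e-8) {
  stopifnot(k >= 0)
  if (!hd_contains(hd_b, hd_a))
    stop("hd_a is not contained in hd_b")
  oa <- omega_basis(hd_a, k, tol)
  Qa <- oa$basis
  Bka <- boundary_matrix(hd_a, k, tol)
  down <- crossprod(Bka)

  Fb1 <- hd_edges(hd_b, k + 1)
  if (nrow(Fb1) == 0 || ncol(Qa) == 0) {
    L <- down + matrix(0, ncol(Qa), ncol(Qa))
    return((L + t(L)) / 2)
  }
  ob <- omega_basis(hd_b, k + 1, tol)
  Qb <- ob$basis
  if (ncol(Qb) == 0) {
    L <- down
    return((L + t(L)) / 2)
  }
  keys_a <- edge_keys(oa$edges)
  fc_keys <- unique(tuple_faces(Fb1)$key)
  U <- unique(c(fc_keys, keys_a, edge_keys(hd_edges(hd_b, k))))
  Damb <- ambient_boundary(Fb1, U)
  # Omega_k^a embedded in the ambient coordinates
  Qa_amb <- matrix(0, length(U), ncol(Qa))
  Qa_amb[match(keys_a, U), ] <- Qa
  M <- Damb %*% Qb
  Mperp <- M - Qa_amb %*% crossprod(Qa_amb, M)
  sv <- svd(Mperp, nu = 0, nv = ncol(Mperp))
  s <- c(sv$d, rep(0, ncol(Mperp) - length(sv$d)))
  R <- sv$v[, s < tol * max(1, s[1]), drop = FALSE]
  if (ncol(R) == 0) {
    L <- down
    return((L + t(L)) / 2)
  }
  # persistent boundary in the Omega_k^a basis
  Bp <- crossprod(Qa, (Damb %*% (Qb %*% R))[match(keys_a, U), , drop = FALSE])
  L <- tcrossprod(Bp) + down
  (L + t(L)) / 2
}

#' Persistent Betti number
#'
#' Kernel dimension of the persistent Laplacian [persistent_laplacian()].
#'
#' @inheritParams persistent_laplacian
#' @param zero_tol Relative zero threshold for the spectrum.
#' @return Non-negative integer count of features alive from scale a to b.
#' @export
persistent_betti <- function(hd_a, hd_b, k, tol = 1e-8, zero_tol = 1e-8) {
  L <- persistent_laplacian(hd_a, hd_b, k, tol)
  laplacian_spectrum(L, zero_tol)$n_zero
}

#' Export a spectrum (or several) as a CSV table
#'
#' @param spectra Named list of `"laplacian_spectrum"` objects, keyed by
#'   dimension or any label.
#' @param path Output CSV path.
#' @return The path, invisibly. Columns: `dimension`, `index`, `eigenvalue`.
#' @export
spectra_to_csv <- function(spectra, path) {
  rows <- lapply(names(spectra), function(nm) {
    v <- spectra[[nm]]$values
    if (length(v) == 0) return(NULL)
    data.frame(dimension = nm, index = seq_along(v), eigenvalue = v)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(dimension = character(),
                                    index = integer(), eigenvalue = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
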