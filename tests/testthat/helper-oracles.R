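# Independent topology oracles used to cross-check the package's Omega-basis
# Laplacian pipeline. Deliberately separate machinery: plain simplicial
# complexes with ascending-sorted vertex simplices, signed incidence
# matrices, and rank computations, with no use of the package's hyperdigraph
# code paths.

# All (k+1)-subsets of vertices whose diameter is <= eta, rows sorted
# ascending. `dmat` is a symmetric distance matrix.
oracle_simplices <- function(dmat, k, eta) {
  n <- nrow(dmat)
  if (k + 1 > n) return(matrix(integer(), 0, k + 1))
  if (k == 0) return(matrix(seq_len(n), ncol = 1))
  sets <- utils::combn(n, k + 1)
  keep <- apply(sets, 2, function(s) max(dmat[s, s]) <= eta)
  t(sets[, keep, drop = FALSE])
}

oracle_key <- function(m) apply(m, 1, paste, collapse = "-")

# Signed incidence matrix of the k-th simplicial boundary operator,
# rows = (k-1)-simplices, columns = k-simplices.
oracle_boundary <- function(Sk, Skm1) {
  B <- matrix(0, nrow(Skm1), nrow(Sk))
  if (nrow(Sk) == 0 || nrow(Skm1) == 0) return(B)
  keys <- oracle_key(Skm1)
  for (j in seq_len(nrow(Sk))) {
    s <- Sk[j, ]
    for (i in seq_along(s)) {
      face <- paste(s[-i], collapse = "-")
      r <- match(face, keys)
      if (!is.na(r)) B[r, j] <- (-1)^(i - 1)
    }
  }
  B
}

oracle_rank <- function(M, tol = 1e-8) {
  if (length(M) == 0 || min(dim(M)) == 0) return(0L)
  s <- svd(M, nu = 0, nv = 0)$d
  sum(s > tol * max(1, s[1]))
}

# Betti number via rank-nullity on the Vietoris-Rips complex at scale eta.
oracle_betti <- function(dmat, eta, k) {
  Sk <- oracle_simplices(dmat, k, eta)
  if (nrow(Sk) == 0) return(0L)
  Skm1 <- if (k > 0) oracle_simplices(dmat, k - 1, eta) else
    matrix(integer(), 0, 0)
  Sk1 <- oracle_simplices(dmat, k + 1, eta)
  Bk <- if (k > 0) oracle_boundary(Sk, Skm1) else
    matrix(0, 0, nrow(Sk))
  Bk1 <- oracle_boundary(Sk1, Sk)
  z <- nrow(Sk) - oracle_rank(Bk)     # dim of cycle space
  b <- oracle_rank(Bk1)               # dim of boundary space
  as.integer(z - b)
}

# Persistent Betti number beta_k^{a,b} for nested VR scales ea <= eb:
# rank([Z_k^a  B_k^b]) - rank(B_k^b), with the cycle space of scale a
# embedded in the chain space of scale b.
oracle_persistent_betti <- function(dmat, ea, eb, k) {
  Ska <- oracle_simplices(dmat, k, ea)
  if (nrow(Ska) == 0) return(0L)
  Skb <- oracle_simplices(dmat, k, eb)
  Skm1a <- if (k > 0) oracle_simplices(dmat, k - 1, ea) else
    matrix(integer(), 0, 0)
  Bka <- if (k > 0) oracle_boundary(Ska, Skm1a) else
    matrix(0, 0, nrow(Ska))
  # null-space basis of the boundary of scale a = cycle space Z_k^a
  if (nrow(Bka) == 0) {
    Za <- diag(1, nrow(Ska))
  } else {
    sv <- svd(Bka, nu = 0, nv = ncol(Bka))
    s <- c(sv$d, rep(0, ncol(Bka) - length(sv$d)))
    Za <- sv$v[, s < 1e-8 * max(1, s[1]), drop = FALSE]
  }
  # embed into the scale-b chain space
  Zemb <- matrix(0, nrow(Skb), ncol(Za))
  Zemb[match(oracle_key(Ska), oracle_key(Skb)), ] <- Za
  Db <- oracle_boundary(oracle_simplices(dmat, k + 1, eb), Skb)
  as.integer(oracle_rank(cbind(Zemb, Db)) - oracle_rank(Db))
}

# Connected components of a thresholded (possibly masked) distance matrix
# via union-find; Inf entries never connect.
oracle_components <- function(D, d) {
  n <- nrow(D)
  parent <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && is.finite(D[i, j]) && D[i, j] <= d &&
          parent[i] != parent[j]) {
        m <- min(parent[i], parent[j])
        parent[parent == parent[i] | parent == parent[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(parent))
}

# Random seeded point cloud for oracle comparisons (kept local to the tests).
oracle_cloud <- function(n, seed, box = 4) {
  set.seed(seed)
  matrix(stats::runif(3 * n, 0, box), ncol = 3)
}

# Temp file scoped to the calling test.
withr_tempfile <- function(ext) {
  withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
}
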