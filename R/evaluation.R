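# CASF-style evaluation: scoring, ranking, docking, screening, consensus.

#' Scoring metrics: PCC and RMSE
#'
#' Pearson correlation and root-mean-squared error between predicted and
#' experimental binding affinities (in -log Kd/Ki units), plus the RMSE after
#' the kcal/mol conversion, which multiplies the values by 1.3633.
#'
#' @param pred,expt Numeric vectors of equal length (`>= 2`), both with
#'   nonzero variance.
#' @param kcal_factor Conversion factor from -log units to kcal/mol.
#' @return List with `pcc`, `rmse`, `rmse_kcal`.
#' @export
scoring_metrics <- function(pred, expt, kcal_factor = 1.3633) {
  stopifnot(length(pred) == length(expt), length(pred) >= 2,
            all(is.finite(pred)), all(is.finite(expt)))
  if (stats::sd(pred) == 0 || stats::sd(expt) == 0)
    stop("correlation undefined: zero variance in pred or expt")
  rmse <- sqrt(mean((pred - expt)^2))
  list(pcc = stats::cor(pred, expt),
       rmse = rmse,
       rmse_kcal = kcal_factor * rmse)
}

#' Ranking power within affinity clusters
#'
#' High-level success requires the predicted affinities to reproduce the
#' experimental order of a cluster exactly; low-level success only requires
#' the top-affinity complex to be ranked first. Rates are fractions of
#' clusters, so `high_rate <= low_rate` always. Experimental ties make exact
#' ordering ill-defined; by default tied clusters count as high-level
#' failures.
#'
#' @param clusters Data frame with columns `cluster_id`, `complex_id`,
#'   `expt`, `pred`; cluster sizes must be uniform.
#' @param ties `"fail"` (default) or `"drop"` (exclude tied clusters).
#' @return List with `high_rate`, `low_rate`, `n_clusters`, `cluster_size`.
#' @export
ranking_power <- function(clusters, ties = c("fail", "drop")) {
  ties <- match.arg(ties)
  stopifnot(all(c("cluster_id", "expt", "pred") %in% names(clusters)))
  parts <- split(clusters, clusters$cluster_id)
  sizes <- unique(vapply(parts, nrow, integer(1)))
  if (length(sizes) != 1)
    stop("cluster sizes are not uniform: ", paste(sizes, collapse = ", "))
  tied <- vapply(parts, function(p) anyDuplicated(p$expt) > 0, logical(1))
  if (ties == "drop") parts <- parts[!tied]
  high <- vapply(parts, function(p) {
    anyDuplicated(p$expt) == 0 &&
      identical(order(p$pred, decreasing = TRUE),
                order(p$expt, decreasing = TRUE))
  }, logical(1))
  low <- vapply(parts, function(p) {
    which.max(p$pred) == which.max(p$expt)
  }, logical(1))
  list(high_rate = mean(high), low_rate = mean(low),
       n_clusters = length(parts), cluster_size = sizes)
}

#' Docking success rate
#'
#' A ligand counts as a success when its top-scored pose is native, i.e. has
#' RMSD to the crystallographic pose strictly below the threshold (2 A by
#' convention). Score ties are broken deterministically by lowest pose id.
#'
#' @param poses Data frame with columns `ligand_id`, `pose_id`, `rmsd`,
#'   `score` (higher is better).
#' @param threshold RMSD threshold in Angstrom.
#' @return List with `success_rate`, `n_ligands`, and the per-ligand logical
#'   vector `success`.
#' @export
docking_success <- function(poses, threshold = 2.0) {
  stopifnot(threshold > 0,
            all(c("ligand_id", "pose_id", "rmsd", "score") %in% names(poses)),
            all(poses$rmsd >= 0))
  parts <- split(poses, poses$ligand_id)
  success <- vapply(parts, function(p) {
    p <- p[order(-p$score, p$pose_id), , drop = FALSE]
    p$rmsd[1] < threshold
  }, logical(1))
  list(success_rate = mean(success), n_ligands = length(parts),
       success = success)
}

#' Root-mean-square deviation between two conformations
#'
#' Plain per-atom RMSD in a shared frame (no superposition: docking poses
#' share the receptor frame with the crystal pose).
#'
#' @param coords_a,coords_b Numeric N x 3 coordinate matrices with matching
#'   atom order.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)))
    stop("coordinate sets differ in shape")
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' Screening power: success rate and enrichment factor
#'
#' Candidates are ranked per target by the combined score `S = S1 * S2`
#' (regression score times binder probability), descending. For each cutoff
#' `alpha` the top set has `ceiling(alpha * n)` members (so at least one
#' compound is always selected). The success rate at `alpha` is the fraction
#' of targets whose best true binder (highest experimental affinity when an
#' `affinity` column is present, otherwise any binder) appears in the top
#' set; the enrichment factor per target is
#' `(#binders in top set) / (#binders * alpha)`, averaged over targets.
#'
#' @param screens Data frame with columns `target_id`, `ligand_id`,
#'   `is_binder`, `s1`, `s2`, optional `affinity`.
#' @param alphas Numeric vector of top fractions (default 1%, 5%, 10%).
#' @return Data frame with one row per `alpha`: `alpha`, `success_rate`,
#'   `ef`, plus attribute `"best_binder"` noting which convention applied.
#' @export
screening_metrics <- function(screens, alphas = c(0.01, 0.05, 0.10)) {
  stopifnot(all(c("target_id", "ligand_id", "is_binder", "s1", "s2")
                %in% names(screens)),
            all(alphas > 0 & alphas <= 1))
  has_aff <- "affinity" %in% names(screens)
  parts <- split(screens, screens$target_id)
  if (any(vapply(parts, function(p) sum(p$is_binder) == 0, logical(1))))
    stop("every target needs at least one true binder")
  res <- lapply(alphas, function(alpha) {
    per <- vapply(parts, function(p) {
      s <- p$s1 * p$s2
      ord <- order(-s, p$ligand_id)
      top <- ord[seq_len(ceiling(alpha * nrow(p)))]
      nb <- sum(p$is_binder)
      best <- if (has_aff) {
        bi <- which(p$is_binder)
        bi[which.max(p$affinity[bi])]
      } else NA_integer_
      c(success = if (has_aff) best %in% top else any(p$is_binder[top]),
        ef = sum(p$is_binder[top]) / (nb * alpha))
    }, numeric(2))
    c(alpha = alpha, success_rate = mean(per["success", ]),
      ef = mean(per["ef", ]))
  })
  out <- as.data.frame(do.call(rbind, res))
  attr(out, "best_binder") <- if (has_aff) "highest-affinity" else "any"
  out
}

#' Consensus averaging over model subsets
#'
#' Repeatedly draws `size` prediction vectors at random (without
#' replacement), averages them, and scores the average against the
#' experimental values, mirroring the repeated-consensus evaluation
#' protocol (400 repetitions per size in the reference setting).
#'
#' @param model_predictions List of numeric prediction vectors, one per
#'   model, all the same length as `expt`.
#' @param expt Experimental affinity vector.
#' @param size Consensus size (`1 <= size <=` number of models).
#' @param repeats Number of repetitions.
#' @param seed Integer seed.
#' @return List with per-repetition `pcc` and `rmse` vectors and the
#'   aggregate `mean_pcc`, `sd_pcc`, `mean_rmse`, `sd_rmse`.
#' @export
consensus <- function(model_predictions, expt, size, repeats = 400,
                      seed = 1) {
  m <- length(model_predictions)
  stopifnot(size >= 1, size <= m, repeats >= 1)
  stopifnot(all(vapply(model_predictions, length, integer(1)) == length(expt)))
  withr_seed(seed)
  P <- do.call(cbind, model_predictions)
  pcc <- numeric(repeats); rm_ <- numeric(repeats)
  for (r in seq_len(repeats)) {
    pick <- sample.int(m, size)
    avg <- rowMeans(P[, pick, drop = FALSE])
    sm <- scoring_metrics(avg, expt)
    pcc[r] <- sm$pcc; rm_[r] <- sm$rmse
  }
  list(pcc = pcc, rmse = rm_,
       mean_pcc = mean(pcc), sd_pcc = stats::sd(pcc),
       mean_rmse = mean(rm_), sd_rmse = stats::sd(rm_))
}

#' Read evaluation tables from CSV
#'
#' Schemas: clusters `(cluster_id, complex_id, expt, pred)`; poses
#' `(ligand_id, pose_id, rmsd, score)`; screens
#' `(target_id, ligand_id, is_binder, s1, s2[, affinity])`.
#'
#' @param path CSV path.
#' @param kind One of `"clusters"`, `"poses"`, `"screens"`.
#' @return Data frame validated against the schema.
#' @export
read_benchmark_csv <- function(path, kind = c("clusters", "poses", "screens")) {
  kind <- match.arg(kind)
  need <- switch(kind,
    clusters = c("cluster_id", "complex_id", "expt", "pred"),
    poses = c("ligand_id", "pose_id", "rmsd", "score"),
    screens = c("target_id", "ligand_id", "is_binder", "s1", "s2"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing columns in ", kind, " table: ", paste(miss, collapse = ", "))
  if (kind == "screens") df$is_binder <- as.logical(df$is_binder)
  df
}
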