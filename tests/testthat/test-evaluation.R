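test_that("scoring metrics recover correlation, error and unit conversion", {
  expt <- c(4.2, 5.1, 6.3, 7.8, 9.0)
  perfect <- scoring_metrics(expt, expt)
  expect_equal(perfect$pcc, 1)
  expect_equal(perfect$rmse, 0)
  anti <- scoring_metrics(-expt, expt)
  expect_equal(anti$pcc, -1)
  # RMSE of 1.0 in -log units is 1.3633 kcal/mol
  shifted <- scoring_metrics(expt + 1, expt)
  expect_equal(shifted$rmse, 1.0)
  expect_equal(shifted$rmse_kcal, 1.3633)
  expect_error(scoring_metrics(rep(1, 5), expt), "zero variance")
  expect_error(scoring_metrics(1, 1))
})

make_clusters <- function(preds) {
  # four size-3 clusters with experimental affinities 3 > 2 > 1
  data.frame(
    cluster_id = rep(1:4, each = 3),
    complex_id = sprintf("c%02d", 1:12),
    expt = rep(c(3, 2, 1), 4),
    pred = preds
  )
}

test_that("ranking power counts exact orders and top picks", {
  perfect <- make_clusters(rep(c(3, 2, 1), 4))
  expect_equal(ranking_power(perfect)[c("high_rate", "low_rate")],
               list(high_rate = 1, low_rate = 1))
  reversed <- make_clusters(rep(c(1, 2, 3), 4))
  expect_equal(ranking_power(reversed)[c("high_rate", "low_rate")],
               list(high_rate = 0, low_rate = 0))
  # 2 perfectly ordered, 1 top-correct-only, 1 wrong -> (0.5, 0.75)
  mixed <- make_clusters(c(3, 2, 1,  3, 2, 1,  3, 1, 2,  1, 3, 2))
  rp <- ranking_power(mixed)
  expect_equal(rp$high_rate, 0.5)
  expect_equal(rp$low_rate, 0.75)
  expect_lte(rp$high_rate, rp$low_rate)
})

test_that("experimental ties fail (or drop) the high-level criterion", {
  tied <- data.frame(cluster_id = rep(1:2, each = 3),
                     complex_id = sprintf("c%d", 1:6),
                     expt = c(3, 3, 1, 3, 2, 1),
                     pred = c(3, 2, 1, 3, 2, 1))
  expect_equal(ranking_power(tied)$high_rate, 0.5)
  expect_equal(ranking_power(tied, ties = "drop")$high_rate, 1)
  bad <- data.frame(cluster_id = c(1, 1, 2), complex_id = c("a", "b", "c"),
                    expt = 1:3, pred = 1:3)
  expect_error(ranking_power(bad), "not uniform")
})

test_that("docking success uses a strict 2 A threshold and pose-id tie-breaks", {
  one <- data.frame(ligand_id = "l1", pose_id = 1:3,
                    rmsd = c(1.6, 5, 8), score = c(9, 2, 1))
  expect_equal(docking_success(one)$success_rate, 1)
  boundary <- data.frame(ligand_id = "l1", pose_id = 1:2,
                         rmsd = c(2.0, 4), score = c(9, 1))
  expect_equal(docking_success(boundary)$success_rate, 0)  # strict <
  # 10 ligands, 7 with a native top pose
  set.seed(2)
  tab <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(ligand_id = sprintf("l%02d", i), pose_id = 1:5,
               rmsd = c(if (i <= 7) 0.5 else 3.5, runif(4, 2.5, 9)),
               score = c(10, runif(4, 0, 5)))
  }))
  expect_equal(docking_success(tab)$success_rate, 0.7)
  # ties: lowest pose id wins deterministically
  tie <- data.frame(ligand_id = "l1", pose_id = c(2, 1),
                    rmsd = c(0.5, 5), score = c(7, 7))
  expect_equal(docking_success(tie)$success_rate, 0)
})

test_that("docking success is invariant under monotone score transforms", {
  tabs <- benchmark_tables(n_ligands = 12, n_poses = 20, noise = 0.4,
                           seed = 8)$poses
  base <- docking_success(tabs)$success_rate
  for (f in list(function(x) 2 * x + 3, function(x) exp(x / 5))) {
    t2 <- tabs; t2$score <- f(t2$score)
    expect_equal(docking_success(t2)$success_rate, base)
  }
})

test_that("rmsd matches hand-computed displacements", {
  a <- matrix(rnorm(15), 5, 3)
  expect_equal(rmsd(a, a), 0)
  expect_equal(rmsd(a, a + rep(c(2, 0, 0), each = 5)), 2.0)
  b <- rbind(c(0, 0, 0), c(0, 0, 0))
  d <- rbind(c(3, 0, 0), c(0, 4, 0))
  expect_equal(rmsd(b, d), sqrt((9 + 16) / 2))
  expect_error(rmsd(a, a[1:3, ]), "shape")
})

test_that("screening metrics follow the ceiling top-set and EF formula", {
  # 100 candidates, 5 binders, the single top-1% slot holds a binder
  s <- data.frame(target_id = "t1", ligand_id = sprintf("l%03d", 1:100),
                  is_binder = c(rep(TRUE, 5), rep(FALSE, 95)),
                  s1 = c(10, rep(5, 4), rep(4, 95)),
                  s2 = 1)
  m <- screening_metrics(s, alphas = 0.01)
  expect_equal(m$ef, 1 / (5 * 0.01))                 # = 20
  # all binders ranked last
  worst <- s; worst$s1 <- c(rep(0, 5), rep(4, 95))
  m2 <- screening_metrics(worst, alphas = 0.01)
  expect_equal(m2$ef, 0)
  expect_equal(m2$success_rate, 0)
  # 195 candidates: ceil(1.95) = 2 selected at 1%
  s195 <- data.frame(target_id = "t1", ligand_id = sprintf("l%03d", 1:195),
                     is_binder = c(TRUE, TRUE, rep(FALSE, 193)),
                     s1 = seq(195, 1), s2 = 1)
  m3 <- screening_metrics(s195, alphas = 0.01)
  expect_equal(m3$ef, 2 / (2 * 0.01) * (1 / 100) * 100)  # both binders in top-2
  expect_equal(m3$ef, 100)
  expect_error(screening_metrics(transform(s, is_binder = FALSE)),
               "true binder")
})

test_that("random rankings give EF near one and the EF bound holds", {
  set.seed(77)
  efs <- replicate(400, {
    s <- data.frame(target_id = "t", ligand_id = sprintf("l%03d", 1:100),
                    is_binder = sample(c(rep(TRUE, 5), rep(FALSE, 95))),
                    s1 = runif(100), s2 = 1)
    screening_metrics(s, alphas = 0.05)$ef
  })
  expect_true(all(efs >= 0 & efs <= 1 / 0.05))
  se <- sd(efs) / sqrt(length(efs))
  expect_lt(abs(mean(efs) - 1), 3 * se + 1e-9)
})

test_that("consensus averaging behaves as an ensemble should", {
  set.seed(5)
  expt <- runif(50, 2, 10)
  models <- lapply(1:8, function(i) expt + rnorm(50, 0, 1))
  # size = number of models: every repetition is the full average
  full <- consensus(models, expt, size = 8, repeats = 10, seed = 3)
  expect_equal(sd(full$pcc), 0)
  # identical models: zero variance across repetitions
  same <- consensus(rep(models[1], 4), expt, size = 2, repeats = 10, seed = 3)
  expect_equal(sd(same$pcc), 0)
  # size 1 reproduces single-model metrics
  one <- consensus(models, expt, size = 1, repeats = 200, seed = 9)
  singles <- vapply(models, function(p) scoring_metrics(p, expt)$pcc,
                    numeric(1))
  expect_true(all(one$pcc %in% singles))
  expect_error(consensus(models, expt, size = 9))
})

test_that("benchmark CSV readers validate their schemas", {
  tabs <- benchmark_tables(n_clusters = 4, n_ligands = 3, n_poses = 5,
                           n_targets = 2, seed = 1)
  d <- withr::local_tempdir()
  for (kind in c("clusters", "poses", "screens")) {
    f <- file.path(d, paste0(kind, ".csv"))
    write.csv(tabs[[kind]], f, row.names = FALSE)
    df <- read_benchmark_csv(f, kind)
    expect_equal(nrow(df), nrow(tabs[[kind]]))
  }
  bad <- file.path(d, "bad.csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_benchmark_csv(bad, "poses"), "missing columns")
})
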