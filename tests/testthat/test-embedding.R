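region_from_atoms <- function(..., cutoff = 12, id = "test") {
  structure(list(atoms = rbind(...), cutoff = cutoff, source_id = id),
            class = "complex_region")
}

test_that("the element scheme has the printed 11 x 13 = 143 structure", {
  sc <- element_scheme()
  expect_length(sc$protein, 11)
  expect_length(sc$ligand, 13)
  expect_length(combo_labels(sc), 143)
  expect_equal(combo_labels(sc)[1], "protein:C|ligand:C")
  # protein sets use only C,N,O,S; ligand sets only the 9 scheme elements
  expect_true(all(unlist(sc$protein) %in% c("C", "N", "O", "S")))
  expect_true(all(unlist(sc$ligand) %in%
                    c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")))
  # exactly 5 C-containing sets on each side -> 25 C x C combinations
  expect_equal(sum(vapply(sc$protein, function(s) "C" %in% s, logical(1))), 5)
  expect_equal(sum(vapply(sc$ligand, function(s) "C" %in% s, logical(1))), 5)
})

test_that("filtration schedules follow the half-open grid convention", {
  s <- filtration_schedule(2, 12, 0.2)
  expect_length(s$grid, 50)
  expect_equal(s$grid[1], 2.2)
  expect_equal(s$grid[50], 12)
  expect_true(all(diff(s$grid) > 0))
  expect_error(filtration_schedule(0, 1, 0.3), "integer multiple")
})

test_that("presets reproduce the published analysis domains", {
  lg <- preset("large")
  expect_equal(lg$cutoff, 20)
  expect_length(lg$schedule$grid, 100)
  sm <- preset("small")
  expect_equal(sm$cutoff, 12)
  expect_length(sm$schedule$grid, 50)
  expect_equal(sm$schedule$grid[50], 12)
  expect_error(preset("medium"))
})

test_that("cross-distance matrices mask same-origin pairs with infinity", {
  reg <- region_from_atoms(
    atom_table("C", 0, 0, 0, "protein"),
    atom_table("C", 3, 0, 0, "ligand"))
  cdm <- cross_distance_matrix(reg, "C", "C")
  expect_equal(dim(cdm$D), c(2, 2))
  expect_equal(cdm$D[1, 2], 3.0)
  expect_true(all(is.infinite(diag(cdm$D))))
  # no matching protein atom -> empty matrix
  empty <- cross_distance_matrix(reg, "N", "C")
  expect_equal(dim(empty$D), c(1, 1))               # ligand C still selected
  expect_true(all(is.infinite(empty$D)))
  # two protein C + one ligand O: protein-protein pair masked
  reg2 <- region_from_atoms(
    atom_table(c("C", "C"), c(0, 1), 0, 0, "protein"),
    atom_table("O", c(0.5), 1, 0, "ligand"))
  cdm2 <- cross_distance_matrix(reg2, "C", "O")
  expect_true(is.infinite(cdm2$D[1, 2]))            # protein-protein
  expect_equal(sum(is.finite(cdm2$D)), 4)           # two symmetric cross pairs
})

test_that("the one-carbon worked example produces the K2 spectrum step", {
  reg <- region_from_atoms(
    atom_table("C", 0, 0, 0, "protein"),
    atom_table("C", 3, 0, 0, "ligand"))
  ts <- embed_complex(reg, preset("small")$schedule)
  expect_equal(dim(ts$tensor), c(50, 143, 6))
  grid <- ts$schedule$grid
  cc <- which(dimnames(ts$tensor)[[2]] == "protein:C|ligand:C")
  for (t in seq_along(grid)) {
    expected <- if (grid[t] < 3.0) c(2, 0, 0, 0, 0, 0) else c(1, 2, 0, 2, 2, 2)
    expect_equal(unname(ts$tensor[t, cc, ]), expected, tolerance = 1e-12)
  }
  # exactly the 25 combos with C active on both sides show the K2 step
  at3 <- apply(ts$tensor[grid >= 3, , , drop = FALSE], 2, function(m)
    all(abs(t(matrix(m, ncol = 6)) - c(1, 2, 0, 2, 2, 2)) < 1e-12))
  expect_equal(sum(at3), 25)
})

test_that("an empty region embeds to the all-zero tensor", {
  reg <- structure(list(atoms = atom_table(character(), numeric(),
                                           numeric(), numeric(), character()),
                        cutoff = 12, source_id = "empty"),
                   class = "complex_region")
  ts <- embed_complex(reg, filtration_schedule(2, 4, 0.5))
  expect_true(all(ts$tensor == 0))
})

test_that("zero multiplicity is monotone non-increasing along every filtration", {
  cx <- synthetic_complex(25, 6, seed = 19, box = 15)
  reg <- extract_region(cx, 12)
  ts <- embed_complex(reg, filtration_schedule(2, 12, 0.5))
  mono <- apply(ts$tensor[, , 1], 2, function(v) all(diff(v) <= 1e-12))
  expect_true(all(mono))
})

test_that("the embedding is invariant to atom input order", {
  cx <- synthetic_complex(15, 5, seed = 23, box = 12)
  reg <- extract_region(cx, 12)
  sched <- filtration_schedule(2, 8, 1)
  ts1 <- embed_complex(reg, sched)
  perm <- sample(nrow(reg$atoms))
  reg2 <- structure(list(atoms = reg$atoms[perm, ], cutoff = reg$cutoff,
                         source_id = reg$source_id),
                    class = "complex_region")
  ts2 <- embed_complex(reg2, sched)
  expect_equal(ts1$tensor, ts2$tensor, tolerance = 1e-10)
})

test_that("a fixed atom pair is counted by exactly the supersets on each side", {
  sc <- element_scheme()
  reg <- region_from_atoms(
    atom_table("C", 0, 0, 0, "protein"),
    atom_table("N", 2, 0, 0, "ligand"))
  n_pro <- sum(vapply(sc$protein, function(s) "C" %in% s, logical(1)))
  n_lig <- sum(vapply(sc$ligand, function(s) "N" %in% s, logical(1)))
  count <- 0
  for (p in sc$protein) for (l in sc$ligand) {
    cdm <- cross_distance_matrix(reg, p, l)
    count <- count + sum(is.finite(cdm$D)) / 2
  }
  expect_equal(count, n_pro * n_lig)
})

test_that("full-combination components match a union-find oracle at the last scale", {
  sc <- element_scheme()
  full_p <- sc$protein[[11]]; full_l <- sc$ligand[[13]]
  for (seed in c(3, 31)) {
    cx <- synthetic_complex(20, 6, seed = seed, box = 14)
    reg <- extract_region(cx, 12)
    sched <- filtration_schedule(2, 12, 1)
    ts <- embed_complex(reg, sched)
    cdm <- cross_distance_matrix(reg, full_p, full_l)
    expect_equal(ts$tensor[length(sched$grid), 143, 1],
                 oracle_components(cdm$D, sched$grid[length(sched$grid)]))
  }
})

test_that("the embedding L0 agrees with the hyperdigraph pipeline per combo", {
  reg <- region_from_atoms(
    atom_table(c("C", "N"), c(0, 1), 0, 0, "protein"),
    atom_table(c("C", "O"), c(2, 3), c(1, 0), 0, "ligand"))
  sched <- filtration_schedule(1, 4, 0.5)
  ts <- embed_complex(reg, sched)
  sc <- element_scheme()
  ci <- 0
  for (p in sc$protein) for (l in sc$ligand) {
    ci <- ci + 1
    cdm <- cross_distance_matrix(reg, p, l)
    if (nrow(cdm$D) == 0) next
    for (t in seq_along(sched$grid)) {
      hd <- vr_hyperdigraph(dist_matrix = cdm$D, eta = sched$grid[t],
                            max_dim = 1)
      expect_equal(unname(ts$tensor[t, ci, ]),
                   unname(spectral_summary(
                     laplacian_spectrum(hd_laplacian(hd, 0)))),
                   tolerance = 1e-10)
    }
  }
})

test_that("sequences survive a save/load round trip bit-exactly", {
  cx <- synthetic_complex(10, 4, seed = 2, box = 10)
  reg <- extract_region(cx, 12)
  ts <- embed_complex(reg, filtration_schedule(2, 6, 1))
  f <- withr_tempfile(".json")
  save_sequence(ts, f)
  back <- load_sequence(f)
  expect_identical(back$tensor, ts$tensor)
  expect_equal(back$schedule$grid, ts$schedule$grid)
  expect_equal(back$cutoff, ts$cutoff)
  expect_equal(back$scheme_version, ts$scheme_version)
  expect_equal(back$source_id, ts$source_id)
  corrupt <- withr_tempfile(".json")
  writeLines("{not json", corrupt)
  expect_error(load_sequence(corrupt), "cannot parse")
})

test_that("CSV export has T x 143 rows and scheme-ordered labels", {
  reg <- region_from_atoms(
    atom_table("C", 0, 0, 0, "protein"),
    atom_table("C", 3, 0, 0, "ligand"))
  ts <- embed_complex(reg, filtration_schedule(2, 4, 1))
  f <- withr_tempfile(".csv")
  sequence_to_csv(ts, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 2 * 143)
  expect_equal(df$combo_label[1], "protein:C|ligand:C")
  expect_equal(df$n_zero[df$step == 2 & df$combo_label == "protein:C|ligand:C"],
               1)
})
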