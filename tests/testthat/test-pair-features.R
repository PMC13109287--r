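# Hydropathy score, neighbor selection, feature assembly, normalization.

test_that("hydropathy parabola matches its closed form", {
  expect_equal(hydropathy_complementarity(0, 0), 0)
  # vertex at the product b/(2a) = 5.5 with height b^2/(4a) = 0.99825
  expect_equal(hydropathy_complementarity(sqrt(5.5), sqrt(5.5)), 0.99825)
  expect_equal(0.363^2 / (4 * 0.033), 0.99825)
  # second root at the product b/a = 11
  expect_equal(hydropathy_complementarity(sqrt(11), sqrt(11)), 0, tolerance = 1e-12)
  expect_error(hydropathy_complementarity(-1, 2), ">= 0")
})

test_that("hydropathy is symmetric and maximal at the vertex", {
  set.seed(1)
  ha <- runif(50, 0, 3.3)
  hb <- runif(50, 0, 3.3)
  expect_equal(
    hydropathy_complementarity(ha, hb),
    hydropathy_complementarity(hb, ha)
  )
  x <- seq(0, 11, by = 0.01)
  vals <- -0.033 * x^2 + 0.363 * x
  expect_lte(max(vals), 0.99825)
})

test_that("the shipped surrogate scale is complete and class-consistent", {
  sc <- load_hydrophobicity_scale()
  expect_equal(nrow(sc), 20)
  expect_true(all(sc$H >= 0))
  cls <- residue_class(sc$resname)
  expect_lt(max(sc$H[cls == "H"]), min(sc$H[cls == "P"]))
  expect_lt(max(sc$H[cls == "P"]), min(sc$H[cls == "C"]))
  # maximum product sits at the parabola's upper root
  expect_equal(max(sc$H)^2, 11, tolerance = 0.05)
  expect_error(residue_hydropathy("XXX", "LEU", sc), "not in")
})

test_that("pair classes are order-insensitive and complete", {
  expect_equal(pair_class("LEU", "SER"), "HP")
  expect_equal(pair_class("SER", "LEU"), "HP")
  expect_equal(pair_class("ARG", "GLU"), "CC")
  expect_equal(pair_class("SER", "THR"), "PP")
  expect_true(is.na(pair_class("UNK", "LEU")))
  res20 <- surfcomp:::STANDARD_RESIDUES
  combos <- expand.grid(a = res20, b = res20)
  expect_setequal(
    unique(pair_class(as.character(combos$a), as.character(combos$b))),
    c("HH", "HP", "HC", "PP", "PC", "CC")
  )
})

test_that("neighbor selection matches a brute-force sort and breaks ties deterministically", {
  # 12 residues on a line: nearest 9 kept, in ascending distance
  df <- data.frame(x = rep(0:12, each = 2), y = rep(c(0, 0.2), 13), z = 0)
  cloud <- cloud_from_points(df)
  cloud$resnum <- rep(0:12, each = 2) + 1L
  nb <- select_neighbors(cloud, resnum = 1, k = 9, radius = 10)
  expect_equal(nb$resnum, 1:10) # self + the 9 nearest by distance
  expect_equal(nb$neighbor, 0:9)
  expect_true(all(diff(nb$dist) >= 0))

  # equal-distance tie -> lower residue number first
  df2 <- data.frame(x = c(0, -2, 2), y = 0, z = 0)
  c2 <- cloud_from_points(df2)
  c2$resnum <- c(5L, 9L, 2L)
  nb2 <- select_neighbors(c2, resnum = 5, k = 9, radius = 10)
  expect_equal(nb2$resnum, c(5L, 2L, 9L))

  # isolated residue: only neighbor 0 present
  df3 <- data.frame(x = c(0, 50), y = 0, z = 0)
  c3 <- cloud_from_points(df3)
  c3$resnum <- c(1L, 2L)
  expect_equal(nrow(select_neighbors(c3, 1)), 1)
})

test_that("feature matrices carry hand-computed hydropathy and pad missing neighbors", {
  cfg <- tiny_config(seed = 51)
  cx <- generate_complex(cfg, 1)
  iface <- detect_interface(cx$cloud_a, cx$cloud_b)
  core <- find_core_pairs(cx$cloud_a, cx$cloud_b, iface)
  sc <- load_hydrophobicity_scale()
  mat <- build_feature_matrix(
    cx$cloud_a, core$resnum_a[1], cx$cloud_b, core$resnum_b[1], sc,
    seed = 3
  )
  expect_equal(dim(mat), c(3, 10))
  nb <- select_neighbors(cx$cloud_b, core$resnum_b[1])
  resname_a <- core$resname_a[1]
  expected_h <- residue_hydropathy(rep(resname_a, nrow(nb)), nb$resname, sc)
  expect_equal(unname(mat["h", seq_len(nrow(nb))]), expected_h)
  if (nrow(nb) < 10) {
    expect_true(all(is.na(mat[, (nrow(nb) + 1):10])))
  }

  # optional 4th row holds neighbor centroid distances
  mat4 <- build_feature_matrix(
    cx$cloud_a, core$resnum_a[1], cx$cloud_b, core$resnum_b[1], sc,
    distance_row = TRUE, seed = 3
  )
  expect_equal(dim(mat4), c(4, 10))
  expect_equal(unname(mat4["d", seq_len(nrow(nb))]), unname(nb$dist))
})

test_that("feature column 0 equals the direct pair complementarities", {
  cfg <- tiny_config(seed = 61)
  ds <- generate_dataset(cfg)
  cx <- ds$complexes[[1]]
  pairs1 <- ds$pairs[ds$pairs$complex == 1, ][1:3, ]
  sc <- load_hydrophobicity_scale()
  ft <- build_pair_features(pairs1, cx$cloud_a, cx$cloud_b, sc, seed = 4)
  direct <- pair_complementarities(pairs1, cx$cloud_a, cx$cloud_b, sc, seed = 4)
  expect_equal(ft$s_0, direct$shape, tolerance = 1e-10)
  expect_equal(ft$e_0, direct$electrostatic, tolerance = 1e-10)
  expect_equal(ft$h_0, direct$hydropathy, tolerance = 1e-12)
})

test_that("residue complementarity is reproducible and respects the pair cap", {
  cfg <- tiny_config(seed = 71)
  cx <- generate_complex(cfg, 1)
  iface <- detect_interface(cx$cloud_a, cx$cloud_b)
  core <- find_core_pairs(cx$cloud_a, cx$cloud_b, iface)
  v1 <- residue_complementarity(
    cx$cloud_a, core$resnum_a[1], cx$cloud_b, core$resnum_b[1],
    kind = "shape", seed = 5
  )
  v2 <- residue_complementarity(
    cx$cloud_a, core$resnum_a[1], cx$cloud_b, core$resnum_b[1],
    kind = "shape", seed = 5
  )
  expect_identical(v1, v2)
  expect_gte(v1, 0)
})

test_that("min-max normalization scales, clips, pads and is idempotent", {
  ft <- tibble::tibble(label = c("core", "decoy", "core"))
  for (k in c("s", "e", "h")) {
    for (j in 0:9) ft[[paste0(k, "_", j)]] <- c(0, 5, 10)
  }
  norm <- normalize_features(ft)
  expect_equal(norm$s_3, c(0, 0.5, 1))
  stats <- attr(norm, "norm_stats")
  expect_equal(stats$min, rep(0, 3))
  expect_equal(stats$max, rep(10, 3))

  # test values beyond the training range are clipped and counted
  te <- ft
  te$s_0 <- c(-2, 5, 12)
  nte <- normalize_features(te, stats)
  expect_equal(nte$s_0, c(0, 0.5, 1))
  expect_equal(attr(nte, "n_clipped"), 2L)

  # padded (NA) entries become the worst-complementarity fill
  pad <- ft
  pad$e_9 <- c(NA, 5, NA)
  npad <- normalize_features(pad, stats)
  expect_equal(npad$e_9, c(1, 0.5, 1))

  # renormalizing with the same stats is a no-op
  expect_identical(normalize_features(norm, stats), norm)

  # zero range maps to 0 with a warning
  flat <- ft
  for (j in 0:9) flat[[paste0("h_", j)]] <- rep(4, 3)
  expect_warning(nflat <- normalize_features(flat), "zero range")
  expect_true(all(nflat$h_0 == 0))
})
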