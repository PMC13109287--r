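# Surface cloud I/O and interface geometry.

test_that("point-cloud reader parses both dialects and validates rows", {
  cloud <- plane_cloud(3)
  path <- withr::local_tempfile(fileext = ".pts")
  write_point_cloud(cloud, path)
  back <- read_point_cloud(path)
  expect_equal(nrow(back), 9)
  expect_equal(back$x, cloud$x)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_point_cloud(cloud, csv)
  expect_equal(read_point_cloud(csv)$z, cloud$z)

  gz <- withr::local_tempfile(fileext = ".pts.gz")
  write_point_cloud(cloud, gz)
  expect_equal(nrow(read_point_cloud(gz)), 9)

  # comments are skipped
  lines <- readLines(path)
  writeLines(c("# a comment", lines, "# another"), path)
  expect_equal(nrow(read_point_cloud(path)), 9)
})

test_that("malformed clouds are rejected with informative errors", {
  df <- as.data.frame(plane_cloud(2))
  expect_error(
    as_surface_cloud(df[setdiff(names(df), "potential")]),
    "potential",
    class = "surfcomp_format_error"
  )
  bad <- df
  bad$nx <- 0
  bad$ny <- 0
  bad$nz <- c(0, rep(1, nrow(bad) - 1))
  expect_error(
    as_surface_cloud(bad[seq_len(10)]),
    "row 1",
    class = "surfcomp_validation_error"
  )
})

test_that("nonstandard residues are flagged but retained; normals renormalized", {
  df <- as.data.frame(plane_cloud(2))
  df$resname[1] <- "XYZ"
  df$nx <- 0
  df$ny <- 0
  df$nz <- 3 # non-unit
  cloud <- as_surface_cloud(df)
  expect_true(cloud$nonstandard[1])
  expect_false(any(cloud$nonstandard[-1]))
  expect_equal(cloud$nz, rep(1, 4))
})

test_that("interface detection matches closed-form plane geometry", {
  a <- plane_cloud(8, z = 0, chain = "A")
  b <- plane_cloud(8, z = 5, chain = "B", up = FALSE)
  iface <- detect_interface(a, b)
  expect_equal(length(iface$a$indices), nrow(a)) # all points at 5 A
  expect_equal(length(iface$b$indices), nrow(b))

  far <- plane_cloud(8, z = 7, chain = "B", up = FALSE)
  expect_warning(iface7 <- detect_interface(a, far), "empty")
  expect_true(iface7$a$empty && iface7$b$empty)
})

test_that("interface membership is strict and per-point", {
  a <- cloud_from_points(data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 10)))
  a$resnum <- c(1L, 2L)
  b <- cloud_from_points(data.frame(x = 0, y = 0, z = 4), chain = "B")
  iface <- detect_interface(a, b)
  expect_equal(iface$a$indices, 1L) # only z=0 point is within 6 A
  expect_equal(iface$a$center, c(0, 0, 0))
  # boundary: exactly 6 A is excluded (strict <)
  b6 <- cloud_from_points(data.frame(x = 0, y = 0, z = 6), chain = "B")
  expect_warning(i6 <- detect_interface(a[1, ], b6), "empty")
  expect_true(i6$a$empty)
})

test_that("interface detection is symmetric in its arguments", {
  a <- random_cloud(120, "A", seed = 5)
  b <- random_cloud(100, "B", seed = 6)
  i1 <- detect_interface(a, b)
  i2 <- detect_interface(b, a)
  expect_identical(i1$a$indices, i2$b$indices)
  expect_identical(i1$b$indices, i2$a$indices)
})

test_that("interface matches the brute-force all-pairs oracle", {
  a <- random_cloud(300, "A", seed = 11)
  b <- random_cloud(250, "B", seed = 12)
  xyz <- function(cl) cbind(cl$x, cl$y, cl$z)
  d <- as.matrix(dist(rbind(xyz(a), xyz(b))))
  cross <- d[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b))]
  expect_equal(
    detect_interface(a, b)$a$indices,
    unname(which(apply(cross, 1, min) < 6))
  )
})

test_that("core pairs follow the 3 A / 5 A centroid rule on a toy system", {
  # residues as single-point 'centroids': A1 at origin-ish, A2 far;
  # B1 2 A from A1, B2 6 A from the center
  a <- cloud_from_points(data.frame(
    x = c(0, 0, 8, 8), y = 0, z = c(0, 0.5, 0, 0.5)
  ))
  a$resnum <- c(1L, 1L, 2L, 2L)
  b <- cloud_from_points(data.frame(
    x = c(0, 0, 8, 8), y = c(2, 2.5, 2, 2.5), z = 0
  ), chain = "B")
  b$resnum <- c(1L, 1L, 2L, 2L)
  iface <- detect_interface(a, b)
  core <- find_core_pairs(a, b, iface)
  # center ~ (4, 1.1, .2): A1/B1 centroids are > 3.9 A from it -> excluded;
  # exhaustive check against the rule
  ca <- residue_centroids(a)
  cb <- residue_centroids(b)
  expected <- 0L
  for (i in seq_len(nrow(ca))) {
    for (j in seq_len(nrow(cb))) {
      dij <- sqrt(sum((c(ca$x[i], ca$y[i], ca$z[i]) - c(cb$x[j], cb$y[j], cb$z[j]))^2))
      d_ci <- sqrt(sum((c(ca$x[i], ca$y[i], ca$z[i]) - iface$center)^2))
      d_cj <- sqrt(sum((c(cb$x[j], cb$y[j], cb$z[j]) - iface$center)^2))
      if (dij < 3 && d_ci < 5 && d_cj < 5) expected <- expected + 1L
    }
  }
  expect_equal(nrow(core), expected)
  expect_true(all(core$dist < 3))
})

test_that("core pairs are invariant under joint rigid motion", {
  cfg <- tiny_config(seed = 21)
  cx <- generate_complex(cfg, 1)
  iface <- detect_interface(cx$cloud_a, cx$cloud_b)
  core <- find_core_pairs(cx$cloud_a, cx$cloud_b, iface)

  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(3, -2, 5)
  rotate <- function(cloud) {
    xyz <- cbind(cloud$x, cloud$y, cloud$z) %*% R
    nrm <- cbind(cloud$nx, cloud$ny, cloud$nz) %*% R
    cloud$x <- xyz[, 1] + shift[1]
    cloud$y <- xyz[, 2] + shift[2]
    cloud$z <- xyz[, 3] + shift[3]
    cloud$nx <- nrm[, 1]
    cloud$ny <- nrm[, 2]
    cloud$nz <- nrm[, 3]
    cloud
  }
  a2 <- rotate(cx$cloud_a)
  b2 <- rotate(cx$cloud_b)
  core2 <- find_core_pairs(a2, b2, detect_interface(a2, b2))
  expect_equal(
    core[c("resnum_a", "resnum_b")],
    core2[c("resnum_a", "resnum_b")]
  )
})

test_that("decoy sampling is reproducible, balanced and outside the interface", {
  cfg <- tiny_config(seed = 31)
  cx <- generate_complex(cfg, 1)
  iface <- detect_interface(cx$cloud_a, cx$cloud_b)
  d1 <- sample_decoy_pairs(cx$cloud_a, cx$cloud_b, iface, n = 5, seed = 9)
  d2 <- sample_decoy_pairs(cx$cloud_a, cx$cloud_b, iface, n = 5, seed = 9)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 5)
  interfacial <- unique(cx$cloud_a$resnum[iface$a$indices])
  expect_false(any(d1$resnum_a %in% interfacial))

  expect_equal(nrow(sample_decoy_pairs(cx$cloud_a, cx$cloud_b, iface, n = 0)), 0)
  expect_warning(
    many <- sample_decoy_pairs(cx$cloud_a, cx$cloud_b, iface, n = 10000, seed = 1),
    "available"
  )
  expect_gt(nrow(many), 0)
})

test_that("annular composition fractions sum to one and count correctly", {
  # 2 H + 1 C + 1 P residues in one ring
  df <- data.frame(
    x = c(3, -3, 0, 0), y = c(0, 0, 3, -3), z = 0,
    resname = c("LEU", "VAL", "ARG", "SER")
  )
  df <- df[rep(1:4, each = 3), ]
  df$x <- df$x + rep(c(-0.1, 0, 0.1), 4)
  cloud <- cloud_from_points(df)
  cloud$resnum <- rep(1:4, each = 3)
  cloud$resname <- rep(c("LEU", "VAL", "ARG", "SER"), each = 3)
  ac <- annular_composition(cloud, center = c(0, 0, 0))
  ring <- ac[ac$n > 0, ]
  expect_equal(nrow(ring), 1)
  expect_equal(ring$f_H, 0.5)
  expect_equal(ring$f_C, 0.25)
  expect_equal(ring$f_P, 0.25)
  expect_true(all(abs(rowSums(ring[c("f_H", "f_P", "f_C")]) - 1) < 1e-12))
  expect_true(all(is.na(ac$f_H[ac$n == 0])))
})

test_that("all-hydrophobic cloud gives H frequency 1 in occupied rings", {
  cloud <- plane_cloud(6, resname = "ILE")
  ac <- annular_composition(cloud, center = c(3, 3, 0), max_radius = 10)
  occ <- ac[ac$n > 0, ]
  expect_true(all(occ$f_H == 1))
})

test_that("pair tables round-trip through TSV", {
  cfg <- tiny_config(seed = 41)
  ds <- generate_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(ds$pairs, path)
  back <- read_pair_table(path)
  expect_equal(back$resnum_a, ds$pairs$resnum_a)
  expect_equal(back$pair_class, ds$pairs$pair_class)
})
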