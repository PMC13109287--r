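# Synthetic protein-protein complex generator.
#
# Each chain is a surface point cloud over two disjoint planar disks: an
# interface disk shared by the two chains and a "far" disk carrying the
# non-interacting surface. Chain A's interface is a smooth random
# heightfield (sum of seeded Gaussian bumps); chain B's is the mating
# surface - the same heightfield offset by a small gap with opposite
# outward normals - mixed with an independent field at weight (1 - eta_s)
# plus vertical jitter. The far disks are offset +-far_offset laterally,
# always beyond the interface cutoff, and follow the same statistical
# process on both chains, so decoy residue pairs are exchangeable between
# chains and carry no planted signal. Standard residues are tiled only in
# the central residue_radius of each disk; the outer collar is filler
# surface assigned to a nonstandard UNK residue. The collar guarantees
# that every labeled residue - core, decoy, or neighbor - has a full,
# untruncated 9 A patch, removing footprint-truncation artifacts from the
# descriptor comparison. Interfacial electrostatic potentials are
# anti-correlated with coefficient -rho_el; residue classes follow a
# radial profile (hydrophobic core, charged rim; far-disk residues use
# the rim composition). Ground truth is known by construction, so every
# downstream stage can be tested against planted signal strengths.

#' Generator configuration
#'
#' Defaults define the package's reference study conditions: 50 complexes,
#' two 15 A surface disks per chain (interface and far) at 4 surface
#' points per square Angstrom, standard residues tiled in the central 6 A
#' of each disk (the collar is UNK filler surface so every labeled
#' residue has a full 9 A patch), a 2 A inter-surface gap, strong shape
#' complementarity (`eta_s = 0.9`), weak electrostatic anti-correlation
#' (`rho_el = 0.2`), and a hydrophobic-core / charged-rim composition
#' profile (H 80% -> 40%, C 2% -> 35% over `profile_range` = 6 A;
#' far-disk residues use the rim values).
#'
#' @param n_complexes Number of complexes.
#' @param density Surface points per square Angstrom.
#' @param surface_radius Radius of each surface disk in Angstrom.
#' @param residue_radius Radius of the central region tiled with standard
#'   residues; the collar beyond it is UNK filler surface.
#' @param far_offset Lateral displacement of the far disks (chain A at
#'   `+far_offset`, chain B at `-far_offset`); must keep them beyond the
#'   6 A interface cutoff.
#' @param eta_s Shape complementarity fidelity in `[0, 1]`: weight of the
#'   mirrored heightfield in chain B's interface (1 = perfect mirror).
#' @param rho_el Electrostatic anti-correlation in `[0, 1]`: interfacial
#'   A/B potentials correlate at `-rho_el`.
#' @param gap Inter-surface gap in Angstrom.
#' @param points_per_residue Mean surface points per residue tile.
#' @param h_core,h_rim,c_core,c_rim,profile_range Radial class profile:
#'   hydrophobic and charged frequencies at the interface center and at
#'   `profile_range` Angstrom (and beyond).
#' @param n_bumps,bump_amp,bump_sd_range Random heightfield parameters
#'   (per disk).
#' @param noise_z Vertical jitter on chain B's interface (Angstrom).
#' @param noise_potential Per-point potential noise (field units).
#' @param pairs_per_complex Cap on core pairs kept per complex (seeded
#'   subsample; keeps dataset-scale feature extraction affordable).
#' @param decoys_per_complex Decoy pairs per complex; `NULL` balances the
#'   core-pair count.
#' @param mirror_sampling Sample chain B's interface points at exactly
#'   chain A's planar positions (the exact-complementarity limit used in
#'   self-complementarity checks).
#' @param seed Master seed; complex i uses a derived sub-seed.
#' @return A `generator_config` list (also records the derived
#'   `points_per_chain` and `interface_fraction`).
#' @export
generator_config <- function(n_complexes = 50L, density = 4,
                             surface_radius = 15, residue_radius = 6,
                             far_offset = 44,
                             eta_s = 0.8, rho_el = 0.4, gap = 2.0,
                             points_per_residue = 18L,
                             h_core = 0.85, h_rim = 0.40,
                             c_core = 0.01, c_rim = 0.35,
                             profile_range = 6,
                             n_bumps = 24L, bump_amp = 1.2,
                             bump_sd_range = c(1.5, 3),
                             noise_z = 0.1, noise_potential = 0.25,
                             pairs_per_complex = 12L,
                             decoys_per_complex = NULL,
                             mirror_sampling = FALSE,
                             seed = 1337L) {
  stopifnot(
    eta_s >= 0, eta_s <= 1, rho_el >= -1, rho_el <= 1,
    gap > 0, h_core + c_core < 1, h_rim + c_rim < 1,
    residue_radius < surface_radius,
    far_offset > 2 * surface_radius + 6
  )
  cfg <- as.list(environment())
  cfg$points_per_chain <- round(2 * density * pi * surface_radius^2)
  cfg$interface_fraction <- 0.5
  structure(cfg, class = "generator_config")
}

# smooth random field: sum of Gaussian bumps with analytic gradient
random_field <- function(n_bumps, amp, sd_range, radius, center = c(0, 0)) {
  cx <- center[1] + runif(n_bumps, -radius, radius)
  cy <- center[2] + runif(n_bumps, -radius, radius)
  a <- rnorm(n_bumps, 0, amp)
  s <- runif(n_bumps, sd_range[1], sd_range[2])
  list(
    value = function(x, y) {
      out <- numeric(length(x))
      for (j in seq_len(n_bumps)) {
        out <- out + a[j] * exp(-((x - cx[j])^2 + (y - cy[j])^2) / (2 * s[j]^2))
      }
      out
    },
    grad = function(x, y) {
      gx <- numeric(length(x))
      gy <- numeric(length(x))
      for (j in seq_len(n_bumps)) {
        e <- a[j] * exp(-((x - cx[j])^2 + (y - cy[j])^2) / (2 * s[j]^2))
        gx <- gx - e * (x - cx[j]) / s[j]^2
        gy <- gy - e * (y - cy[j]) / s[j]^2
      }
      cbind(gx, gy)
    }
  )
}

# contiguous residue tiles from a seeded k-means on planar positions
tile_residues <- function(x, y, points_per_residue) {
  k <- max(2L, round(length(x) / points_per_residue))
  km <- suppressWarnings(
    stats::kmeans(cbind(x, y), centers = k, iter.max = 30L, nstart = 1L)
  )
  list(resnum = km$cluster, centers = km$centers)
}

# radial H/P/C class profile; r is the effective distance from the
# interface center (far-disk residues are mapped to the rim)
sample_classes <- function(r, cfg) {
  t <- pmin(r / cfg$profile_range, 1)
  p_h <- cfg$h_core + (cfg$h_rim - cfg$h_core) * t
  p_c <- cfg$c_core + (cfg$c_rim - cfg$c_core) * t
  p_p <- 1 - p_h - p_c
  vapply(seq_along(r), function(i) {
    sample(c("H", "P", "C"), 1L, prob = c(p_h[i], p_p[i], p_c[i]))
  }, character(1))
}

class_members <- function() {
  if (is.null(the$class_members)) {
    the$class_members <- split(names(RESIDUE_CLASS_MAP), RESIDUE_CLASS_MAP)
  }
  the$class_members
}

#' Generate one synthetic complex
#'
#' @param config A [generator_config()].
#' @param index Complex index (drives the derived sub-seed).
#' @return List with `cloud_a`, `cloud_b` (validated `surface_cloud`s) and
#'   `truth` (planted parameters: sub-seed, interface radius, gap, signal
#'   strengths).
#' @export
generate_complex <- function(config, index = 1L) {
  cfg <- config
  sub_seed <- derive_seed(cfg$seed, "complex", index)
  with_seed(sub_seed, {
    n_disk <- round(cfg$density * pi * cfg$surface_radius^2)
    # interface fields (shared between chains); far fields are per chain
    f <- random_field(cfg$n_bumps, cfg$bump_amp, cfg$bump_sd_range, cfg$surface_radius)
    g <- random_field(cfg$n_bumps, cfg$bump_amp, cfg$bump_sd_range, cfg$surface_radius)
    u <- random_field(cfg$n_bumps, cfg$bump_amp, cfg$bump_sd_range, cfg$surface_radius)
    w <- random_field(cfg$n_bumps, cfg$bump_amp, cfg$bump_sd_range, cfg$surface_radius)

    sample_disk <- function(n, radius, center) {
      rr <- radius * sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
    }
    p_if_a <- sample_disk(n_disk, cfg$surface_radius, c(0, 0))
    p_if_b <- if (cfg$mirror_sampling) p_if_a else sample_disk(n_disk, cfg$surface_radius, c(0, 0))

    build_chain <- function(side) {
      if (side == "A") {
        p_if <- p_if_a
        far_center <- c(cfg$far_offset, 0)
        nz <- 1
      } else {
        p_if <- p_if_b
        far_center <- c(-cfg$far_offset, 0)
        nz <- -1
      }
      p_far <- sample_disk(n_disk, cfg$surface_radius, far_center)
      shape_far <- random_field(
        cfg$n_bumps, cfg$bump_amp, cfg$bump_sd_range,
        cfg$surface_radius, far_center
      )
      pot_far <- random_field(
        cfg$n_bumps, cfg$bump_amp, cfg$bump_sd_range,
        cfg$surface_radius, far_center
      )
      x <- c(p_if[, 1], p_far[, 1])
      y <- c(p_if[, 2], p_far[, 2])
      n_if <- nrow(p_if)
      n_far <- nrow(p_far)
      if (side == "A") {
        z_if <- f$value(p_if[, 1], p_if[, 2])
        gr_if <- f$grad(p_if[, 1], p_if[, 2])
        pot_if <- u$value(p_if[, 1], p_if[, 2])
      } else {
        z_if <- cfg$gap + cfg$eta_s * f$value(p_if[, 1], p_if[, 2]) +
          (1 - cfg$eta_s) * g$value(p_if[, 1], p_if[, 2]) +
          rnorm(n_if, 0, cfg$noise_z)
        gr_if <- cfg$eta_s * f$grad(p_if[, 1], p_if[, 2]) +
          (1 - cfg$eta_s) * g$grad(p_if[, 1], p_if[, 2])
        pot_if <- -cfg$rho_el * u$value(p_if[, 1], p_if[, 2]) +
          sqrt(max(1 - cfg$rho_el^2, 0)) * w$value(p_if[, 1], p_if[, 2])
      }
      z_far <- shape_far$value(p_far[, 1], p_far[, 2]) + if (side == "A") 0 else cfg$gap
      gr_far <- shape_far$grad(p_far[, 1], p_far[, 2])
      z <- c(z_if, z_far)
      gr <- rbind(gr_if, gr_far)
      pot <- c(pot_if, pot_far$value(p_far[, 1], p_far[, 2])) +
        rnorm(n_if + n_far, 0, cfg$noise_potential)
      # outward normal of a heightfield, flipped for the chain facing down
      nrm <- cbind(-gr[, 1] * nz, -gr[, 2] * nz, rep(nz, length(z)))
      nrm <- nrm / sqrt(rowSums(nrm^2))

      # standard residues tile the central region of each disk; the
      # collar is filler surface owned by one nonstandard UNK residue
      # per disk (full-patch support without truncated footprints)
      r_if_local <- sqrt(x[1:n_if]^2 + y[1:n_if]^2)
      r_far_local <- sqrt((x[n_if + 1:n_far] - far_center[1])^2 +
        (y[n_if + 1:n_far] - far_center[2])^2)
      r_local <- c(r_if_local, r_far_local)
      central <- r_local <= cfg$residue_radius
      resnum <- integer(length(x))
      resname <- character(length(x))
      next_res <- 1L
      for (disk in 1:2) {
        in_disk <- if (disk == 1) seq_len(n_if) else n_if + seq_len(n_far)
        core_idx <- in_disk[central[in_disk]]
        tiles <- tile_residues(x[core_idx], y[core_idx], cfg$points_per_residue)
        cen_r <- if (disk == 1) {
          sqrt(tiles$centers[, 1]^2 + tiles$centers[, 2]^2)
        } else {
          rep(cfg$profile_range, nrow(tiles$centers)) # far disk -> rim
        }
        cls <- sample_classes(cen_r, cfg)
        names_by_tile <- vapply(
          cls, function(cc) sample(class_members()[[cc]], 1L), character(1)
        )
        resnum[core_idx] <- next_res - 1L + tiles$resnum
        resname[core_idx] <- names_by_tile[tiles$resnum]
        next_res <- next_res + max(tiles$resnum)
        collar_idx <- setdiff(in_disk, core_idx)
        resnum[collar_idx] <- 9000L + disk
        resname[collar_idx] <- "UNK"
      }
      as_surface_cloud(data.frame(
        x = x, y = y, z = z,
        nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
        potential = pot,
        chain = side,
        resnum = resnum,
        resname = resname
      ))
    }

    list(
      cloud_a = build_chain("A"),
      cloud_b = build_chain("B"),
      truth = list(
        index = index, seed = sub_seed,
        interface_radius = cfg$surface_radius,
        gap = cfg$gap, eta_s = cfg$eta_s, rho_el = cfg$rho_el
      )
    )
  })
}

#' Generate a labeled synthetic dataset
#'
#' Builds `n_complexes` complexes, labels core-interacting pairs and decoy
#' pairs on each with the interface-geometry operations (6 A interface,
#' 3 A / 5 A core rule, decoys sampled outside the interface), and returns
#' the balanced pair table plus a manifest of per-complex seeds. A complex
#' whose geometry yields an empty interface or no core pairs is regenerated
#' with the next sub-seed (bounded retries).
#'
#' @param config A [generator_config()].
#' @param dir Optional output directory; clouds, pair table and manifest
#'   are written there when given.
#' @param max_retries Regeneration attempts per complex slot.
#' @return List with `complexes` (list of `generate_complex()` outputs),
#'   `pairs` (tibble with a `complex` column), and `manifest`.
#' @export
generate_dataset <- function(config, dir = NULL, max_retries = 5L) {
  complexes <- vector("list", config$n_complexes)
  pair_rows <- list()
  manifest_rows <- list()
  for (i in seq_len(config$n_complexes)) {
    done <- FALSE
    for (try_i in 0:max_retries) {
      idx <- i + try_i * 7919L
      cx <- generate_complex(config, index = idx)
      iface <- withCallingHandlers(
        detect_interface(cx$cloud_a, cx$cloud_b),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (iface$a$empty || iface$b$empty) next
      core <- find_core_pairs(cx$cloud_a, cx$cloud_b, iface)
      if (nrow(core) == 0) next
      if (!is.null(config$pairs_per_complex) &&
        nrow(core) > config$pairs_per_complex) {
        core <- with_seed(
          derive_seed(config$seed, "corecap", idx),
          core[sort(sample(nrow(core), config$pairs_per_complex)), ]
        )
      }
      n_dec <- config$decoys_per_complex %||% nrow(core)
      decoys <- withCallingHandlers(
        sample_decoy_pairs(cx$cloud_a, cx$cloud_b, iface,
          n = n_dec,
          seed = derive_seed(config$seed, "decoy", idx)
        ),
        warning = function(w) invokeRestart("muffleWarning")
      )
      cx$interface <- iface
      complexes[[i]] <- cx
      pairs_i <- dplyr::bind_rows(core, decoys)
      pairs_i$complex <- i
      pair_rows[[i]] <- pairs_i
      manifest_rows[[i]] <- tibble::tibble(
        complex = i, sub_seed = cx$truth$seed, index = idx,
        n_core = nrow(core), n_decoy = nrow(decoys)
      )
      done <- TRUE
      break
    }
    if (!done) {
      abort(paste0(
        "could not generate a usable complex for slot ", i,
        " after ", max_retries + 1L, " attempts"
      ))
    }
  }
  manifest <- list(
    config = unclass(config),
    complexes = dplyr::bind_rows(manifest_rows)
  )
  out <- list(
    complexes = complexes,
    pairs = dplyr::bind_rows(pair_rows),
    manifest = manifest
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(complexes)) {
      write_point_cloud(
        complexes[[i]]$cloud_a,
        file.path(dir, sprintf("complex%03d_A.pts", i))
      )
      write_point_cloud(
        complexes[[i]]$cloud_b,
        file.path(dir, sprintf("complex%03d_B.pts", i))
      )
    }
    utils::write.table(out$pairs, file.path(dir, "pairs.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    jsonlite::write_json(
      list(
        config = manifest$config,
        complexes = as.data.frame(manifest$complexes)
      ),
      file.path(dir, "manifest.json"),
      digits = NA, auto_unbox = TRUE
    )
  }
  out
}

#' Feature table for a generated dataset
#'
#' Runs [build_pair_features()] per complex (descriptor caches are
#' per-complex) and binds the rows, keeping the `complex` column.
#'
#' @param dataset Output of [generate_dataset()].
#' @param scale Hydrophobicity scale (default: shipped surrogate).
#' @param seed Subsampling seed.
#' @param ... Passed to [build_pair_features()].
#' @return Unnormalized feature tibble for all pairs of the dataset.
#' @export
build_dataset_features <- function(dataset, scale = load_hydrophobicity_scale(),
                                   seed = 1L, ...) {
  out <- lapply(seq_along(dataset$complexes), function(i) {
    cx <- dataset$complexes[[i]]
    pairs_i <- dataset$pairs[dataset$pairs$complex == i, ]
    if (nrow(pairs_i) == 0) {
      return(NULL)
    }
    ft <- build_pair_features(
      pairs_i, cx$cloud_a, cx$cloud_b, scale,
      seed = derive_seed(seed, "feat", i), ...
    )
    ft$complex <- i
    ft
  })
  dplyr::bind_rows(out)
}

#' Direct complementarities for a generated dataset
#'
#' [pair_complementarities()] per complex, bound into one tibble.
#'
#' @inheritParams build_dataset_features
#' @return `dataset$pairs` with `shape`, `electrostatic`, `hydropathy`
#'   columns.
#' @export
dataset_complementarities <- function(dataset, scale = load_hydrophobicity_scale(),
                                      seed = 1L, ...) {
  out <- lapply(seq_along(dataset$complexes), function(i) {
    cx <- dataset$complexes[[i]]
    pairs_i <- dataset$pairs[dataset$pairs$complex == i, ]
    if (nrow(pairs_i) == 0) {
      return(NULL)
    }
    pair_complementarities(
      pairs_i, cx$cloud_a, cx$cloud_b, scale,
      seed = derive_seed(seed, "comp", i), ...
    )
  })
  dplyr::bind_rows(out)
}
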