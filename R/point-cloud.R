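# Surface point-cloud data model and I/O.
#
# A cloud is the per-chain output of a molecular-surface program (one point
# per surface cell) with outward unit normals, a per-point electrostatic
# potential sampled onto the surface, and residue provenance. The package
# does not compute surfaces or potentials itself; this reader documents the
# expected upstream format.

CLOUD_COLUMNS <- c(
  "x", "y", "z", "nx", "ny", "nz", "potential", "chain", "resnum", "resname"
)

#' Build a validated surface point cloud from a data frame
#'
#' Checks the column contract, re-normalises normals, flags nonstandard
#' residue names, and stamps the chain identifier.
#'
#' @param df Data frame with columns `x y z nx ny nz potential chain resnum
#'   resname`.
#' @param chain Optional chain id; defaults to the (single) chain present.
#' @return A `surface_cloud` tibble with an extra logical column
#'   `nonstandard` and attribute `chain`.
#' @export
as_surface_cloud <- function(df, chain = NULL) {
  missing <- setdiff(CLOUD_COLUMNS, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "point cloud is missing column(s): ", paste(missing, collapse = ", ")
    ), class = "surfcomp_format_error")
  }
  df <- tibble::as_tibble(df)[CLOUD_COLUMNS]
  if (nrow(df) == 0) abort("point cloud is empty")
  for (col in c("x", "y", "z", "nx", "ny", "nz", "potential")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]])) {
      abort(paste0("non-numeric or missing values in column '", col, "'"),
        class = "surfcomp_format_error"
      )
    }
  }
  df$resnum <- as.integer(df$resnum)
  df$resname <- toupper(as.character(df$resname))
  df$chain <- as.character(df$chain)
  if (is.null(chain)) chain <- df$chain[1]
  if (!all(df$chain == chain)) {
    abort("all points in a cloud must share one chain id")
  }
  nlen <- sqrt(df$nx^2 + df$ny^2 + df$nz^2)
  bad <- which(nlen < 1e-12)
  if (length(bad) > 0) {
    abort(paste0(
      "zero-length normal at row ", bad[1],
      if (length(bad) > 1) paste0(" (and ", length(bad) - 1, " more)") else ""
    ), class = "surfcomp_validation_error")
  }
  df$nx <- df$nx / nlen
  df$ny <- df$ny / nlen
  df$nz <- df$nz / nlen
  df$nonstandard <- !(df$resname %in% STANDARD_RESIDUES)
  attr(df, "chain") <- chain
  class(df) <- c("surface_cloud", class(df))
  df
}

#' Read a surface point cloud from disk
#'
#' Accepts the whitespace-separated columnar text format
#' `x y z nx ny nz potential chain resnum resname` (lines starting with `#`
#' are comments) or a CSV dialect with a header row carrying the same column
#' names. Gzip-compressed files are read transparently. Normals are
#' re-normalised on load; rows with a zero-length normal raise a validation
#' error naming the row.
#'
#' @param path Path to the file.
#' @param format `"auto"` (sniff), `"columnar"` or `"csv"`.
#' @return A `surface_cloud` tibble; see [as_surface_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "columnar", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    first <- readLines(path, n = 25L, warn = FALSE)
    first <- first[!grepl("^\\s*#", first) & nzchar(trimws(first))]
    format <- if (length(first) > 0 && grepl(",", first[1])) "csv" else "columnar"
  }
  df <- if (format == "csv") {
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    utils::read.table(path,
      header = FALSE, comment.char = "#",
      col.names = CLOUD_COLUMNS, stringsAsFactors = FALSE
    )
  }
  as_surface_cloud(df)
}

#' Write a surface point cloud
#'
#' @param cloud A `surface_cloud`.
#' @param path Output path; `.csv` suffix selects the CSV dialect, anything
#'   else the whitespace columnar format. A `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path) {
  df <- as.data.frame(cloud)[CLOUD_COLUMNS]
  if (grepl("\\.csv(\\.gz)?$", path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  } else {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    writeLines(c(
      "# x y z nx ny nz potential chain resnum resname",
      do.call(paste, c(df, sep = " "))
    ), con)
    close(con)
  }
  invisible(path)
}

cloud_xyz <- function(cloud) {
  cbind(cloud$x, cloud$y, cloud$z)
}

cloud_normals <- function(cloud) {
  cbind(cloud$nx, cloud$ny, cloud$nz)
}

#' Residue centroids of a surface cloud
#'
#' Each residue is represented by the centroid of the surface points it
#' generates; these centroids define core-pair distances, neighbor
#' selection and annular composition.
#'
#' @param cloud A `surface_cloud`.
#' @return Tibble with `chain`, `resnum`, `resname`, `class`, centroid
#'   `x`,`y`,`z` and `n_points`.
#' @export
residue_centroids <- function(cloud) {
  key <- factor(cloud$resnum)
  sums <- rowsum(cbind(cloud$x, cloud$y, cloud$z), key)
  n <- as.vector(rowsum(rep(1, nrow(cloud)), key))
  resnum <- as.integer(levels(key))
  first <- match(levels(key), as.character(cloud$resnum))
  tibble::tibble(
    chain = cloud$chain[first],
    resnum = resnum,
    resname = cloud$resname[first],
    x = sums[, 1] / n, y = sums[, 2] / n, z = sums[, 3] / n,
    n_points = as.integer(n),
    class = residue_class(cloud$resname[first])
  ) |>
    dplyr::arrange(.data$resnum)
}

#' Read a residue-pair label table
#'
#' Tab-separated text with columns `chain_a resnum_a resname_a chain_b
#' resnum_b resname_b label`.
#'
#' @param path Path to the TSV file.
#' @return Tibble of pair labels with a `pair_class` column added.
#' @export
read_pair_table <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, comment.char = "#"
  )
  need <- c(
    "chain_a", "resnum_a", "resname_a",
    "chain_b", "resnum_b", "resname_b", "label"
  )
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "pair table is missing column(s): ", paste(missing, collapse = ", ")
    ), class = "surfcomp_format_error")
  }
  df <- tibble::as_tibble(df)
  df$pair_class <- pair_class(df$resname_a, df$resname_b)
  df
}

#' Write a residue-pair label table
#'
#' @param pairs Tibble of pairs (as produced by [find_core_pairs()] or
#'   [sample_decoy_pairs()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  cols <- c(
    "chain_a", "resnum_a", "resname_a",
    "chain_b", "resnum_b", "resname_b", "label"
  )
  utils::write.table(as.data.frame(pairs)[cols], path,
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
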