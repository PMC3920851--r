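# CT volume container and volume file I/O.
#
# A ct_volume is a 3-D scalar array plus per-axis voxel spacing (mm) and a
# world origin: the world position of voxel [i, j, k] (1-based) is
# origin + (i-1, j-1, k-1) * spacing, at the voxel center. All downstream
# geometry works in world mm so anisotropic spacing is handled uniformly.

#' Construct a CT volume
#'
#' @param data 3-D numeric array of intensities (arbitrary units).
#' @param spacing Numeric length-3 voxel spacing in mm, all positive.
#' @param origin World position (mm) of the center of voxel `[1, 1, 1]`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_hipwear("data must be a 3-D array", "hipwear_invalid_input")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop_hipwear("spacing must be 3 positive voxel sizes in mm",
                 "hipwear_format_error")
  }
  origin <- as_point3(origin, "origin")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, intensity range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

# World coordinates of the voxel-center grid along one axis.
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis]
}

# Trilinear interpolation of intensities at world points (n x 3 matrix, mm).
# Points outside the voxel-center bounding box return `outside` (default NA).
interp_trilinear <- function(vol, pts, outside = NA_real_) {
  d <- dim(vol$data)
  fx <- (pts[, 1] - vol$origin[1]) / vol$spacing[1]
  fy <- (pts[, 2] - vol$origin[2]) / vol$spacing[2]
  fz <- (pts[, 3] - vol$origin[3]) / vol$spacing[3]
  inb <- fx >= 0 & fx <= d[1] - 1 & fy >= 0 & fy <= d[2] - 1 &
    fz >= 0 & fz <= d[3] - 1
  out <- rep(outside, nrow(pts))
  if (!any(inb)) return(out)
  fx <- fx[inb]; fy <- fy[inb]; fz <- fz[inb]
  i0 <- pmin(floor(fx), d[1] - 2); wx <- fx - i0
  j0 <- pmin(floor(fy), d[2] - 2); wy <- fy - j0
  k0 <- pmin(floor(fz), d[3] - 2); wz <- fz - k0
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- 1 + i0 + j0 * nx + k0 * nxy
  v <- vol$data
  v000 <- v[base];             v100 <- v[base + 1]
  v010 <- v[base + nx];        v110 <- v[base + nx + 1]
  v001 <- v[base + nxy];       v101 <- v[base + nxy + 1]
  v011 <- v[base + nx + nxy];  v111 <- v[base + nx + nxy + 1]
  c00 <- v000 * (1 - wx) + v100 * wx
  c10 <- v010 * (1 - wx) + v110 * wx
  c01 <- v001 * (1 - wx) + v101 * wx
  c11 <- v011 * (1 - wx) + v111 * wx
  c0 <- c00 * (1 - wy) + c10 * wy
  c1 <- c01 * (1 - wy) + c11 * wy
  out[inb] <- c0 * (1 - wz) + c1 * wz
  out
}

#' Read a CT volume from file
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) and NRRD (`.nrrd`). Spatial metadata is
#' mandatory: a file without valid voxel spacing is rejected rather than
#' silently assumed to be 1 mm.
#'
#' @param path Path to the volume file.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop_hipwear(sprintf("volume file not found: %s", path),
                 "hipwear_format_error")
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    read_volume_nifti(path)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    read_volume_nrrd(path)
  } else {
    stop_hipwear(
      sprintf("unsupported volume format: %s (expected .nii, .nii.gz, .nrrd)",
              basename(path)),
      "hipwear_format_error")
  }
}

read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop_hipwear("expected a 3-D volume", "hipwear_format_error")
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (is.null(spacing) || length(spacing) < 3 || !all(is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop_hipwear("NIfTI file has missing or invalid voxel spacing",
                 "hipwear_format_error")
  }
  xf <- RNifti::xform(img)
  org <- xf[1:3, 4]
  data <- array(as.numeric(img), dim = dim(img))
  ct_volume(data, spacing = as.numeric(spacing), origin = as.numeric(org))
}

#' Write a CT volume to file
#'
#' Format is chosen from the extension: `.nii`/`.nii.gz` (NIfTI) or `.nrrd`
#' (NRRD, gzip-encoded raw). Spacing and origin round-trip exactly.
#'
#' @param vol A [ct_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    a <- vol$data
    attr(a, "pixdim") <- vol$spacing
    img <- RNifti::asNifti(a, datatype = "double")
    xf <- diag(4)
    diag(xf)[1:3] <- vol$spacing
    xf[1:3, 4] <- vol$origin
    img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_volume_nrrd(vol, path)
  } else {
    stop_hipwear(sprintf("unsupported volume format: %s", basename(path)),
                 "hipwear_format_error")
  }
  invisible(path)
}

# Minimal NRRD0004 writer: detached header is not used; data inline, gzip,
# little-endian doubles.
write_volume_nrrd <- function(vol, path) {
  d <- dim(vol$data)
  hdr <- c(
    "NRRD0004",
    "# Complete NRRD file format specification at:",
    "# http://teem.sourceforge.net/nrrd/format.html",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: gzip",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(memCompress(writeBin(as.numeric(vol$data), raw(),
                                size = 8, endian = "little"),
                       type = "gzip"),
           con)
  invisible(path)
}

read_volume_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) {
    stop_hipwear("not an NRRD file", "hipwear_format_error")
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) {
      stop_hipwear("truncated NRRD header", "hipwear_format_error")
    }
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(kv[2])]] <- kv[3]
  }
  need <- function(k) {
    if (is.null(fields[[k]])) {
      stop_hipwear(sprintf("NRRD header missing field '%s'", k),
                   "hipwear_format_error")
    }
    fields[[k]]
  }
  sizes <- as.integer(strsplit(trimws(need("sizes")), "\\s+")[[1]])
  if (length(sizes) != 3L) {
    stop_hipwear("only 3-D NRRD volumes are supported", "hipwear_format_error")
  }
  if (is.null(fields[["space directions"]])) {
    stop_hipwear("NRRD file has no 'space directions'; voxel spacing unknown",
                 "hipwear_format_error")
  }
  dirs <- regmatches(fields[["space directions"]],
                     gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
  dirmat <- t(vapply(dirs, function(s) {
    as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  }, numeric(3)))
  spacing <- sqrt(rowSums(dirmat^2))
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop_hipwear("NRRD file has invalid voxel spacing", "hipwear_format_error")
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  }
  type <- trimws(need("type"))
  encoding <- trimws(need("encoding"))
  n <- prod(sizes)
  payload <- readBin(con, raw(), n = file.size(path))
  if (encoding == "gzip") {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stop_hipwear(sprintf("unsupported NRRD encoding '%s'", encoding),
                 "hipwear_format_error")
  }
  endian <- if (!is.null(fields[["endian"]])) trimws(fields[["endian"]]) else "little"
  vals <- switch(type,
    "double" = readBin(payload, numeric(), n = n, size = 8, endian = endian),
    "float"  = readBin(payload, numeric(), n = n, size = 4, endian = endian),
    "short"  = readBin(payload, integer(), n = n, size = 2, endian = endian),
    "int"    = readBin(payload, integer(), n = n, size = 4, endian = endian),
    stop_hipwear(sprintf("unsupported NRRD type '%s'", type),
                 "hipwear_format_error"))
  ct_volume(array(as.numeric(vals), dim = sizes), spacing = spacing,
            origin = origin)
}
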