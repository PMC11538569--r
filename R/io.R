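#' Write a height map as delimited text
#'
#' Tab-separated pixel-height matrix in millimetres, preceded by
#' comment lines recording the lens geometry.
#'
#' @param map a `"height_map"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_height_map <- function(map, path) {
  stopifnot(inherits(map, "height_map"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# holographic lens height map (mm)", con)
  writeLines(sprintf("# pixels: %d x %d, pixel_width_mm: %g",
                     nrow(map$heights), ncol(map$heights),
                     map$spec$pixel_width * 1e3), con)
  writeLines(sprintf("# base_thickness_mm: %g, h_max_mm: %g, quantized: %s",
                     map$spec$base_thickness * 1e3, map$spec$h_max * 1e3,
                     map$quantized), con)
  utils::write.table(format(map$heights * 1e3, trim = TRUE), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a pressure field as delimited text
#'
#' One row per sample: x, y, z (mm) and the real and imaginary parts
#' of the pressure (Pa).
#'
#' @param field a [pressure_field()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_field_txt <- function(field, path) {
  stopifnot(inherits(field, "pressure_field"))
  pts <- grid_points(field$grid)
  df <- data.frame(x_mm = pts[, 1] * 1e3, y_mm = pts[, 2] * 1e3,
                   z_mm = pts[, 3] * 1e3,
                   re_pa = Re(field$values), im_pa = Im(field$values))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Binary volume-field container
#'
#' Compact binary format for volume fields: an ASCII magic `"HFLD1"`,
#' then little-endian doubles for origin (3), spacing (3), frequency,
#' int32 shape (3), and the interleaved Re/Im samples (first grid axis
#' fastest).  [read_field_bin()] inverts it exactly.
#'
#' @param field a [pressure_field()] on a [volume_grid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_field_bin <- function(field, path) {
  stopifnot(inherits(field, "pressure_field"),
            inherits(field$grid, "volume_grid"))
  g <- field$grid
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("HFLD1"), con)
  writeBin(c(min(g$x), min(g$y), min(g$z), g$spacing, field$frequency),
           con, size = 8, endian = "little")
  writeBin(as.integer(g$shape), con, size = 4, endian = "little")
  writeBin(as.vector(rbind(Re(field$values), Im(field$values))),
           con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_field_bin
#' @export
read_field_bin <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 5L))
  if (magic != "HFLD1") stop("not a HFLD1 field container", call. = FALSE)
  hdr <- readBin(con, "double", 7L, size = 8, endian = "little")
  shape <- readBin(con, "integer", 3L, size = 4, endian = "little")
  n <- prod(shape)
  ri <- readBin(con, "double", 2L * n, size = 8, endian = "little")
  grid <- volume_grid(hdr[1] + c(0, (shape[1] - 1) * hdr[4]),
                      hdr[2] + c(0, (shape[2] - 1) * hdr[5]),
                      hdr[3] + c(0, (shape[3] - 1) * hdr[6]),
                      hdr[4:6])
  pressure_field(grid, complex(real = ri[c(TRUE, FALSE)],
                               imaginary = ri[c(FALSE, TRUE)]), hdr[7])
}

#' Write a line profile as two-column text
#'
#' @param profile a [line_profile()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "line_profile"))
  df <- data.frame(coordinate_mm = profile$profile$coordinate * 1e3,
                   amplitude = profile$profile$amplitude)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a quantized height map as a binary STL mesh
#'
#' Stereolithography export in millimetre units: one closed
#' 12-triangle box per pixel, each spanning the full column from the
#' lens bottom (z = 0) to `base_thickness + h`, `12 * n_pixels`
#' triangles in total.  The union of these closed solids is the
#' watertight lens (the shared base is covered because every column is
#' at least `base_thickness` tall); adjacent boxes share faces rather
#' than being merged into one surface — slicers handle unions of
#' closed solids, and the unmerged count keeps the writer
#' deterministic: re-export is byte-identical.  Unquantized maps are
#' refused (print on a 100 um grid what you designed on a 100 um
#' grid).
#'
#' @param map a quantized `"height_map"`.
#' @param path output `.stl` file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(map, path) {
  stopifnot(inherits(map, "height_map"))
  if (!map$quantized) {
    stop(paste("height map must be quantized before STL export;",
               "call quantize_heights() first"), call. = FALSE)
  }
  spec <- map$spec
  np <- spec$n_pixels
  dw <- spec$pixel_width * 1e3           # mm
  base <- spec$base_thickness * 1e3
  tris <- vector("list", prod(np))
  idx <- 1L
  for (j in seq_len(np[2])) {
    for (i in seq_len(np[1])) {
      x0 <- (i - 1 - np[1] / 2) * dw
      y0 <- (j - 1 - np[2] / 2) * dw
      h <- map$heights[i, j] * 1e3
      tris[[idx]] <- box_triangles(x0, y0, 0, x0 + dw, y0 + dw, base + h)
      idx <- idx + 1L
    }
  }
  tris <- do.call(rbind, tris)
  ntri <- nrow(tris) / 3L
  # 12 floats per record: normal + three vertices
  rec <- matrix(0, 12L, ntri)
  for (t in seq_len(ntri)) {
    v <- tris[(3 * t - 2):(3 * t), , drop = FALSE]
    rec[, t] <- c(tri_normal(v), t(v))
  }
  fl <- writeBin(as.numeric(rec), raw(), size = 4, endian = "little")
  fl <- matrix(fl, 48L, ntri)
  body <- as.vector(rbind(fl, matrix(as.raw(0), 2L, ntri)))
  con <- file(path, "wb"); on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "holofocus height map (mm)"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  writeBin(body, con)
  invisible(path)
}

# 12 triangles (36 vertex rows) of an axis-aligned box, outward winding
box_triangles <- function(x0, y0, z0, x1, y1, z1) {
  v <- rbind(c(x0, y0, z0), c(x1, y0, z0), c(x1, y1, z0), c(x0, y1, z0),
             c(x0, y0, z1), c(x1, y0, z1), c(x1, y1, z1), c(x0, y1, z1))
  faces <- rbind(
    c(1, 3, 2), c(1, 4, 3),   # bottom (-z)
    c(5, 6, 7), c(5, 7, 8),   # top (+z)
    c(1, 2, 6), c(1, 6, 5),   # -y
    c(2, 3, 7), c(2, 7, 6),   # +x
    c(3, 4, 8), c(3, 8, 7),   # +y
    c(4, 1, 5), c(4, 5, 8)    # -x
  )
  v[t(faces), , drop = FALSE][seq_len(36), ]
}

tri_normal <- function(v) {
  a <- v[2, ] - v[1, ]; b <- v[3, ] - v[1, ]
  n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  nn <- sqrt(sum(n^2))
  if (nn == 0) c(0, 0, 0) else n / nn
}
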