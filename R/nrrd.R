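#' Write a voxel grid as NRRD
#'
#' Minimal NRRD writer for 3D scalar volumes: header fields `type`,
#' `dimension`, `sizes`, `space directions` (diagonal from the spacing),
#' `space origin`, `endian` and `encoding`. The canonical encoding is
#' `raw` little-endian doubles, which round-trips values, spacing and
#' origin bit-exactly; `ascii` is available for text-only storage.
#'
#' @param grid a `voxel_grid`.
#' @param path output path.
#' @param encoding `"raw"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, encoding = c("raw", "ascii")) {
  stopifnot(inherits(grid, "voxel_grid"))
  encoding <- match.arg(encoding)
  d <- dim(grid$values)
  hdr <- c(
    "NRRD0004",
    "# written by arcplan",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            grid$spacing[1], grid$spacing[2], grid$spacing[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    "endian: little",
    sprintf("encoding: %s", encoding),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(grid$values), con, size = 8, endian = "little")
  } else {
    writeLines(paste(format(as.numeric(grid$values), digits = 17),
                     collapse = " "), con)
  }
  invisible(path)
}

parse_nrrd_vectors <- function(s) {
  m <- gregexpr("\\(([^)]*)\\)", s)[[1]]
  parts <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(parts, function(p)
    as.numeric(strsplit(gsub("[()]", "", p), ",")[[1]]))
}

#' Read a 3D NRRD volume
#'
#' Supports the encodings and types this package writes (`raw` doubles /
#' unsigned ints, `ascii`). Non-3D files and malformed headers are
#' rejected with the offending field named.
#'
#' @param path NRRD file path.
#' @return A `voxel_grid`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD"))
    stop("not an NRRD file (bad magic): ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("malformed NRRD header (no blank line): ", path)
    if (ln == "") break
    if (startsWith(ln, "#")) next
    kv <- regmatches(ln, regexpr("^[^:]+", ln))
    fields[[trimws(kv)]] <- trimws(sub("^[^:]+:\\s*", "", ln))
  }
  need <- function(f) {
    if (is.null(fields[[f]])) stop("NRRD header of ", path,
                                   " is missing field '", f, "'")
    fields[[f]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop("expected a 3D volume in ", path, " (field 'dimension')")
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3 || any(is.na(sizes)) || any(sizes < 1))
    stop("bad 'sizes' field in ", path)
  dirs <- parse_nrrd_vectors(need("space directions"))
  spacing <- vapply(seq_len(3), function(k) dirs[[k]][k], numeric(1))
  origin <- parse_nrrd_vectors(need("space origin"))[[1]]
  type <- need("type")
  enc <- need("encoding")
  n <- prod(sizes)
  vals <- if (enc == "raw") {
    if (type == "double")
      readBin(con, what = "numeric", n = n, size = 8, endian = "little")
    else if (type %in% c("unsigned int", "uint32"))
      readBin(con, what = "integer", n = n, size = 4, endian = "little")
    else stop("unsupported NRRD type '", type, "' in ", path)
  } else if (enc == "ascii") {
    txt <- strsplit(paste(readLines(con), collapse = " "), "\\s+")[[1]]
    as.numeric(txt[nzchar(txt)])
  } else stop("unsupported NRRD encoding '", enc, "' in ", path)
  if (length(vals) != n) stop("NRRD data length mismatch in ", path)
  voxel_grid(array(as.numeric(vals), sizes), spacing, origin)
}

#' Write a structure set as a bit-encoded NRRD label map plus JSON table
#'
#' The ROIs of a structure set overlap (targets nest, organs abut the
#' target), so a single exclusive label map cannot hold them; instead each
#' ROI is assigned one bit of an unsigned integer label and the JSON side
#' table maps names to bits (and records which ROIs are derived).
#'
#' @param structs a `structure_set` (at most 31 ROIs).
#' @param path_nrrd,path_json output paths.
#' @return Invisibly, the name-to-bit table.
#' @export
write_structures <- function(structs, path_nrrd, path_json) {
  nm <- names(structs$masks)
  if (length(nm) > 31) stop("at most 31 ROIs per label map")
  lab <- array(0, structs$dims)
  for (i in seq_along(nm))
    lab <- lab + bitwShiftL(1L, i - 1L) * structs$masks[[i]]$voxels
  g <- voxel_grid(lab, structs$spacing, structs$origin)
  # write as raw unsigned ints
  d <- dim(g$values)
  hdr <- c("NRRD0004", "# written by arcplan", "type: unsigned int",
           "dimension: 3", "space: left-posterior-superior",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   g$spacing[1], g$spacing[2], g$spacing[3]),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   g$origin[1], g$origin[2], g$origin[3]),
           "endian: little", "encoding: raw", "")
  con <- file(path_nrrd, "wb")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.integer(g$values), con, size = 4, endian = "little")
  close(con)
  table <- list(rois = stats::setNames(as.list(seq_along(nm) - 1L), nm),
                derived = structs$derived)
  jsonlite::write_json(table, path_json, auto_unbox = TRUE, pretty = TRUE)
  invisible(table)
}

#' Read a bit-encoded structure set written by [write_structures()]
#' @param path_nrrd,path_json the label map and name table paths.
#' @return A `structure_set`.
#' @export
read_structures <- function(path_nrrd, path_json) {
  g <- read_volume(path_nrrd)
  table <- jsonlite::fromJSON(path_json)
  lab <- as.integer(g$values)
  masks <- lapply(names(table$rois), function(nm) {
    bit <- bitwShiftL(1L, table$rois[[nm]])
    roi_mask(nm, array(bitwAnd(lab, bit) > 0, dim(g$values)),
             g$spacing, g$origin)
  })
  s <- structure_set(masks)
  s$derived <- as.character(table$derived)
  s
}

#' Serialize an arc plan to JSON
#' @param plan an `arc_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  obj <- list(
    collimator_deg = plan$collimator_deg,
    isocenter_mm = plan$isocenter_mm,
    prescription_gy = plan$prescription_gy,
    machine = unclass(plan$machine),
    fluence_grid = plan$fluence_grid,
    control_points = lapply(plan$control_points, function(cp)
      list(gantry_deg = cp$gantry_deg, mu = cp$mu,
           leaf_left_mm = cp$leaf_left_mm, leaf_right_mm = cp$leaf_right_mm)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an arc plan from JSON written by [write_plan()]
#' @param path JSON path.
#' @return An `arc_plan`.
#' @export
read_plan <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  plan <- build_arc(o$isocenter_mm, n_cp = length(o$control_points),
                    collimator_deg = o$collimator_deg,
                    machine = do.call(beam_model, o$machine),
                    prescription_gy = o$prescription_gy)
  plan$control_points <- lapply(o$control_points, function(cp)
    list(gantry_deg = cp$gantry_deg, mu = cp$mu,
         leaf_left_mm = as.numeric(unlist(cp$leaf_left_mm)),
         leaf_right_mm = as.numeric(unlist(cp$leaf_right_mm))))
  if (!is.null(o$fluence_grid))
    plan$fluence_grid <- list(u = as.numeric(unlist(o$fluence_grid$u)),
                              v = as.numeric(unlist(o$fluence_grid$v)))
  plan
}
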