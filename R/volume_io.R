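# Volume and mesh I/O. All readers convert spacing to the canonical internal
# unit (mm) on request via spacing_mm(); spacing itself is stored as tagged.
# Axis order is never permuted silently: slices are stacked along array axis 1
# (U-D) in the order given, and every writer emits a sidecar recording the
# axis convention.

# Numeric-aware ascending filename sort: digit runs compare numerically, so
# "slice2" < "slice10" (matches numbered-bitmap export conventions).
numeric_aware_sort <- function(paths) {
  base <- basename(paths)
  pieces <- regmatches(base, gregexpr("[0-9]+|[^0-9]+", base))
  maxlen <- max(lengths(pieces))
  keys <- lapply(seq_len(maxlen), function(i) {
    part <- vapply(pieces, function(p) if (i <= length(p)) p[i] else "", "")
    num <- suppressWarnings(as.numeric(part))
    if (all(!is.na(num) | part == "")) {
      num[part == ""] <- -Inf
      num
    } else part
  })
  paths[do.call(order, keys)]
}

.sidecar_path <- function(path) {
  sub("\\.[A-Za-z0-9]+$", "", path[1]) |> paste0(".yaml")
}

.write_sidecar <- function(path, spacing, unit, type, label_count = NULL) {
  meta <- list(
    spacing = sprintf("%.17g", spacing),
    unit = unit,
    axes = as.list(NEST_AXES),
    axis_note = "axis1=UD (gravity toward -UD), axis2=BF (wall at low face), axis3=RL",
    type = type
  )
  if (!is.null(label_count)) meta$label_count <- as.integer(label_count)
  yaml::write_yaml(meta, path)
  path
}

.read_sidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  meta <- yaml::read_yaml(path)
  if (!is.null(meta$spacing)) meta$spacing <- as.numeric(meta$spacing)
  meta
}

# Minimal reader for uncompressed 8-bit BMP files (read-only support for
# numbered bitmap slice exports). The palette index is taken as the intensity,
# which is exact for grayscale-palette bitmaps.
read_bmp8 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path)
  le <- function(bytes) sum(as.integer(bytes) * 256^(seq_along(bytes) - 1))
  offset <- le(raw[11:14])
  width  <- le(raw[19:22])
  height <- le(raw[23:26])
  bitcount <- le(raw[29:30])
  compression <- le(raw[31:34])
  if (bitcount != 8L) stop("only 8-bit BMP supported (got ", bitcount, "-bit)")
  if (compression != 0L) stop("compressed BMP not supported")
  if (height > 2^30) stop("top-down BMP not supported")
  row_bytes <- ((width + 3) %/% 4) * 4
  px <- raw[(offset + 1):(offset + row_bytes * height)]
  m <- matrix(as.integer(px), nrow = row_bytes, ncol = height)[seq_len(width), , drop = FALSE]
  # BMP rows are stored bottom-up; flip so row 1 is the top row
  t(m)[height:1, , drop = FALSE]
}

.read_slice <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    if (!is.list(img)) img <- list(img)
    lapply(img, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1]  # take first channel
      m
    })
  } else if (ext == "bmp") {
    list(read_bmp8(path))
  } else {
    stop("unsupported slice format: .", ext)
  }
}

#' Read a volumetric image from a slice stack or volume file
#'
#' Accepts a directory of slice files (TIFF/BMP, sorted with numeric-aware
#' filename comparison), an explicit ordered vector of slice paths, a single
#' multipage TIFF, or a MetaImage `.mhd` header. Slices are stacked along
#' array axis 1 (U-D) in the given order. Spacing must come from the file
#' header (`.mhd`), a sidecar YAML written by [write_volume()], or the
#' `spacing` argument; a missing spacing is an explicit error, never a silent
#' default.
#'
#' @param paths Directory, ordered vector of slice files, or a single volume
#'   file.
#' @param spacing,unit Voxel spacing override (unit `"mm"` or `"um"`).
#' @param type `"image"` (default, 8-bit [voxel_volume()]), `"mask"` or
#'   `"label"`.
#' @return A `voxel_volume`, `mask_volume` or `label_volume`.
#' @export
read_stack <- function(paths, spacing = NULL, unit = "mm", type = c("image", "mask", "label")) {
  type <- match.arg(type)
  if (length(paths) == 1L && dir.exists(paths)) {
    files <- list.files(paths, pattern = "\\.(tif|tiff|bmp)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop("no slice files found in ", paths)
    paths <- numeric_aware_sort(files)
    sidecars <- list.files(dirname(paths[1]), pattern = "\\.ya?ml$", full.names = TRUE)
    sidecar <- if (length(sidecars)) .read_sidecar(sidecars[1]) else NULL
  } else {
    if (!all(file.exists(paths))) stop("unreadable file(s): ",
                                       paste(paths[!file.exists(paths)], collapse = ", "))
    sidecar <- .read_sidecar(.sidecar_path(paths[1]))
  }

  ext1 <- tolower(sub(".*\\.", "", paths[1]))
  if (ext1 == "mhd") {
    if (length(paths) != 1L) stop("a .mhd volume must be a single file")
    return(read_mhd(paths, type = type))
  }

  slices <- unlist(lapply(paths, .read_slice), recursive = FALSE)
  shapes <- vapply(slices, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("mixed slice shapes: ", paste(unique(shapes), collapse = " vs "))

  if (is.null(spacing)) {
    if (!is.null(sidecar$spacing)) {
      spacing <- sidecar$spacing
      unit <- sidecar$unit %||% "mm"
    } else {
      stop("voxel spacing not found in headers or sidecar; pass `spacing` explicitly")
    }
  }

  d2 <- dim(slices[[1]])
  data <- array(0L, dim = c(length(slices), d2[1], d2[2]))
  for (i in seq_along(slices)) data[i, , ] <- slices[[i]]

  if (type == "image") {
    if (max(data) > 255) stop("intensities exceed 8-bit range")
    voxel_volume(data, spacing, unit)
  } else if (type == "mask") {
    mask_volume(data > 0, spacing, unit)
  } else {
    label_volume(data, spacing, unit)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volume to disk
#'
#' Supported formats: multipage TIFF (`"tiff"`), a numbered TIFF slice stack
#' (`"tiff_stack"`, one file per U-D slice) and MetaImage (`"mhd"` header +
#' raw). A sidecar YAML carrying spacing (full precision), unit and the axis
#' convention is always written, so [read_stack()] round-trips data and
#' spacing bit-exactly. Label volumes are stored at the smallest unsigned
#' width (8 or 16 bit) that fits `label_count`.
#'
#' @param vol A `voxel_volume`, `mask_volume` or `label_volume`.
#' @param path Output file path (for `"tiff_stack"`: a directory).
#' @param format `"tiff"`, `"tiff_stack"` or `"mhd"`.
#' @return Invisibly, the written file paths.
#' @export
write_volume <- function(vol, path, format = c("tiff", "tiff_stack", "mhd")) {
  format <- match.arg(format)
  type <- switch(class(vol)[1],
                 voxel_volume = "image", mask_volume = "mask",
                 label_volume = "label",
                 stop("unsupported volume class"))
  data <- if (type == "mask") array(as.integer(vol$data), dim = dim(vol$data)) else vol$data
  maxval <- if (type == "label") max(1L, vol$label_count) else 255L
  if (type == "label" && vol$label_count > 65535L)
    stop("label_count exceeds 16-bit storage")
  bits <- if (maxval > 255L) 16L else 8L
  denom <- if (bits == 8L) 255 else 65535

  if (format == "mhd") {
    files <- write_mhd(vol, path)
    .write_sidecar(.sidecar_path(path), vol$spacing, vol$unit, type,
                   if (type == "label") vol$label_count)
    return(invisible(files))
  }

  if (format == "tiff") {
    pages <- lapply(seq_len(dim(data)[1]), function(i) data[i, , ] / denom)
    tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
    .write_sidecar(.sidecar_path(path), vol$spacing, vol$unit, type,
                   if (type == "label") vol$label_count)
    invisible(path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    n <- dim(data)[1]
    files <- file.path(path, sprintf("slice_%05d.tiff", seq_len(n)))
    for (i in seq_len(n))
      tiff::writeTIFF(data[i, , ] / denom, files[i], bits.per.sample = bits,
                      compression = "none")
    .write_sidecar(file.path(path, "stack.yaml"), vol$spacing, vol$unit, type,
                   if (type == "label") vol$label_count)
    invisible(files)
  }
}

# MetaImage writer: text .mhd header plus raw payload in array (column-major)
# order, i.e. DimSize is (UD, BF, RL) with UD fastest.
write_mhd <- function(vol, path) {
  type <- switch(class(vol)[1],
                 voxel_volume = "image", mask_volume = "mask", label_volume = "label")
  data <- if (type == "mask") as.integer(vol$data) else as.integer(vol$data)
  bits <- if (type == "label" && max(1L, vol$label_count) > 255L) 16L else 8L
  etype <- if (bits == 8L) "MET_UCHAR" else "MET_USHORT"
  rawpath <- sub("\\.mhd$", ".raw", path)
  s <- vol$spacing
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    paste("DimSize =", paste(dim(vol$data), collapse = " ")),
    sprintf("ElementSpacing = %.17g %.17g %.17g", s, s, s),
    paste("ElementSpacingUnit =", vol$unit),
    paste("ElementType =", etype),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("ElementDataFile =", basename(rawpath))
  )
  writeLines(hdr, path)
  writeBin(data, rawpath, size = bits %/% 8L, endian = "little")
  invisible(c(path, rawpath))
}

# MetaImage reader (subset sufficient to round-trip write_mhd output).
read_mhd <- function(path, type = c("image", "mask", "label")) {
  type <- match.arg(type)
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get <- function(k) vals[match(k, keys)]
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spc <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  if (length(unique(spc)) != 1L) stop("anisotropic spacing not supported")
  unit <- get("ElementSpacingUnit"); if (is.na(unit)) unit <- "mm"
  etype <- get("ElementType")
  size <- switch(etype, MET_UCHAR = 1L, MET_USHORT = 2L,
                 stop("unsupported ElementType: ", etype))
  rawpath <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(dims)
  data <- readBin(rawpath, "integer", n = n, size = size, signed = FALSE,
                  endian = "little")
  data <- array(data, dim = dims)
  switch(type,
         image = voxel_volume(data, spc[1], unit),
         mask = mask_volume(data > 0, spc[1], unit),
         label = label_volume(data, spc[1], unit))
}

#' Export a finite-element model as VTK or Abaqus input
#'
#' Writes node coordinates in mm and elements as 8-node hexahedra. Node sets
#' (pinned plus every load set) are emitted as named `*NSET` blocks in the
#' Abaqus variant and as 0/1 point-data arrays in legacy VTK. The VTK variant
#' also carries per-element scalar fields (element density plus anything in
#' `cell_data`).
#'
#' @param model An `fe_model` (see [build_model()]).
#' @param path Output path.
#' @param format `"vtk"` (legacy ASCII) or `"inp"` (Abaqus nodes/elements/nsets).
#' @param cell_data Optional named list of per-element numeric vectors (VTK
#'   only), e.g. the max-principal-stress field.
#' @return Invisibly, `path`.
#' @export
export_mesh <- function(model, path, format = c("vtk", "inp"), cell_data = NULL) {
  format <- match.arg(format)
  if (!inherits(model, "fe_model")) stop("model must be an fe_model")
  n_nodes <- nrow(model$nodes)
  n_elem <- nrow(model$elements)
  if (n_elem == 0L || n_nodes == 0L) stop("empty mesh")

  sets <- c(list(pinned = model$pinned_nodes),
            lapply(model$load_sets, `[[`, "nodes"))

  if (format == "vtk") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0",
                 "nestmech voxel-hexahedral mesh (mm)",
                 "ASCII", "DATASET UNSTRUCTURED_GRID",
                 sprintf("POINTS %d float", n_nodes)), con)
    writeLines(sprintf("%.9g %.9g %.9g",
                       model$nodes[, 1], model$nodes[, 2], model$nodes[, 3]), con)
    writeLines(sprintf("CELLS %d %d", n_elem, n_elem * 9L), con)
    e0 <- model$elements - 1L
    writeLines(paste(8L, e0[, 1], e0[, 2], e0[, 3], e0[, 4],
                     e0[, 5], e0[, 6], e0[, 7], e0[, 8]), con)
    writeLines(sprintf("CELL_TYPES %d", n_elem), con)
    writeLines(as.character(rep(12L, n_elem)), con)
    cd <- c(list(density = model$material$density_field), cell_data)
    cd <- Filter(Negate(is.null), cd)
    if (length(cd)) {
      writeLines(sprintf("CELL_DATA %d", n_elem), con)
      for (nm in names(cd)) {
        writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.9g", cd[[nm]]), con)
      }
    }
    writeLines(sprintf("POINT_DATA %d", n_nodes), con)
    for (nm in names(sets)) {
      flag <- integer(n_nodes); flag[sets[[nm]]] <- 1L
      writeLines(c(sprintf("SCALARS nset_%s int 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(as.character(flag), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("*HEADING", "nestmech voxel-hexahedral mesh (units: mm, N, MPa)",
                 "*NODE"), con)
    writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(n_nodes),
                       model$nodes[, 1], model$nodes[, 2], model$nodes[, 3]), con)
    writeLines("*ELEMENT, TYPE=C3D8", con)
    e <- model$elements
    writeLines(paste0(seq_len(n_elem), ", ",
                      e[, 1], ", ", e[, 2], ", ", e[, 3], ", ", e[, 4], ", ",
                      e[, 5], ", ", e[, 6], ", ", e[, 7], ", ", e[, 8]), con)
    for (nm in names(sets)) {
      writeLines(sprintf("*NSET, NSET=%s", toupper(nm)), con)
      ids <- sets[[nm]]
      rows <- split(ids, ceiling(seq_along(ids) / 16))
      writeLines(vapply(rows, paste, "", collapse = ", "), con)
    }
  }
  invisible(path)
}

# Minimal legacy-VTK reader (points/cells only), used to verify exports.
read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS ", lines)[1]
  n_nodes <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- do.call(rbind, lapply(lines[(ip + 1):(ip + n_nodes)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  ic <- grep("^CELLS ", lines)[1]
  n_elem <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cells <- do.call(rbind, lapply(lines[(ic + 1):(ic + n_elem)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]])[-1] + 1L))
  list(n_nodes = n_nodes, n_elements = n_elem, points = pts, cells = cells)
}

# Parse *NSET blocks from an Abaqus .inp written by export_mesh().
read_inp_nsets <- function(path) {
  lines <- readLines(path)
  starts <- grep("^\\*NSET", lines)
  keywords <- grep("^\\*", lines)
  sets <- list()
  for (s in starts) {
    nm <- sub(".*NSET=", "", lines[s])
    nxt <- keywords[keywords > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    ids <- as.integer(unlist(strsplit(paste(lines[(s + 1):end], collapse = ","), ",")))
    sets[[nm]] <- ids[!is.na(ids)]
  }
  sets
}
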