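# File formats: 32-bit float / 8-bit label multi-page TIFF with JSON
# sidecars, JSON-lines traces, ImageJ ROI archives, cells CSV.
#
# Reading TIFFs uses the tiff package. Writing goes through a minimal
# uncompressed little-endian TIFF writer because float pages of arbitrary
# range are needed (phase in radians is not confined to [0, 1]).

# ---- TIFF writing ---------------------------------------------------------

# pages: list of matrices. type: "float32" or "uint8".
write_tiff_pages <- function(pages, path, type = c("float32", "uint8")) {
  type <- match.arg(type)
  stopifnot(length(pages) >= 1)
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  # header: II, magic 42, first IFD offset (filled in layout below)
  bps <- if (type == "float32") 32L else 8L
  sfmt <- if (type == "float32") 3L else 1L
  sizes <- vapply(pages, function(p) length(p) * (bps / 8L), numeric(1))
  # layout: header(8) | page1 data | page1 IFD | page2 data | ...
  n_tags <- 10L
  ifd_len <- 2 + 12 * n_tags + 4
  offs_data <- numeric(length(pages)); offs_ifd <- numeric(length(pages))
  pos <- 8
  for (i in seq_along(pages)) {
    offs_data[i] <- pos; pos <- pos + sizes[i]
    offs_ifd[i] <- pos;  pos <- pos + ifd_len
  }
  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42L); w4(offs_ifd[1])
  tag <- function(id, typ, count, value) {
    w2(id); w2(typ); w4(count)
    if (typ == 3L && count == 1L) { w2(value); w2(0L) } else w4(value)
  }
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    stopifnot(is.matrix(p))
    # pixel data, row-major
    v <- as.vector(t(p))
    if (type == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      if (any(v < 0 | v > 255)) stop("uint8 page values must be in [0, 255]", call. = FALSE)
      writeBin(as.raw(as.integer(round(v))), con)
    }
    w2(n_tags)
    tag(256L, 4L, 1L, ncol(p))          # ImageWidth
    tag(257L, 4L, 1L, nrow(p))          # ImageLength
    tag(258L, 3L, 1L, bps)              # BitsPerSample
    tag(259L, 3L, 1L, 1L)               # Compression: none
    tag(262L, 3L, 1L, 1L)               # Photometric: BlackIsZero
    tag(273L, 4L, 1L, offs_data[i])     # StripOffsets
    tag(277L, 3L, 1L, 1L)               # SamplesPerPixel
    tag(278L, 4L, 1L, nrow(p))          # RowsPerStrip
    tag(279L, 4L, 1L, sizes[i])         # StripByteCounts
    tag(339L, 3L, 1L, sfmt)             # SampleFormat
    w4(if (i < length(pages)) offs_ifd[i + 1] else 0L)
  }
  invisible(path)
}

read_tiff_pages <- function(path) {
  pg <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pg)) pg <- list(pg)
  pg
}

# ---- interferogram stacks -------------------------------------------------

#' Write / read a four-frame interferogram stack
#'
#' The stack is stored as a grayscale 32-bit float multi-page TIFF with page
#' order (z0 f0, z0 f1, z0 f2, z0 f3, z1 f0, ...) plus a JSON metadata
#' sidecar (`<path>.json`) carrying `wavelength_um`, `shear_um`,
#' `voxel_um`, `phase_shifts`, `seed`, and the grid shape.
#'
#' @param stack A `glim_stack`.
#' @param path TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "glim_stack"))
  d <- dim(stack$frames)
  pages <- vector("list", d[3] * 4)
  for (z in seq_len(d[3])) for (n in 1:4) {
    pages[[(z - 1) * 4 + n]] <- stack$frames[, , z, n]
  }
  write_tiff_pages(pages, path, "float32")
  cfg <- stack$config
  meta <- list(wavelength_um = cfg$wavelength, shear_um = cfg$shear_um,
               voxel_um = cfg$voxel_um, phase_shifts = cfg$phase_shifts,
               axial_psf_um = cfg$axial_psf_um, na = cfg$na,
               seed = cfg$seed, shape = d[1:3], n_frames = 4L)
  jsonlite::write_json(meta, sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar <- function(path) paste0(path, ".json")

read_stack_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("metadata sidecar %s not found", path), call. = FALSE)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("wavelength_um", "shear_um", "voxel_um")
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    stop(sprintf("metadata missing required field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (length(meta$voxel_um) != 3) stop("voxel_um must have 3 entries", call. = FALSE)
  meta
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- read_stack_metadata(sidecar(path))
  pg <- read_tiff_pages(path)
  if (length(pg) %% 4 != 0) {
    stop(sprintf("page count %d is not a multiple of 4 frames", length(pg)), call. = FALSE)
  }
  nz <- length(pg) / 4
  d <- dim(pg[[1]])
  if (!is.null(meta$shape) && !all(unlist(meta$shape) == c(d, nz))) {
    stop(sprintf("TIFF shape %s does not match metadata shape %s",
                 paste(c(d, nz), collapse = "x"),
                 paste(unlist(meta$shape), collapse = "x")), call. = FALSE)
  }
  frames <- array(0, dim = c(d, nz, 4))
  for (z in seq_len(nz)) for (n in 1:4) frames[, , z, n] <- pg[[(z - 1) * 4 + n]]
  cfg <- acquisition_config(wavelength = meta$wavelength_um,
                            shear_um = meta$shear_um,
                            voxel_um = unlist(meta$voxel_um),
                            axial_psf_um = meta$axial_psf_um %||% 1.5,
                            na = meta$na %||% 0.75,
                            seed = meta$seed %||% 1L)
  structure(list(frames = frames, config = cfg), class = "glim_stack")
}

# ---- phase tomograms ------------------------------------------------------

#' Write / read a phase tomogram
#'
#' 32-bit float multi-page TIFF (one page per z, radians) with a JSON
#' provenance sidecar.
#' @param phase A `glim_phase`.
#' @param path TIFF path.
#' @export
write_tomogram <- function(phase, path) {
  stopifnot(inherits(phase, "glim_phase"))
  phi <- phase$phi
  if (length(dim(phi)) == 2) dim(phi) <- c(dim(phi), 1)
  pages <- lapply(seq_len(dim(phi)[3]), function(z) phi[, , z])
  write_tiff_pages(pages, path, "float32")
  meta <- c(list(voxel_um = phase$voxel_um, shape = dim(phi), kind = "phase_rad"),
            phase$provenance)
  jsonlite::write_json(meta, sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tomogram
#' @export
read_tomogram <- function(path) {
  meta <- jsonlite::read_json(sidecar(path), simplifyVector = TRUE)
  if (is.null(meta$voxel_um)) stop("metadata missing voxel_um", call. = FALSE)
  pg <- read_tiff_pages(path)
  d <- dim(pg[[1]])
  phi <- array(0, dim = c(d, length(pg)))
  for (z in seq_along(pg)) phi[, , z] <- pg[[z]]
  if (!is.null(meta$shape) && !all(unlist(meta$shape) == dim(phi))) {
    stop(sprintf("TIFF shape %s does not match metadata shape %s",
                 paste(dim(phi), collapse = "x"),
                 paste(unlist(meta$shape), collapse = "x")), call. = FALSE)
  }
  prov <- meta[setdiff(names(meta), c("voxel_um", "shape", "kind"))]
  new_phase(phi, unlist(meta$voxel_um), provenance = prov)
}

#' Write cell masks as an 8-bit label TIFF
#'
#' Refined masks are painted as labels 1..n in `cell_id` order (maximum 255
#' cells per tomogram) with a JSON sidecar mapping labels to cell ids.
#' @param masks List of refined `glim_mask` objects.
#' @param path TIFF path.
#' @export
write_masks <- function(masks, path) {
  stopifnot(length(masks) >= 1, length(masks) <= 255)
  d <- dim(masks[[1]]$coarse)
  lab <- array(0L, dim = d)
  for (i in seq_along(masks)) {
    m <- masks[[i]]$refined %||% masks[[i]]$coarse
    lab[m] <- i
  }
  pages <- lapply(seq_len(d[3]), function(z) lab[, , z])
  write_tiff_pages(pages, path, "uint8")
  jsonlite::write_json(
    list(labels = seq_along(masks),
         cell_id = vapply(masks, function(m) as.character(m$cell_id), character(1)),
         voxel_um = masks[[1]]$voxel_um, shape = d),
    sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- traces: JSON lines ---------------------------------------------------

#' Write / read traces as JSON lines
#'
#' One line per polygon: `{"cell_id": ..., "z": ..., "xy": [[x, y], ...]}`.
#' @param traces List of `glim_trace`.
#' @param path File path (conventionally `.jsonl`).
#' @export
write_traces <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in traces) {
    for (p in tr$polygons) {
      writeLines(jsonlite::toJSON(
        list(cell_id = tr$cell_id, z = p$z,
             xy = unname(apply(as.matrix(p$xy), 1, function(r) unname(as.numeric(r)), simplify = FALSE))),
        auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' @rdname write_traces
#' @param source Source tag attached to the traces read (default "manual").
#' @export
read_traces <- function(path, source = "manual") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  ids <- vapply(recs, function(r) as.character(r$cell_id), character(1))
  lapply(split(recs, factor(ids, levels = unique(ids))), function(rs) {
    polys <- lapply(rs, function(r) {
      xy <- if (is.matrix(r$xy)) r$xy else do.call(rbind, lapply(r$xy, as.numeric))
      list(z = r$z, xy = xy)
    })
    cell_trace(rs[[1]]$cell_id, polys, source = source)
  })
}

# ---- ImageJ ROI archives --------------------------------------------------

# Minimal ImageJ .roi (polygon) codec: big-endian, "Iout" magic, type 0,
# bounding box shorts, vertex shorts relative to (left, top).
encode_imagej_roi <- function(xy) {
  xy <- round(as.matrix(xy))
  left <- min(xy[, 1]); top <- min(xy[, 2])
  right <- max(xy[, 1]) + 1; bottom <- max(xy[, 2]) + 1
  n <- nrow(xy)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  ws <- function(x) writeBin(as.integer(x), con, size = 2, endian = "big")
  writeChar("Iout", con, nchars = 4, eos = NULL)
  ws(227)            # version
  writeBin(as.raw(c(0, 0)), con)  # type 0 = polygon, pad
  ws(c(top, left, bottom, right, n))
  writeBin(raw(64 - 18), con)     # unused header fields
  ws(xy[, 1] - left)
  ws(xy[, 2] - top)
  rawConnectionValue(con)
}

decode_imagej_roi <- function(raw_bytes) {
  con <- rawConnection(raw_bytes, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4)
  if (!identical(magic, "Iout")) stop("not an ImageJ ROI file", call. = FALSE)
  readBin(con, "integer", 1, size = 2, endian = "big")          # version
  type <- readBin(con, "integer", 1, size = 1)
  readBin(con, "integer", 1, size = 1)                          # pad
  if (!type %in% c(0L, 7L)) {  # polygon / freehand
    stop(sprintf("unsupported ROI type %d (only polygon traces)", type), call. = FALSE)
  }
  hdr <- readBin(con, "integer", 5, size = 2, endian = "big")   # top left bottom right n
  top <- hdr[1]; left <- hdr[2]; n <- hdr[5]
  readBin(con, "raw", 64 - 18)
  xs <- readBin(con, "integer", n, size = 2, endian = "big")
  ys <- readBin(con, "integer", n, size = 2, endian = "big")
  cbind(x = xs + left, y = ys + top)
}

# store-only ZIP writer (no compression): enough for ImageJ ROI archives.
write_zip_stored <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  # CRC32 is unsigned 32-bit; writeBin wants a signed int
  signed32 <- function(x) { x <- as.numeric(x); as.integer(x - (x >= 2^31) * 2^32) }
  w4 <- function(x) writeBin(signed32(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  offsets <- numeric(length(entries))
  pos <- 0
  for (i in seq_along(entries)) {
    name <- names(entries)[i]
    data <- entries[[i]]
    crc <- .crc32_cpp(data)
    offsets[i] <- pos
    writeBin(as.raw(c(0x50, 0x4b, 0x03, 0x04)), con)
    w2(20L); w2(0L); w2(0L); w2(0L); w2(0L)   # version, flags, method, time, date
    w4(crc); w4(length(data)); w4(length(data))
    w2(nchar(name, "bytes")); w2(0L)
    writeChar(name, con, eos = NULL)
    writeBin(data, con)
    pos <- pos + 30 + nchar(name, "bytes") + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    name <- names(entries)[i]
    data <- entries[[i]]
    writeBin(as.raw(c(0x50, 0x4b, 0x01, 0x02)), con)
    w2(20L); w2(20L); w2(0L); w2(0L); w2(0L); w2(0L)
    w4(.crc32_cpp(data)); w4(length(data)); w4(length(data))
    w2(nchar(name, "bytes")); w2(0L); w2(0L); w2(0L); w2(0L)
    w4(0L); w4(offsets[i])
    writeChar(name, con, eos = NULL)
    pos <- pos + 46 + nchar(name, "bytes")
  }
  writeBin(as.raw(c(0x50, 0x4b, 0x05, 0x06)), con)
  w2(0L); w2(0L); w2(length(entries)); w2(length(entries))
  w4(pos - cd_start); w4(cd_start); w2(0L)
  invisible(path)
}

#' Write / read traces as an ImageJ ROI archive
#'
#' Each polygon becomes one `.roi` entry named `<cellID>-z<INDEX>.roi`
#' (vertex coordinates are rounded to integer pixels, the ImageJ convention).
#' Reading accepts any zip of polygon/freehand ROIs following that naming
#' scheme.
#'
#' @param traces List of `glim_trace`.
#' @param path Archive path (`.zip`).
#' @export
write_roi_zip <- function(traces, path) {
  entries <- list()
  for (tr in traces) {
    for (p in tr$polygons) {
      nm <- sprintf("%s-z%d.roi", tr$cell_id, as.integer(p$z))
      entries[[nm]] <- encode_imagej_roi(p$xy)
    }
  }
  write_zip_stored(entries, path)
}

#' @rdname write_roi_zip
#' @param source Source tag for the traces read (default "manual").
#' @export
read_roi_zip <- function(path, source = "manual") {
  exdir <- tempfile("roizip")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  files <- files[grepl("\\.roi$", files)]
  if (!length(files)) stop("no .roi entries in archive", call. = FALSE)
  base <- basename(files)
  m <- regmatches(base, regexec("^(.*)-z([0-9]+)\\.roi$", base))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    stop(sprintf("ROI name(s) not matching <cellID>-z<INDEX>.roi: %s",
                 paste(base[bad], collapse = ", ")), call. = FALSE)
  }
  ids <- vapply(m, `[`, character(1), 2)
  zs <- as.integer(vapply(m, `[`, character(1), 3))
  lapply(split(seq_along(files), factor(ids, levels = unique(ids))), function(ii) {
    polys <- lapply(ii, function(i) {
      bytes <- readBin(files[i], "raw", file.size(files[i]))
      list(z = zs[i], xy = decode_imagej_roi(bytes))
    })
    cell_trace(ids[ii[1]], polys, source = source)
  })
}

# ---- tables ---------------------------------------------------------------

#' Write / read the per-cell record table as CSV
#' @param records Cell table tibble.
#' @param path CSV path (UTF-8, '.' decimal separator).
#' @export
write_cells <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8",
                                    stringsAsFactors = FALSE))
}

#' Read a cell grouping table
#'
#' CSV with columns `cell_id`, `animal_id`, `group` and optional `Vm_mV`,
#' `Rin_MOhm` pass-through columns.
#' @param path CSV path.
#' @export
read_groups <- function(path) {
  g <- tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8",
                                         stringsAsFactors = FALSE))
  req <- c("cell_id", "animal_id", "group")
  miss <- setdiff(req, names(g))
  if (length(miss)) {
    stop(sprintf("groups CSV missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  g
}
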