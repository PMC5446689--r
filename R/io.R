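# Readers/writers for the formats touched: TIFF volume stacks and masks,
# PNG/16-bit-TIFF renders, PNG or run-length text stroke rasters, and the
# YAML project configuration standing in for the GUI's scene description.
#
# Volumes travel as multi-page grayscale TIFF (pages = z); in memory they
# are (nx, ny, nz) arrays, so each page matrix (rows = y, cols = x) is
# transposed on the way in and out.  Integer round trips are lossless:
# 8-bit data live in 8-bit containers, 12- and 16-bit in 16-bit containers,
# with raw values preserved verbatim.

#' Read a TIFF stack as a raw integer volume
#'
#' @param path TIFF file (multi-page, pages = z, or a single page).
#' @param bit_depth declared bit depth (8, 12 or 16); values are validated
#'   against it -- 12-bit data in 16-bit containers is declared, never
#'   inferred from the data maximum.
#' @return integer array `(nx, ny, nz)` of raw intensities.
#' @export
read_volume <- function(path, bit_depth) {
  bit_depth <- check_bit_depth(bit_depth)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  for (k in seq_along(pages)) {
    if (length(dims[[k]]) != 2) {
      stop(sprintf("page %d of '%s' is not single-sample grayscale", k, path))
    }
    if (!identical(dims[[k]], dims[[1]])) {
      stop(sprintf("page %d of '%s' has mismatched size", k, path))
    }
  }
  nz <- length(pages)
  ny <- dims[[1]][1]
  nx <- dims[[1]][2]
  vol <- array(0L, c(nx, ny, nz))
  for (k in seq_len(nz)) vol[, , k] <- t(pages[[k]])
  full <- 2^bit_depth - 1
  mx <- max(vol)
  if (mx > full) {
    stop(sprintf("'%s': value %d exceeds the declared %d-bit maximum %d",
                 path, mx, bit_depth, full))
  }
  if (min(vol) < 0) stop(sprintf("'%s': negative intensity values", path))
  vol
}

#' Write a raw integer volume as a TIFF stack
#'
#' @param volume integer array `(nx, ny, nz)` of raw intensities.
#' @param path output path.
#' @param bit_depth 8, 12 or 16; 12-bit volumes are stored in 16-bit
#'   containers with values preserved (lossless round trip with
#'   [read_volume()]).
#' @export
write_volume <- function(volume, path, bit_depth) {
  bit_depth <- check_bit_depth(bit_depth)
  if (length(volume) == 0) stop("refusing to write an empty volume")
  if (length(dim(volume)) != 3) stop("volume must be a 3D array")
  full <- 2^bit_depth - 1
  if (max(volume) > full || min(volume) < 0) {
    stop("volume values outside the declared bit depth")
  }
  container_bits <- if (bit_depth == 8) 8L else 16L
  scale <- 2^container_bits - 1
  pages <- lapply(seq_len(dim(volume)[3]), function(k) t(volume[, , k]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = container_bits)
  invisible(path)
}

#' Write a rendered image
#'
#' 8-bit renders go to PNG; 10-bit renders to 16-bit TIFF with the 10-bit
#' code values (0..1023) stored verbatim in the 16-bit container.
#'
#' @param img quantized integer image from [quantize()] (H x W x 3).
#' @param path output path (`.png` or `.tif`/`.tiff`).
#' @param bits 8 or 10; must match the quantization.
#' @export
write_image <- function(img, path, bits = 8) {
  if (!bits %in% c(8, 10)) stop("bits must be 8 or 10")
  full <- 2^bits - 1
  if (max(img) > full || min(img) < 0) stop("image values exceed the quantization range")
  if (bits == 8) {
    png::writePNG(img / full, path)
  } else {
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Write / read a binary selection mask as an 8-bit TIFF stack (0/255)
#'
#' @param mask an `fv_mask` or logical 3D array.
#' @param path TIFF path.
#' @export
write_mask <- function(mask, path) {
  b <- if (inherits(mask, "fv_mask")) binary_mask(mask) else mask
  write_volume(array(255L * b, dim(b)), path, 8)
}

#' @rdname write_mask
#' @return `read_mask` returns a logical 3D array.
#' @export
read_mask <- function(path) {
  read_volume(path, 8) > 127
}

#' Read a brush-stroke raster
#'
#' Two encodings are supported.  A grayscale PNG encodes both stroke regions
#' in one image: pixel values >= 0.75 mark the seed region, values >= 0.25
#' the diffusion region (so white = seed + diffusion, mid-gray = diffusion
#' only, black = outside).  A run-length text file has a header line
#' `W H` followed by lines `row x0 x1` (zero-based, inclusive) for the
#' diffusion region and lines `S row x0 x1` for seed runs.
#'
#' @param path `.png` or `.txt` stroke file.
#' @param brush_type passed to [brush_stroke()].
#' @return an `fv_stroke`.
#' @export
read_stroke <- function(path, brush_type = "select") {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    seed <- img >= 0.75
    diff <- img >= 0.25
  } else {
    lines <- readLines(path)
    hd <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
    W <- hd[1]; H <- hd[2]
    seed <- matrix(FALSE, H, W)
    diff <- matrix(FALSE, H, W)
    for (ln in lines[-1]) {
      ln <- trimws(ln)
      if (!nzchar(ln)) next
      parts <- strsplit(ln, "\\s+")[[1]]
      is_seed <- identical(parts[1], "S")
      if (is_seed) parts <- parts[-1]
      v <- as.integer(parts)
      cols <- (v[2]:v[3]) + 1L
      diff[v[1] + 1L, cols] <- TRUE
      if (is_seed) seed[v[1] + 1L, cols] <- TRUE
    }
  }
  brush_stroke(seed, diff | seed, brush_type)
}

#' Load a YAML project configuration into a scene
#'
#' The project file is the scripting stand-in for an interactive session: it
#' lists channels (path, bit depth, spacing, per-channel render settings),
#' optional groups, the intermixing mode, camera, tone-mapping parameters
#' and streaming budget.  See the packaged example in the vignette.
#'
#' @param path YAML file.
#' @param base_dir directory against which relative channel paths resolve;
#'   defaults to the project file's directory.
#' @return list with `scene` (an `fv_scene`), `tone` ([tone_params()]),
#'   `budget` and `seed`.
#' @export
read_project <- function(path, base_dir = dirname(path)) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$channels) || length(cfg$channels) == 0) {
    stop("project must list at least one channel")
  }
  chans <- list()
  for (entry in cfg$channels) {
    p <- entry$path
    if (!file.exists(p)) p <- file.path(base_dir, entry$path)
    if (!file.exists(p)) stop(sprintf("channel file not found: %s", entry$path))
    bd <- entry$bit_depth %||% 8
    raw <- read_volume(p, bd)
    sp <- unlist(entry$spacing %||% c(1, 1, 1))
    st <- do.call(render_settings, entry$settings %||% list())
    nm <- entry$name %||% sub("\\.[^.]*$", "", basename(entry$path))
    chans[[nm]] <- channel(normalize_intensity(raw, bd), name = nm,
                           bit_depth = bd, spacing = sp, settings = st)
  }
  items <- list()
  used <- character(0)
  for (grp in cfg$groups %||% list()) {
    members <- chans[unlist(grp$members)]
    if (any(vapply(members, is.null, logical(1)))) {
      stop("group references an unknown channel")
    }
    items[[length(items) + 1L]] <- channel_group(members,
                                                 intermix_mode = grp$mode %||% "composite",
                                                 name = grp$name %||% "group")
    used <- c(used, unlist(grp$members))
  }
  for (nm in setdiff(names(chans), used)) items[[length(items) + 1L]] <- chans[[nm]]
  camcfg <- cfg$camera %||% list()
  box <- scene_box(items)
  cam <- ortho_camera(box,
                      view_direction = unlist(camcfg$view_direction %||% c(0, 0, 1)),
                      viewport = if (!is.null(camcfg$viewport)) unlist(camcfg$viewport) else NULL)
  scn <- scene(items,
               intermix_mode = cfg$scene$mode %||% "composite",
               camera = cam,
               background = unlist(cfg$scene$background %||% c(0, 0, 0)),
               sample_spacing = cfg$scene$sample_spacing %||% NULL,
               max_brick_dim = cfg$stream$max_brick_dim %||% 128)
  tn <- do.call(tone_params, cfg$tone %||% list())
  list(scene = scn, channels = chans, tone = tn,
       budget = cfg$stream$budget %||% Inf,
       segmentation = cfg$segmentation %||% list(),
       seed = cfg$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
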