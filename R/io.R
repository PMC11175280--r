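#' Read a labeled volume from NIfTI, MetaImage or NRRD
#'
#' Formats are recognized by extension: `.nii`/`.nii.gz` (via RNifti),
#' `.mha`/`.mhd` (MetaImage) and `.nrrd`. Voxels must be of an integer type;
#' floating-point volumes are rejected. On read the volume is normalized to
#' the package convention (axis-aligned grid, positive spacing, world = voxel
#' centers in mm): axes stored with a negative scale are flipped and the
#' origin adjusted, anything non-axis-aligned is an error. DICOM series are
#' deliberately not supported; convert to one of the research formats first.
#'
#' @param path file to read.
#' @param role_map named list mapping roles to integer labels, e.g.
#'   `list(skin = 1, liver = 2, tumor = 3, vessel = 4, bone = 5, lung = integer(0))`;
#'   a role mapped to a label absent from the file is a configuration error.
#' @return A [label_volume()].
#' @seealso [write_label_volume()], [read_role_map()]
#' @export
read_label_volume <- function(path, role_map) {
  if (!file.exists(path))
    npl_stop(sprintf("cannot read '%s': no such file", path), "npl_format_error")
  fmt <- .volume_format(path)
  raw <- switch(fmt,
    nifti = .read_nifti(path),
    metaimage = .read_metaimage(path),
    nrrd = .read_nrrd(path))
  label_volume(raw$labels, raw$grid, role_map)
}

#' Write a labeled volume
#'
#' The output format follows the file extension (see [read_label_volume()]).
#' Files written by this function read back with identical labels, spacing
#' and origin. MetaImage and NRRD are written uncompressed with 32-bit
#' little-endian integers; `.mhd` writes a sibling `.raw` file.
#'
#' @param volume a [label_volume()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  if (!dir.exists(dirname(path)))
    npl_stop(sprintf("directory '%s' does not exist", dirname(path)), "npl_io_error")
  fmt <- .volume_format(path)
  switch(fmt,
    nifti = .write_nifti(volume, path),
    metaimage = .write_metaimage(volume, path),
    nrrd = .write_nrrd(volume, path))
  invisible(path)
}

#' Read a role map from a JSON file
#'
#' The file is a single JSON object mapping role names to an integer label or
#' array of labels; an empty array marks the role as absent, e.g.
#' `{"skin": 1, "liver": 2, "tumor": 3, "vessel": [4, 7], "lung": []}`.
#'
#' @param path JSON file.
#' @return Named list of integer vectors.
#' @export
read_role_map <- function(path) {
  if (!file.exists(path))
    npl_stop(sprintf("cannot read role map '%s'", path), "npl_format_error")
  rm <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(rm) || is.null(names(rm)))
    npl_stop("role map must be a JSON object of role -> label(s)", "npl_format_error")
  lapply(rm, as.integer)
}

.volume_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", p)) return("nifti")
  if (grepl("\\.mh[ad]$", p)) return("metaimage")
  if (grepl("\\.nrrd$", p)) return("nrrd")
  npl_stop(sprintf("unrecognized volume format: '%s' (use .nii/.nii.gz, .mha/.mhd or .nrrd)", path),
           "npl_format_error")
}

# ---- NIfTI (RNifti) --------------------------------------------------------

.NIFTI_INT_TYPES <- c(2L, 4L, 8L, 256L, 512L, 768L, 1024L, 1280L)

.read_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) npl_stop(
                    sprintf("failed to parse NIfTI '%s': %s", path, conditionMessage(e)),
                    "npl_format_error"))
  hdr <- RNifti::niftiHeader(img)
  if (!hdr$datatype %in% .NIFTI_INT_TYPES)
    npl_stop(sprintf("'%s' has non-integer voxel type (datatype code %d)", path, hdr$datatype),
             "npl_type_error")
  arr <- array(as.integer(img), dim = dim(img))
  aff <- unclass(RNifti::xform(img))
  .normalize_affine(arr, aff[1:3, 1:4, drop = FALSE], path)
}

.write_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$labels)
  # the quaternion form takes its scales from pixdim, so set it explicitly
  RNifti::pixdim(img) <- volume$grid$spacing
  aff <- diag(c(volume$grid$spacing, 1))
  aff[1:3, 4] <- volume$grid$origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "int32")
}

# Flip axes with negative scale, reject non-axis-aligned direction matrices.
.normalize_affine <- function(arr, aff, path) {
  lin <- aff[, 1:3]
  spacing <- sqrt(colSums(lin^2))
  if (any(spacing <= 0))
    npl_stop(sprintf("'%s' has degenerate voxel spacing", path), "npl_format_error")
  for (a in 1:3) {
    on_axis <- abs(lin[a, a])
    off <- sqrt(sum(lin[, a]^2) - on_axis^2)
    if (off > 1e-4 * spacing[a])
      npl_stop(sprintf("'%s' is not axis-aligned; reorient it first", path),
               "npl_format_error")
  }
  origin <- aff[, 4]
  for (a in 1:3) {
    if (lin[a, a] < 0) {
      arr <- .flip_axis(arr, a)
      origin[a] <- origin[a] + lin[a, a] * (dim(arr)[a] - 1L)
    }
  }
  list(labels = arr,
       grid = voxel_grid(dim(arr), spacing = spacing, origin = origin))
}

.flip_axis <- function(arr, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(arr)[axis]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# ---- MetaImage -------------------------------------------------------------

.MET_TYPES <- list(
  MET_CHAR   = list(size = 1L, signed = TRUE),
  MET_UCHAR  = list(size = 1L, signed = FALSE),
  MET_SHORT  = list(size = 2L, signed = TRUE),
  MET_USHORT = list(size = 2L, signed = FALSE),
  MET_INT    = list(size = 4L, signed = TRUE),
  MET_UINT   = list(size = 4L, signed = TRUE))  # uint32 read as int32; labels are small

.read_metaimage <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  # header ends at the newline terminating the ElementDataFile line; only that
  # region is text (the rest is binary payload)
  m <- grepRaw("ElementDataFile", bytes, fixed = TRUE)
  if (!length(m))
    npl_stop(sprintf("'%s': no ElementDataFile key; not a MetaImage header", path),
             "npl_format_error")
  nl <- which(bytes[m:length(bytes)] == as.raw(10L))[1]
  if (is.na(nl))
    npl_stop(sprintf("'%s': unterminated MetaImage header", path), "npl_format_error")
  header_end <- m + nl - 1L
  hdr <- .parse_kv(rawToChar(bytes[1:header_end]), sep = "=")
  if (is.null(hdr$ndims) || as.integer(hdr$ndims) != 3L)
    npl_stop(sprintf("'%s': only 3-D MetaImage volumes are supported", path),
             "npl_format_error")
  if (!is.null(hdr$compresseddata) && tolower(hdr$compresseddata) == "true")
    npl_stop(sprintf("'%s': compressed MetaImage is not supported", path),
             "npl_format_error")
  et <- toupper(hdr$elementtype %||% "")
  if (grepl("FLOAT|DOUBLE", et))
    npl_stop(sprintf("'%s' has non-integer voxel type (%s)", path, et), "npl_type_error")
  spec <- .MET_TYPES[[et]]
  if (is.null(spec))
    npl_stop(sprintf("'%s': unsupported ElementType '%s'", path, et), "npl_format_error")
  if (!is.null(hdr$transformmatrix)) {
    tm <- as.numeric(strsplit(trimws(hdr$transformmatrix), "\\s+")[[1]])
    if (max(abs(tm - as.vector(diag(3)))) > 1e-4)
      npl_stop(sprintf("'%s' is not axis-aligned; reorient it first", path),
               "npl_format_error")
  }
  shape <- as.integer(strsplit(trimws(hdr$dimsize), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(hdr$elementspacing %||% "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(hdr$offset %||% "0 0 0"), "\\s+")[[1]])
  msb <- tolower(hdr$binarydatabyteordermsb %||% hdr$elementbyteordermsb %||% "false") == "true"
  datafile <- trimws(hdr$elementdatafile)
  if (toupper(datafile) == "LOCAL") {
    data <- bytes[(header_end + 1L):length(bytes)]
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      npl_stop(sprintf("'%s': data file '%s' not found", path, datafile), "npl_format_error")
    data <- readBin(rawpath, "raw", file.info(rawpath)$size)
  }
  labels <- .decode_ints(data, prod(shape), spec, if (msb) "big" else "little", path)
  list(labels = array(labels, dim = shape),
       grid = voxel_grid(shape, spacing = spacing, origin = origin))
}

.write_metaimage <- function(volume, path) {
  g <- volume$grid
  mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (mhd) paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw") else "LOCAL"
  hdr <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "CompressedData = False\n",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1\n",
    sprintf("Offset = %.17g %.17g %.17g\n", g$origin[1], g$origin[2], g$origin[3]),
    "CenterOfRotation = 0 0 0\n",
    sprintf("ElementSpacing = %.17g %.17g %.17g\n", g$spacing[1], g$spacing[2], g$spacing[3]),
    sprintf("DimSize = %d %d %d\n", g$shape[1], g$shape[2], g$shape[3]),
    "ElementType = MET_INT\n",
    sprintf("ElementDataFile = %s\n", datafile))
  payload <- writeBin(as.integer(volume$labels), raw(), size = 4L, endian = "little")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  if (mhd) {
    close(con); on.exit()
    rawcon <- file(file.path(dirname(path), datafile), "wb")
    writeBin(payload, rawcon)
    close(rawcon)
  } else {
    writeBin(payload, con)
  }
}

# ---- NRRD ------------------------------------------------------------------

.NRRD_TYPES <- list(
  "signed char" = list(size = 1L, signed = TRUE),  int8 = list(size = 1L, signed = TRUE),
  uchar = list(size = 1L, signed = FALSE), "unsigned char" = list(size = 1L, signed = FALSE),
  uint8 = list(size = 1L, signed = FALSE),
  short = list(size = 2L, signed = TRUE), int16 = list(size = 2L, signed = TRUE),
  ushort = list(size = 2L, signed = FALSE), "unsigned short" = list(size = 2L, signed = FALSE),
  uint16 = list(size = 2L, signed = FALSE),
  int = list(size = 4L, signed = TRUE), int32 = list(size = 4L, signed = TRUE),
  "signed int" = list(size = 4L, signed = TRUE),
  uint = list(size = 4L, signed = TRUE), uint32 = list(size = 4L, signed = TRUE),
  "unsigned int" = list(size = 4L, signed = TRUE))

.read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  nl <- which(bytes == as.raw(10L))
  # header ends at the first blank line
  blank <- nl[c(diff(nl) == 1L, FALSE)] |> utils::head(1)
  if (!length(blank)) {
    # tolerate \r\n line endings
    cr <- which(bytes == as.raw(13L))
    blank <- intersect(nl + 1L, cr + 2L)[1]
    if (is.na(blank)) npl_stop(sprintf("'%s': no NRRD header terminator", path), "npl_format_error")
    blank <- blank + 1L
  } else {
    blank <- blank + 1L
  }
  txt <- gsub("\r", "", rawToChar(bytes[1:blank]))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (!length(lines) || !grepl("^NRRD", lines[1]))
    npl_stop(sprintf("'%s' is not an NRRD file", path), "npl_format_error")
  lines <- lines[-1]
  lines <- lines[!grepl("^#", lines) & !grepl(":=", lines, fixed = TRUE) & nzchar(lines)]
  hdr <- .parse_kv(paste(lines, collapse = "\n"), sep = ":")
  type <- tolower(trimws(hdr$type %||% ""))
  if (grepl("float|double", type))
    npl_stop(sprintf("'%s' has non-integer voxel type (%s)", path, type), "npl_type_error")
  spec <- .NRRD_TYPES[[type]]
  if (is.null(spec))
    npl_stop(sprintf("'%s': unsupported NRRD type '%s'", path, type), "npl_format_error")
  if (!is.null(hdr$`data file`) || !is.null(hdr$datafile))
    npl_stop(sprintf("'%s': detached NRRD data files are not supported", path), "npl_format_error")
  if (as.integer(hdr$dimension %||% 0) != 3L)
    npl_stop(sprintf("'%s': only 3-D NRRD volumes are supported", path), "npl_format_error")
  shape <- as.integer(strsplit(trimws(hdr$sizes), "\\s+")[[1]])
  enc <- tolower(trimws(hdr$encoding %||% "raw"))
  endian <- tolower(trimws(hdr$endian %||% "little"))
  data <- bytes[(blank + 1L):length(bytes)]
  if (enc %in% c("gzip", "gz")) {
    data <- memDecompress(data, type = "gzip")
  } else if (enc != "raw") {
    npl_stop(sprintf("'%s': unsupported NRRD encoding '%s'", path, enc), "npl_format_error")
  }
  labels <- .decode_ints(data, prod(shape), spec, endian, path)
  sd <- .parse_nrrd_vectors(hdr$`space directions`)
  spacing <- c(1, 1, 1); flip <- c(FALSE, FALSE, FALSE)
  if (!is.null(sd)) {
    for (a in 1:3) {
      v <- sd[[a]]
      if (sqrt(sum(v^2) - v[a]^2) > 1e-4 * abs(v[a]))
        npl_stop(sprintf("'%s' is not axis-aligned; reorient it first", path), "npl_format_error")
      spacing[a] <- abs(v[a]); flip[a] <- v[a] < 0
    }
  } else if (!is.null(hdr$spacings)) {
    spacing <- abs(as.numeric(strsplit(trimws(hdr$spacings), "\\s+")[[1]]))
  }
  origin <- c(0, 0, 0)
  if (!is.null(hdr$`space origin`))
    origin <- .parse_nrrd_vectors(hdr$`space origin`)[[1]]
  arr <- array(labels, dim = shape)
  for (a in 1:3) if (flip[a]) {
    arr <- .flip_axis(arr, a)
    origin[a] <- origin[a] - spacing[a] * (shape[a] - 1L)
  }
  list(labels = arr, grid = voxel_grid(shape, spacing = spacing, origin = origin))
}

.write_nrrd <- function(volume, path) {
  g <- volume$grid
  hdr <- paste0(
    "NRRD0004\n",
    "# labeled volume written by needleplan\n",
    "type: int\n",
    "dimension: 3\n",
    "space dimension: 3\n",
    sprintf("sizes: %d %d %d\n", g$shape[1], g$shape[2], g$shape[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)\n",
            g$spacing[1], g$spacing[2], g$spacing[3]),
    "kinds: domain domain domain\n",
    "endian: little\n",
    "encoding: raw\n",
    sprintf("space origin: (%.17g,%.17g,%.17g)\n",
            g$origin[1], g$origin[2], g$origin[3]),
    "\n")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(as.integer(volume$labels), con, size = 4L, endian = "little")
}

.parse_nrrd_vectors <- function(s) {
  if (is.null(s)) return(NULL)
  m <- gregexpr("\\(([^)]*)\\)", s)[[1]]
  if (m[1] < 0) return(NULL)
  vals <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(vals, function(v) as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

# ---- shared helpers --------------------------------------------------------

.parse_kv <- function(txt, sep) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[grepl(sep, lines, fixed = TRUE)]
  keys <- tolower(trimws(sub(paste0("\\", sep, ".*$"), "", lines)))
  vals <- trimws(sub(paste0("^[^", sep, "]*\\", sep), "", lines))
  setNames(as.list(vals), keys)
}

.decode_ints <- function(data, n, spec, endian, path) {
  need <- n * spec$size
  if (length(data) < need)
    npl_stop(sprintf("'%s': truncated data (%d bytes, need %d)", path, length(data), need),
             "npl_format_error")
  vals <- readBin(data, "integer", n = n, size = spec$size,
                  signed = if (spec$size < 4L) spec$signed else TRUE,
                  endian = endian)
  if (any(vals < 0L))
    npl_stop(sprintf("'%s' contains negative labels", path), "npl_type_error")
  vals
}

`%||%` <- function(a, b) if (is.null(a)) b else a
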