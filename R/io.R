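#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supported containers are NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage
#' (`.mha` single-file, or `.mhd` header + raw).  Spacing and origin are
#' taken from the file header (NIfTI: the sform/qform affine; MetaImage:
#' `ElementSpacing` and `Offset`).  Only axis-aligned, positively oriented
#' volumes are produced by [write_volume()]; arbitrary rotations are out of
#' scope.
#'
#' @param path file to read.
#' @param format `"auto"` (from the extension), `"nifti"` or `"metaimage"`.
#' @return an [image_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "metaimage")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("cannot read volume: file '%s' does not exist", path),
         call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    nifti = read_volume_nifti(path),
    metaimage = read_volume_mha(path)
  )
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' @param vol an [image_volume()] or [binary_mask()]; masks are written as
#'   8-bit 0/1 images.
#' @param path destination; extension selects the container when
#'   `format = "auto"`.
#' @param format `"auto"`, `"nifti"` or `"metaimage"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "nifti", "metaimage")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  is_mask <- inherits(vol, "binary_mask")
  if (!is_mask && !inherits(vol, "image_volume"))
    stop("`vol` must be an image_volume or binary_mask", call. = FALSE)
  switch(format,
    nifti = write_volume_nifti(vol, path, is_mask),
    metaimage = write_volume_mha(vol, path, is_mask)
  )
  invisible(path)
}

#' Read a binary mask (any non-zero voxel is set)
#' @inheritParams read_volume
#' @return a [binary_mask()].
#' @export
read_mask <- function(path, format = c("auto", "nifti", "metaimage")) {
  v <- read_volume(path, format)
  binary_mask(array(v$data != 0, dim(v$data)), v$spacing, v$origin)
}

guess_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(mha|mhd)$", low)) return("metaimage")
  stop(sprintf("cannot infer volume format from '%s' (use .nii/.nii.gz/.mha/.mhd)",
               path), call. = FALSE)
}

read_volume_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "failed to parse '%s' as NIfTI: %s", path, conditionMessage(e)),
                    call. = FALSE))
  if (length(dim(img)) != 3L)
    stop(sprintf("'%s' is not a 3D volume", path), call. = FALSE)
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  spacing <- abs(diag(xf[1:3, 1:3, drop = FALSE]))
  if (any(spacing <= 0)) {
    spacing <- RNifti::pixdim(img)[1:3]
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop(sprintf("'%s' has no usable voxel spacing in its header", path),
         call. = FALSE)
  origin <- xf[1:3, 4]
  image_volume(array(as.numeric(img), dim(img)), spacing, origin)
}

write_volume_nifti <- function(vol, path, is_mask) {
  dat <- if (is_mask) array(as.integer(vol$data), dim(vol$data)) else vol$data
  img <- RNifti::asNifti(dat, datatype = if (is_mask) "uint8" else "double")
  aff <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  RNifti::`sform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, path)
}

## --- MetaImage (.mha/.mhd), little-endian raw payload ---------------------

read_volume_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop(sprintf("truncated MetaImage header in '%s'", path), call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L)
      stop(sprintf("malformed MetaImage header line in '%s': %s", path, line),
           call. = FALSE)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  need <- c("NDims", "DimSize", "ElementType", "ElementSpacing")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop(sprintf("MetaImage header '%s' lacks %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (as.integer(hdr$NDims) != 3L)
    stop(sprintf("'%s' is not a 3D MetaImage", path), call. = FALSE)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  n <- prod(dims)
  type <- hdr$ElementType
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path))
      stop(sprintf("MetaImage payload '%s' not found", raw_path), call. = FALSE)
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- switch(type,
    MET_DOUBLE = readBin(raw_con, "double", n, size = 8, endian = "little"),
    MET_FLOAT  = readBin(raw_con, "double", n, size = 4, endian = "little"),
    MET_UCHAR  = as.numeric(readBin(raw_con, "integer", n, size = 1,
                                    signed = FALSE, endian = "little")),
    MET_SHORT  = as.numeric(readBin(raw_con, "integer", n, size = 2,
                                    signed = TRUE, endian = "little")),
    stop(sprintf("unsupported MetaImage ElementType '%s'", type), call. = FALSE)
  )
  if (length(vals) != n)
    stop(sprintf("truncated MetaImage payload in '%s' (%d of %d values)",
                 path, length(vals), n), call. = FALSE)
  image_volume(array(vals, dims), spacing, origin)
}

write_volume_mha <- function(vol, path, is_mask) {
  header_only <- grepl("\\.mhd$", tolower(path))
  type <- if (is_mask) "MET_UCHAR" else "MET_DOUBLE"
  data_file <- if (header_only) sub("\\.mhd$", ".raw", basename(path),
                                    ignore.case = TRUE) else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %s", paste(dim(vol$data), collapse = " ")),
    sprintf("ElementSpacing = %s",
            paste(format(vol$spacing, digits = 15), collapse = " ")),
    sprintf("Offset = %s",
            paste(format(vol$origin, digits = 15), collapse = " ")),
    sprintf("ElementType = %s", type),
    sprintf("ElementDataFile = %s", data_file)
  )
  payload <- function(con) {
    if (is_mask) {
      writeBin(as.raw(as.integer(vol$data)), con)
    } else {
      writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
    }
  }
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop(sprintf(
                    "cannot write '%s': %s", path, conditionMessage(e)),
                    call. = FALSE))
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (header_only) {
    raw_con <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(raw_con), add = TRUE)
    payload(raw_con)
  } else {
    payload(con)
  }
}

## --- tabular reports ------------------------------------------------------

#' Write a keyed report table as CSV
#'
#' RFC-4180 quoting; numeric columns rendered with at least 6 significant
#' digits so that round-trips preserve values to float rendering precision.
#'
#' @param rows a data.frame, or a list of named lists sharing a key set.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  if (!is.data.frame(rows)) {
    if (length(rows) == 0L) {
      stop("cannot infer columns from an empty record list; pass a data.frame",
           call. = FALSE)
    }
    keys <- names(rows[[1]])
    for (r in rows)
      if (!identical(names(r), keys))
        stop("report records do not share a common key set", call. = FALSE)
    rows <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- trimws(formatC(out[[j]], digits = 10, format = "g"))
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop(sprintf("cannot write report to '%s'", path), call. = FALSE)
  invisible(path)
}

#' Read a report CSV written by [write_report()]
#' @param path CSV path.
#' @return a data.frame.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read report: '%s' does not exist", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

## --- mesh export ----------------------------------------------------------

#' Write a triangle mesh to Wavefront OBJ or ASCII STL
#'
#' @param mesh a `tri_mesh` (see [mask_to_mesh()]).
#' @param path destination; `.obj` or `.stl`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  low <- tolower(path)
  v <- mesh$vertices
  f <- mesh$faces
  if (grepl("\\.obj$", low)) {
    lines <- c(
      sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
      sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
    )
    writeLines(lines, path)
  } else if (grepl("\\.stl$", low)) {
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    cc <- v[f[, 3], , drop = FALSE]
    n <- cross3(b - a, cc - a)
    len <- sqrt(rowSums(n^2))
    n <- n / ifelse(len > 0, len, 1)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
        "  outer loop",
        sprintf("    vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
        sprintf("    vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
        sprintf("    vertex %.9g %.9g %.9g", cc[i, 1], cc[i, 2], cc[i, 3]),
        "  endloop",
        "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else {
    stop("mesh export supports .obj and .stl only", call. = FALSE)
  }
  invisible(path)
}

cross3 <- function(u, w) {
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}
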