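#' Write a volume as MetaImage (MHD + RAW)
#'
#' Minimal MetaImage writer: a plain-text `.mhd` header (dimensions, spacing,
#' offset, element type) plus a sidecar `.raw` payload in native byte order.
#' Works for `voxel_grid`, `dose_grid` and plain 3D arrays (masks are written
#' as 0/1 MET_UCHAR).
#'
#' @param x a `voxel_grid`, `dose_grid`, or 3D array.
#' @param path output path ending in `.mhd`.
#' @param spacing,origin geometry when `x` is a plain array.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(x, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(x, "voxel_grid")) {
    arr <- x$rsp; spacing <- x$spacing; origin <- x$origin
  } else if (inherits(x, "dose_grid")) {
    arr <- x$dose; spacing <- x$spacing; origin <- x$origin
  } else arr <- x
  if (length(dim(arr)) != 3L) stop("need a 3D volume", call. = FALSE)
  if (!grepl("\\.mhd$", path)) path <- paste0(path, ".mhd")
  raw_path <- sub("\\.mhd$", ".raw", path)
  is_mask <- is.logical(arr)
  type <- if (is_mask) "MET_UCHAR" else "MET_DOUBLE"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    sprintf("BinaryDataByteOrderMSB = %s",
            if (.Platform$endian == "big") "True" else "False"),
    sprintf("DimSize = %s", paste(dim(arr), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(spacing, digits = 10), collapse = " ")),
    sprintf("Offset = %s", paste(format(origin, digits = 10), collapse = " ")),
    sprintf("ElementType = %s", type),
    sprintf("ElementDataFile = %s", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  if (is_mask) {
    writeBin(as.integer(arr), con, size = 1L)
  } else {
    writeBin(as.numeric(arr), con, size = 8L)
  }
  invisible(path)
}

#' Read a MetaImage (MHD + RAW) volume
#'
#' @param path `.mhd` header path.
#' @param as one of "voxel_grid", "dose_grid", "array", "mask".
#' @return the requested representation; geometry is taken from the header.
#' @export
read_mhd <- function(path, as = c("voxel_grid", "dose_grid", "array", "mask")) {
  as <- match.arg(as)
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), "")
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset", "0 0 0"), "\\s+")[[1]])
  type <- get("ElementType", "MET_DOUBLE")
  datafile <- get("ElementDataFile")
  if (is.null(dims) || is.null(datafile))
    stop("malformed MHD header: ", path, call. = FALSE)
  raw_path <- file.path(dirname(path), datafile)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- switch(type,
    MET_DOUBLE = readBin(con, numeric(), n, size = 8L),
    MET_FLOAT  = readBin(con, numeric(), n, size = 4L),
    MET_UCHAR  = as.numeric(readBin(con, integer(), n, size = 1L, signed = FALSE)),
    MET_SHORT  = as.numeric(readBin(con, integer(), n, size = 2L)),
    stop("unsupported ElementType: ", type, call. = FALSE))
  arr <- array(v, dim = dims)
  switch(as,
    voxel_grid = voxel_grid(arr, spacing, origin),
    dose_grid = dose_grid(arr, spacing, origin),
    array = arr,
    mask = array(arr != 0, dim = dims))
}
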