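# 8-bit grayscale BMP slice stacks. One BMP per axial slice (k index),
# lexicographically ordered file names, plus a JSON sidecar recording dims
# and spacing. Pixels: BMP column = i (x), BMP row = j (y); rows are stored
# bottom-up as the format requires, writer and reader agree.

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")

write_bmp8 <- function(mat, path) {
  w <- nrow(mat)  # i dimension -> columns of the image
  h <- ncol(mat)  # j dimension -> rows
  pad <- (4 - w %% 4) %% 4
  rowbytes <- w + pad
  datasize <- rowbytes * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  write_u32(con, 14 + 40 + 1024 + datasize)
  write_u32(con, 0)
  write_u32(con, 14 + 40 + 1024)
  write_u32(con, 40); write_u32(con, w); write_u32(con, h)
  write_u16(con, 1); write_u16(con, 8)
  write_u32(con, 0); write_u32(con, datasize)
  write_u32(con, 2835); write_u32(con, 2835)
  write_u32(con, 256); write_u32(con, 0)
  pal <- raw(1024)  # 256-entry grayscale palette (B, G, R, 0)
  idx <- rep(0:255, each = 4)
  chan <- rep(1:4, times = 256)
  pal[chan != 4] <- as.raw(idx[chan != 4])
  writeBin(pal, con)
  m <- matrix(pmax(0L, pmin(255L, as.integer(round(mat)))), nrow = w)
  body <- raw(rowbytes * h)
  for (r in seq_len(h)) {      # bottom-up: stored row r = image row r (j = r)
    off <- (r - 1L) * rowbytes
    body[off + seq_len(w)] <- as.raw(m[, r])
  }
  writeBin(body, con)
  invisible(path)
}

read_bmp8 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path, call. = FALSE)
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  data_off <- u32(10)
  w <- u32(18); h <- u32(22)
  bpp <- u16(28); compression <- u32(30)
  if (bpp != 8 || compression != 0)
    stop("only uncompressed 8-bit BMP supported: ", path, call. = FALSE)
  pad <- (4 - w %% 4) %% 4
  rowbytes <- w + pad
  m <- matrix(0L, nrow = w, ncol = h)
  for (r in seq_len(h)) {
    off <- data_off + (r - 1L) * rowbytes
    m[, r] <- as.integer(raw[off + seq_len(w)])
  }
  m
}

#' Write / read a volume as a BMP slice stack
#'
#' `write_bmp_stack` writes one 8-bit BMP per axial slice
#' (`slice_0001.bmp`, ...) plus a `stack.json` sidecar with dims and
#' spacing; `read_bmp_stack` reads any directory of such slices
#' (lexicographic order = k index), using the sidecar's spacing when
#' present.
#'
#' @param vol a [voxel_volume()].
#' @param dir stack directory (created if missing).
#' @return `write_bmp_stack` returns `dir` invisibly; `read_bmp_stack`
#'   returns a `voxel_volume`.
#' @export
write_bmp_stack <- function(vol, dir) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- vol$dims
  for (k in seq_len(d[3]))
    write_bmp8(vol$intensities[, , k],
               file.path(dir, sprintf("slice_%04d.bmp", k)))
  jsonlite::write_json(list(dims = d, spacing_mm = vol$spacing_mm,
                            format = "bmp8"),
                       file.path(dir, "stack.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_bmp_stack
#' @export
read_bmp_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.bmp$", full.names = TRUE))
  if (!length(files)) stop("no BMP slices in ", dir, call. = FALSE)
  slices <- lapply(files, read_bmp8)
  d1 <- dim(slices[[1]])
  arr <- array(0L, dim = c(d1[1], d1[2], length(slices)))
  for (k in seq_along(slices)) {
    if (!identical(dim(slices[[k]]), d1))
      stop("slice dimension mismatch at ", files[k], call. = FALSE)
    arr[, , k] <- slices[[k]]
  }
  spacing <- c(1, 1, 1)
  sidecar <- file.path(dir, "stack.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    if (!is.null(meta$spacing_mm)) spacing <- as.numeric(meta$spacing_mm)
  }
  voxel_volume(arr, spacing_mm = spacing)
}
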