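# Ascii PLY and OBJ mesh readers/writers. Coordinates are written with six
# significant decimals, sub-voxel fidelity at 1 mm spacing.

fmt_num <- function(x) formatC(x, format = "g", digits = 6)

#' Write a mesh to PLY or OBJ
#'
#' Ascii formats only; the extension selects the format. OBJ faces use the
#' conventional 1-based vertex indices; in-memory faces are 1-based R
#' indices, so OBJ round-trips are index-exact.
#'
#' @param mesh a `surface_mesh`.
#' @param path output file ending in `.ply` or `.obj`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    has_n <- !is.null(mesh$normals)
    hdr <- c("ply", "format ascii 1.0",
             paste("comment frame", mesh$frame),
             paste("element vertex", nrow(v)),
             "property float x", "property float y", "property float z",
             if (has_n) c("property float nx", "property float ny", "property float nz"),
             paste("element face", nrow(f)),
             "property list uchar int vertex_indices",
             "end_header")
    vm <- if (has_n) cbind(v, mesh$normals) else v
    vlines <- apply(vm, 1, function(r) paste(fmt_num(r), collapse = " "))
    flines <- paste("3", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    writeLines(c(hdr, vlines, flines), path)
  } else if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    vlines <- paste("v", fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3]))
    flines <- paste("f", f[, 1], f[, 2], f[, 3])
    writeLines(c(paste("# frame", mesh$frame), vlines, flines), path)
  } else stop("unsupported mesh format: ", path, call. = FALSE)
  invisible(path)
}

#' Read a mesh from PLY or OBJ
#'
#' @param path a `.ply` (ascii) or `.obj` file.
#' @return A `surface_mesh`; malformed input raises an error naming the
#'   offending line.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such mesh file: ", path, call. = FALSE)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) read_ply(path)
  else if (grepl("\\.obj$", path, ignore.case = TRUE)) read_obj(path)
  else stop("unsupported mesh format: ", path, call. = FALSE)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("parse error in ", path, " at line 1: missing 'ply' magic", call. = FALSE)
  nv <- nf <- NA_integer_
  frame <- "stack"
  props <- character()
  end <- NA_integer_
  elem <- ""
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "format" && !identical(tok[2], "ascii"))
      stop("parse error in ", path, " at line ", i, ": only ascii PLY supported",
           call. = FALSE)
    if (tok[1] == "comment" && length(tok) >= 3 && tok[2] == "frame") frame <- tok[3]
    if (tok[1] == "element") {
      elem <- tok[2]
      if (tok[2] == "vertex") nv <- as.integer(tok[3])
      if (tok[2] == "face") nf <- as.integer(tok[3])
    }
    if (tok[1] == "property" && elem == "vertex" && tok[2] == "float")
      props <- c(props, tok[3])
    if (tok[1] == "end_header") { end <- i; break }
  }
  if (is.na(end) || is.na(nv) || is.na(nf))
    stop("parse error in ", path, ": incomplete PLY header", call. = FALSE)
  safe_scan <- function(x) tryCatch(suppressWarnings(scan(text = x, quiet = TRUE)),
                                    error = function(e) NA_real_)
  vlines <- lines[end + seq_len(nv)]
  vvals <- safe_scan(vlines)
  if (length(vvals) != nv * length(props) || anyNA(vvals)) {
    # locate the offending line for the error message
    for (i in seq_len(nv)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(vlines[i]), "\\s+")[[1]]))
      if (length(vals) != length(props) || anyNA(vals))
        stop("parse error in ", path, " at line ", end + i, ": bad vertex record",
             call. = FALSE)
    }
    stop("parse error in ", path, ": vertex block inconsistent with header",
         call. = FALSE)
  }
  vdat <- matrix(vvals, nrow = nv, ncol = length(props), byrow = TRUE)
  flines <- lines[end + nv + seq_len(nf)]
  fvals <- safe_scan(flines)
  if (length(fvals) != nf * 4 || anyNA(fvals) ||
      !all(fvals[seq(1, length(fvals), by = 4)] == 3)) {
    for (i in seq_len(nf)) {
      vals <- suppressWarnings(as.integer(strsplit(trimws(flines[i]), "\\s+")[[1]]))
      if (length(vals) != 4 || anyNA(vals) || vals[1] != 3L)
        stop("parse error in ", path, " at line ", end + nv + i,
             ": expected triangle face record", call. = FALSE)
    }
    stop("parse error in ", path, ": face block inconsistent with header",
         call. = FALSE)
  }
  fm <- matrix(as.integer(fvals), nrow = nf, ncol = 4, byrow = TRUE)
  faces <- fm[, 2:4, drop = FALSE] + 1L
  xyz <- match(c("x", "y", "z"), props)
  if (anyNA(xyz)) stop("parse error in ", path, ": vertex x/y/z missing", call. = FALSE)
  normals <- NULL
  nidx <- match(c("nx", "ny", "nz"), props)
  if (!anyNA(nidx)) normals <- vdat[, nidx, drop = FALSE]
  surface_mesh(vdat[, xyz, drop = FALSE], faces, normals = normals, frame = frame)
}

read_obj <- function(path) {
  lines <- readLines(path)
  frame <- "stack"
  vs <- list(); fs <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) {
      tok <- strsplit(ln, "\\s+")[[1]]
      if (length(tok) >= 3 && identical(tok[2], "frame")) frame <- tok[3]
      next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "v") {
      vals <- suppressWarnings(as.numeric(tok[2:4]))
      if (length(vals) != 3 || anyNA(vals))
        stop("parse error in ", path, " at line ", i, ": bad vertex", call. = FALSE)
      vs[[length(vs) + 1L]] <- vals
    } else if (tok[1] == "f") {
      raw <- sub("/.*$", "", tok[-1])
      vals <- suppressWarnings(as.integer(raw))
      if (length(vals) != 3 || anyNA(vals))
        stop("parse error in ", path, " at line ", i,
             ": only triangle faces supported", call. = FALSE)
      fs[[length(fs) + 1L]] <- vals
    }
  }
  if (!length(vs)) stop("parse error in ", path, ": no vertices", call. = FALSE)
  surface_mesh(do.call(rbind, vs), do.call(rbind, fs), frame = frame)
}
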