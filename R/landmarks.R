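#' Named 3D landmark sets
#'
#' A `landmark_set` is a data.frame with columns `name`, `side`
#' (`"left"`, `"right"` or `"midline"`), `x`, `y`, `z`, `frame`
#' (`"stack"` or `"model"`) and `provenance` (e.g. `"manual"`,
#' `"ground_truth"`, `"computed"`). `(name, side)` pairs are unique.
#'
#' @param df data.frame with at least `name`, `side`, `x`, `y`, `z`.
#' @return The validated `landmark_set`.
#' @export
landmark_set <- function(df) {
  need <- c("name", "side", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("landmark set lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (is.null(df$frame)) df$frame <- "stack"
  if (is.null(df$provenance)) df$provenance <- "manual"
  bad <- !df$side %in% c("left", "right", "midline")
  if (any(bad)) stop("invalid side value(s): ", paste(unique(df$side[bad]), collapse = ", "),
                     call. = FALSE)
  key <- paste(df$name, df$side)
  if (anyDuplicated(key))
    stop("duplicate landmark entries: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("landmark_set", "data.frame")
  df
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", nrow(x), " points (",
      paste(unique(x$frame), collapse = "/"), " frame)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Look up one landmark position
#'
#' @param lms a `landmark_set`.
#' @param name point name.
#' @param side `"left"`, `"right"` or `"midline"`; `NULL` requires the name
#'   to be unique in the set.
#' @return Numeric xyz 3-vector.
#' @export
lm_point <- function(lms, name, side = NULL) {
  rows <- if (is.null(side)) lms[lms$name == name, ]
          else lms[lms$name == name & lms$side == side, ]
  if (nrow(rows) == 0L)
    stop("landmark not found: ", name, if (!is.null(side)) paste0(" (", side, ")"),
         call. = FALSE)
  if (nrow(rows) > 1L)
    stop("landmark ", name, " is ambiguous; specify side", call. = FALSE)
  c(rows$x, rows$y, rows$z)
}

lm_has <- function(lms, name, side) {
  any(lms$name == name & lms$side == side)
}

#' Write / read landmark sets
#'
#' JSON files hold an array of `{name, side, x, y, z, frame, provenance}`
#' records; CSV files use the header `name,side,x,y,z,frame`.
#'
#' @param lms a `landmark_set`.
#' @param path output file; extension `.json` or `.csv` selects the format.
#' @return `write_landmarks` returns `path` invisibly; `read_landmarks`
#'   returns a `landmark_set`.
#' @export
write_landmarks <- function(lms, path) {
  stopifnot(inherits(lms, "landmark_set"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(lms), path, digits = NA, auto_unbox = FALSE)
  } else {
    utils::write.csv(as.data.frame(lms), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("no such landmark file: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  landmark_set(as.data.frame(df))
}

# Matrix of positions (n x 3) for a landmark set.
lm_matrix <- function(lms) cbind(lms$x, lms$y, lms$z)
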