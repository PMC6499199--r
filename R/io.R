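#' Read a point cloud from disk
#'
#' Supported dialects:
#' \describe{
#'   \item{`xyz`}{Whitespace-separated text, one point per line:
#'     `x y z [intensity]`, `#` comments allowed.}
#'   \item{`ply`}{ASCII PLY with vertex properties `x, y, z` and optionally
#'     an intensity-like scalar (`intensity` or `scalar_intensity`).}
#' }
#' Coordinates are returned in meters as doubles; point order is preserved.
#'
#' @param path Path to the file.
#' @param format One of `"xyz"`, `"ply"`; default guesses from the extension.
#' @return A [point_cloud()].
#' @export
read_cloud <- function(path, format = c("auto", "xyz", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read point cloud: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", xyz = "xyz", txt = "xyz",
                     stop("cannot guess point-cloud format from extension '.",
                          ext, "'; pass format="))
  }
  switch(format, xyz = read_xyz(path), ply = read_ply(path))
}

#' Write a point cloud to disk
#'
#' Round-trips with [read_cloud()]: coordinates are written with 17
#' significant digits (full double precision for the text dialects) and
#' intensity exactly.
#'
#' @param cloud A [point_cloud()].
#' @param path Output path.
#' @param format One of `"xyz"`, `"ply"`; default guesses from the extension.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "xyz", "ply")) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", xyz = "xyz", txt = "xyz",
                     stop("cannot guess point-cloud format from extension '.",
                          ext, "'; pass format="))
  }
  switch(format, xyz = write_xyz(cloud, path), ply = write_ply(cloud, path))
  invisible(NULL)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(point_cloud(matrix(numeric(0), ncol = 3)))
  tok <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(tok)
  bad <- which(nf < 3L | nf > 4L)
  if (length(bad)) {
    stop("malformed XYZ record at point ", bad[1L], ": expected 'x y z [intensity]'")
  }
  if (length(unique(nf)) != 1L) {
    stop("malformed XYZ file: mixed 3- and 4-column records (first mismatch at point ",
         which(nf != nf[1L])[1L], ")")
  }
  vals <- suppressWarnings(as.numeric(unlist(tok, use.names = FALSE)))
  m <- matrix(vals, ncol = nf[1L], byrow = TRUE)
  if (anyNA(m)) {
    stop("malformed XYZ record at point ", which(rowSums(is.na(m)) > 0)[1L],
         ": non-numeric field")
  }
  point_cloud(m[, 1:3, drop = FALSE],
              intensity = if (nf[1L] == 4L) m[, 4L])
}

write_xyz <- function(cloud, path) {
  n <- n_points(cloud)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# x y z[ intensity] (meters; raw counts)", con)
  if (n == 0L) return(invisible(NULL))
  cols <- apply(cloud$coords, 2, format_full)
  if (!is.matrix(cols)) cols <- matrix(cols, nrow = n)
  body <- if (is.null(cloud$intensity)) {
    paste(cols[, 1L], cols[, 2L], cols[, 3L])
  } else {
    paste(cols[, 1L], cols[, 2L], cols[, 3L], format_full(cloud$intensity))
  }
  writeLines(body, con)
  invisible(NULL)
}

format_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1L]) != "ply") {
    stop("not a PLY file: ", path)
  }
  end_hdr <- which(trimws(lines) == "end_header")[1L]
  if (is.na(end_hdr)) stop("malformed PLY: no end_header")
  hdr <- trimws(lines[seq_len(end_hdr)])
  fmt <- grep("^format ", hdr, value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1L])) {
    stop("only ASCII PLY is supported")
  }
  el <- grep("^element ", hdr)
  vx <- el[grepl("^element vertex ", hdr[el])]
  if (!length(vx)) stop("malformed PLY: no vertex element")
  nv <- as.integer(strsplit(hdr[vx[1L]], "[[:space:]]+")[[1L]][3L])
  nxt <- el[el > vx[1L]]
  prop_lines <- hdr[(vx[1L] + 1L):(if (length(nxt)) nxt[1L] - 1L else end_hdr - 1L)]
  prop_lines <- grep("^property ", prop_lines, value = TRUE)
  props <- vapply(strsplit(prop_lines, "[[:space:]]+"), function(t) t[[3L]], character(1))
  need <- c("x", "y", "z")
  if (!all(need %in% props)) stop("PLY vertex element lacks x/y/z properties")
  int_prop <- intersect(c("intensity", "scalar_intensity", "scalar_Intensity"), props)

  body <- lines[(end_hdr + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv) stop("malformed PLY: fewer vertex records than declared")
  tok <- strsplit(trimws(body[seq_len(max(nv, 0L))]), "[[:space:]]+")
  nf <- lengths(tok)
  if (nv > 0L && any(nf != length(props))) {
    stop("malformed PLY vertex record at point ", which(nf != length(props))[1L])
  }
  if (nv == 0L) return(point_cloud(matrix(numeric(0), ncol = 3)))
  m <- matrix(suppressWarnings(as.numeric(unlist(tok, use.names = FALSE))),
              ncol = length(props), byrow = TRUE)
  if (anyNA(m)) {
    stop("malformed PLY vertex record at point ", which(rowSums(is.na(m)) > 0)[1L])
  }
  colnames(m) <- props
  point_cloud(m[, need, drop = FALSE],
              intensity = if (length(int_prop)) m[, int_prop[1L]])
}

write_ply <- function(cloud, path) {
  n <- n_points(cloud)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z")
  if (!is.null(cloud$intensity)) hdr <- c(hdr, "property double intensity")
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con)
  if (n > 0L) {
    cols <- apply(cloud$coords, 2, format_full)
    if (!is.matrix(cols)) cols <- matrix(cols, nrow = n)
    body <- if (is.null(cloud$intensity)) {
      paste(cols[, 1L], cols[, 2L], cols[, 3L])
    } else {
      paste(cols[, 1L], cols[, 2L], cols[, 3L], format_full(cloud$intensity))
    }
    writeLines(body, con)
  }
  invisible(NULL)
}
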