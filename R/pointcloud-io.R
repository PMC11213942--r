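# Point-cloud file I/O: LAS 1.2 (binary, point format 0), ASCII PLY and
# XYZ/CSV text. LAS classification codes follow the ASPRS convention used
# here: 1 unclassified, 2 ground, 5 high vegetation (above-ground), 7 noise.

.las_class_of_label <- c(UNCLASSIFIED = 1L, GROUND = 2L, ABOVE_GROUND = 5L, NOISE = 7L)

.label_of_las_class <- function(code) {
  out <- rep("UNCLASSIFIED", length(code))
  out[code == 2L] <- "GROUND"
  out[code == 5L] <- "ABOVE_GROUND"
  out[code == 7L] <- "NOISE"
  out
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         las = "las", laz = "laz", ply = "ply",
         xyz = "xyz", csv = "xyz", txt = "xyz",
         stop("cannot infer point-cloud format from extension '.", ext, "'"))
}

#' Read a point cloud from file
#'
#' Supports binary LAS 1.2 (classification preserved), ASCII PLY (vertex
#' x, y, z) and XYZ/CSV text (comma- or whitespace-separated, header
#' auto-detected). Point order is preserved as stored; z is elevation in
#' metres.
#'
#' @param path Input file path.
#' @param format One of `"auto"`, `"las"`, `"laz"`, `"ply"`, `"xyz"`.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format, c("auto", "las", "laz", "ply", "xyz"))
  if (format == "auto") format <- .guess_format(path)
  switch(format,
         las = .read_las(path),
         laz = stop("LAZ (compressed LAS) is not supported; decompress to LAS first"),
         ply = .read_ply(path),
         xyz = .read_xyz(path))
}

#' Write a point cloud to file
#'
#' LAS stores labels in the classification field; PLY and XYZ drop labels
#' with a warning. The LAS writer uses a 0.001 m coordinate scale.
#'
#' @param cloud A [point_cloud()]; must be non-empty.
#' @param path Output file path.
#' @param format One of `"auto"`, `"las"`, `"ply"`, `"xyz"`.
#' @return Invisibly, `path`.
#' @export
write_point_cloud <- function(cloud, path, format = "auto") {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0) stop("cannot write an empty point cloud")
  format <- match.arg(format, c("auto", "las", "laz", "ply", "xyz"))
  if (format == "auto") format <- .guess_format(path)
  if (format == "laz")
    stop("LAZ (compressed LAS) is not supported; write LAS instead")
  if (format != "las" && !is.null(cloud$label))
    warning("point labels are not representable in ", toupper(format),
            " and were dropped")
  switch(format,
         las = .write_las(cloud, path),
         ply = .write_ply(cloud, path),
         xyz = .write_xyz(cloud, path))
  invisible(path)
}

# ---- LAS 1.2, point data record format 0 (20 bytes/point) ----

.write_las <- function(cloud, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- n_points(cloud)
  scale <- 0.001
  off <- c(floor(min(cloud$x)), floor(min(cloud$y)), floor(min(cloud$z)))
  wb <- function(what, size) writeBin(what, con, size = size, endian = "little")
  writeChar("LASF", con, 4, eos = NULL)
  wb(0L, 2)                          # file source id
  wb(0L, 2)                          # global encoding
  wb(integer(4), 4)                  # project GUID (16 bytes)
  writeBin(as.raw(c(1, 2)), con)     # version 1.2
  writeChar(formatC("phenocast", width = 32, flag = "-"), con, 32, eos = NULL)
  writeChar(formatC("phenocast R package", width = 32, flag = "-"), con, 32, eos = NULL)
  wb(1L, 2); wb(2026L, 2)            # creation day/year
  wb(227L, 2)                        # header size
  wb(227L, 4)                        # offset to point data
  wb(0L, 4)                          # number of VLRs
  writeBin(as.raw(0), con)           # point data format 0
  wb(20L, 2)                         # point record length
  wb(n, 4)                           # number of point records
  wb(c(n, 0L, 0L, 0L, 0L), 4)        # points by return
  writeBin(c(scale, scale, scale), con, endian = "little")
  writeBin(as.numeric(off), con, endian = "little")
  writeBin(c(max(cloud$x), min(cloud$x), max(cloud$y), min(cloud$y),
             max(cloud$z), min(cloud$z)), con, endian = "little")
  X <- as.integer(round((cloud$x - off[1]) / scale))
  Y <- as.integer(round((cloud$y - off[2]) / scale))
  Z <- as.integer(round((cloud$z - off[3]) / scale))
  cls <- if (is.null(cloud$label)) rep(0L, n) else
    unname(.las_class_of_label[cloud$label])
  # interleave the 20-byte records as a raw block
  rec <- matrix(as.raw(0), nrow = 20, ncol = n)
  int2raw <- function(v) writeBin(v, raw(), size = 4, endian = "little")
  rec[1:4, ]  <- matrix(int2raw(X), nrow = 4)
  rec[5:8, ]  <- matrix(int2raw(Y), nrow = 4)
  rec[9:12, ] <- matrix(int2raw(Z), nrow = 4)
  rec[15, ] <- as.raw(0x09)          # return 1 of 1
  rec[16, ] <- as.raw(cls)
  writeBin(as.vector(rec), con)
  invisible(path)
}

.read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file: ", path)
  rb <- function(n, size, ...) readBin(con, integer(), n = n, size = size,
                                       endian = "little", ...)
  rb(1, 2); rb(1, 2); rb(4, 4)       # source id, encoding, GUID
  ver <- readBin(con, raw(), 2)
  readChar(con, 64, useBytes = TRUE) # system id + software
  rb(2, 2)                           # day, year
  rb(1, 2)                           # header size
  offset_to_points <- rb(1, 4)
  rb(1, 4)                           # n VLRs
  fmt <- as.integer(readBin(con, raw(), 1))
  rec_len <- rb(1, 2)
  n <- rb(1, 4)
  rb(5, 4)
  scale <- readBin(con, numeric(), 3, endian = "little")
  off <- readBin(con, numeric(), 3, endian = "little")
  readBin(con, numeric(), 6, endian = "little")
  if (fmt > 5) stop("unsupported LAS point format: ", fmt)
  seek(con, offset_to_points)
  block <- readBin(con, raw(), n * rec_len)
  if (length(block) < n * rec_len) stop("truncated LAS point data: ", path)
  rec <- matrix(block, nrow = rec_len)
  raw2int <- function(r) readBin(as.vector(r), integer(), n = ncol(rec),
                                 size = 4, endian = "little")
  x <- raw2int(rec[1:4, ]) * scale[1] + off[1]
  y <- raw2int(rec[5:8, ]) * scale[2] + off[2]
  z <- raw2int(rec[9:12, ]) * scale[3] + off[3]
  cls <- as.integer(rec[16, ])
  label <- if (all(cls == 0L)) NULL else .label_of_las_class(cls)
  point_cloud(x, y, z, label = label)
}

# ---- ASCII PLY ----

.write_ply <- function(cloud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", n_points(cloud)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(data.frame(cloud$x, cloud$y, cloud$z), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.read_ply <- function(path) {
  header <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("malformed PLY header: ", path)
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 1000) stop("malformed PLY header: ", path)
  }
  if (!identical(trimws(header[1]), "ply")) stop("not a PLY file: ", path)
  if (!any(grepl("^format\\s+ascii", trimws(header))))
    stop("only ASCII PLY is supported: ", path)
  vline <- grep("^element\\s+vertex\\s+", trimws(header), value = TRUE)
  if (!length(vline)) stop("PLY file has no vertex element: ", path)
  n <- as.integer(sub("^element\\s+vertex\\s+(\\d+).*", "\\1", vline[1]))
  props <- sub("^property\\s+\\S+\\s+", "",
               grep("^property\\s", trimws(header), value = TRUE))
  ixyz <- match(c("x", "y", "z"), props)
  if (anyNA(ixyz)) stop("PLY vertex element lacks x/y/z properties: ", path)
  vals <- scan(con, what = numeric(), n = n * length(props), quiet = TRUE)
  m <- matrix(vals, ncol = length(props), byrow = TRUE)
  point_cloud(m[, ixyz[1]], m[, ixyz[2]], m[, ixyz[3]])
}

# ---- XYZ / CSV text ----

.write_xyz <- function(cloud, path) {
  utils::write.csv(data.frame(x = cloud$x, y = cloud$y, z = cloud$z),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_xyz <- function(path) {
  first <- readLines(path, n = 1)
  if (!length(first)) stop("empty point-cloud file: ", path)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  probe <- strsplit(trimws(first), if (sep == ",") "," else "\\s+")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(probe[1:min(3, length(probe))])))
  d <- utils::read.table(path, sep = sep, header = has_header,
                         comment.char = "", strip.white = TRUE)
  if (ncol(d) < 3) stop("XYZ/CSV file must have at least 3 columns: ", path)
  point_cloud(d[[1]], d[[2]], d[[3]])
}
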