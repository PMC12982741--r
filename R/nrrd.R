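#' Read a 3-D NRRD volume
#'
#' Minimal reader for the Nearly Raw Raster Data format as used for CT
#' volumes and segmentation masks: attached headers, 3-D payloads, `raw`,
#' `ascii`/`text` or `gzip` encodings, little/big endian. Voxel spacing is
#' taken from the `space directions` field (required; the diagonal of the
#' direction matrix), falling back to `spacings` if present.
#'
#' @param path path to a `.nrrd` file.
#' @return list with `data` (3-D numeric array) and `spacing` (numeric, mm).
#' @seealso [writeNRRD()]
#' @export
readNRRD <- function(path) {
  if (!file.exists(path)) stop("NRRD file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (length(magic) == 0L || !startsWith(magic, "NRRD"))
    stop("not an NRRD file (bad magic): ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated NRRD header (no blank line): ", path)
    if (line == "") break
    if (startsWith(line, "#")) next
    sep <- regexpr(": ", line, fixed = TRUE)
    if (sep < 0) sep <- regexpr(":=", line, fixed = TRUE)
    if (sep < 0) next
    key <- tolower(substr(line, 1, sep - 1))
    fields[[key]] <- substr(line, sep + 2, nchar(line))
  }
  need <- function(key) {
    if (is.null(fields[[key]])) stop("NRRD header missing required field '", key, "': ", path)
    fields[[key]]
  }
  ndim <- as.integer(need("dimension"))
  if (ndim != 3L) stop("only 3-D NRRD payloads are supported (dimension = ", ndim, ")")
  sizes <- as.integer(strsplit(trimws(need("sizes")), "\\s+")[[1]])
  if (length(sizes) != 3L || any(is.na(sizes)) || any(sizes < 1))
    stop("invalid NRRD 'sizes' field")
  spacing <- nrrdSpacing(fields, path)
  type <- tolower(need("type"))
  enc <- tolower(need("encoding"))
  n <- prod(sizes)
  rinfo <- switch(type,
    "double" = list(what = "double", size = 8L, signed = TRUE),
    "float" = list(what = "double", size = 4L, signed = TRUE),
    "int" = , "int32" = , "signed int" = list(what = "integer", size = 4L, signed = TRUE),
    "short" = , "int16" = , "signed short" = list(what = "integer", size = 2L, signed = TRUE),
    "ushort" = , "uint16" = , "unsigned short" = list(what = "integer", size = 2L, signed = FALSE),
    "uchar" = , "uint8" = , "unsigned char" = list(what = "integer", size = 1L, signed = FALSE),
    stop("unsupported NRRD type: ", type))
  endian <- if (!is.null(fields[["endian"]]) && tolower(fields[["endian"]]) == "big")
    "big" else "little"
  vals <- if (enc %in% c("raw", "gzip", "gz")) {
    if (enc == "raw") {
      readBin(con, rinfo$what, n = n, size = rinfo$size, endian = endian,
              signed = rinfo$signed)
    } else {
      payload <- readBin(con, "raw", n = file.size(path))
      bytes <- memDecompress(payload, type = "gzip")
      rcon <- rawConnection(bytes)
      on.exit(close(rcon), add = TRUE)
      readBin(rcon, rinfo$what, n = n, size = rinfo$size, endian = endian,
              signed = rinfo$signed)
    }
  } else if (enc %in% c("ascii", "text", "txt")) {
    txt <- readLines(con, warn = FALSE)
    as.numeric(strsplit(trimws(paste(txt, collapse = " ")), "\\s+")[[1]])[seq_len(n)]
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) < n || anyNA(vals))
    stop("truncated or corrupt NRRD data payload: ", path)
  list(data = array(as.numeric(vals), sizes), spacing = spacing)
}

nrrdSpacing <- function(fields, path) {
  sd <- fields[["space directions"]]
  if (!is.null(sd)) {
    vecs <- regmatches(sd, gregexpr("\\(([^)]*)\\)", sd))[[1]]
    vecs <- vecs[nzchar(vecs)]
    if (length(vecs) != 3L) stop("NRRD 'space directions' must carry 3 vectors: ", path)
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    return(unname(sqrt(rowSums(m^2))))
  }
  sp <- fields[["spacings"]]
  if (!is.null(sp)) return(as.numeric(strsplit(trimws(sp), "\\s+")[[1]]))
  stop("NRRD header missing spacing metadata (field 'space directions'): ", path)
}

#' Write a 3-D volume as NRRD
#'
#' Writes an attached-header NRRD file with `space directions` encoding the
#' voxel spacing on the diagonal. Raw little-endian encoding by default;
#' `ascii` available for human-readable fixtures. Write/read roundtrips are
#' bit-exact for the data payload in `double` raw encoding.
#'
#' @param data 3-D numeric array.
#' @param path output path.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param type payload type: `"double"`, `"short"` or `"uchar"`.
#' @param encoding `"raw"` (default) or `"ascii"`.
#' @return the path, invisibly.
#' @export
writeNRRD <- function(data, path, spacing = c(1, 1, 1), type = c("double", "short", "uchar"),
                      encoding = c("raw", "ascii")) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L)
  hdr <- c(
    "NRRD0004",
    "# generated by MorphoImprint",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(dim(data), collapse = " ")),
    paste0("space directions: (", spacing[1], ",0,0) (0,", spacing[2], ",0) (0,0,", spacing[3], ")"),
    "kinds: domain domain domain",
    if (type != "uchar" && encoding == "raw") "endian: little",
    paste0("encoding: ", encoding),
    "space origin: (0,0,0)",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(paste(format(as.vector(data), trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  } else {
    size <- switch(type, double = 8L, short = 2L, uchar = 1L)
    vec <- if (type == "double") as.numeric(data) else as.integer(data)
    writeBin(vec, con, size = size, endian = "little")
  }
  invisible(path)
}
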