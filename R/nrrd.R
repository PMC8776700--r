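#' Write and read dose grids as detached-header NRRD
#'
#' Serializes a [dose_grid()] as an NRRD detached header (`.nhdr`) plus a
#' data file, for interoperability with medical-imaging viewers. `raw`
#' encoding writes little-endian doubles; `ascii` writes plain-text numbers.
#' The first (fastest) NRRD axis is LR, matching the array layout.
#'
#' @param grid a [dose_grid()].
#' @param path header file path (`.nhdr`).
#' @param encoding `"raw"` (default) or `"ascii"`.
#' @return [write_dose_nrrd()] returns `path` invisibly; [read_dose_nrrd()]
#'   returns a [dose_grid()].
#' @export
write_dose_nrrd <- function(grid, path, encoding = c("raw", "ascii")) {
  stopifnot(inherits(grid, "dose_grid"))
  encoding <- match.arg(encoding)
  ext <- if (encoding == "raw") ".raw" else ".txt"
  data_file <- paste0(sub("\\.nhdr$", "", path), ext)
  d <- dim(grid$dose_gy)
  hdr <- c(
    "NRRD0004",
    "# dose grid (LR, CC, AP), Gy",
    "type: double",
    "dimension: 3",
    paste("sizes:", paste(d, collapse = " ")),
    paste0("encoding: ", encoding),
    if (encoding == "raw") "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
            grid$spacing_mm[1], grid$spacing_mm[2], grid$spacing_mm[3]),
    sprintf("space origin: (%g,%g,%g)", grid$origin_mm[1], grid$origin_mm[2],
            grid$origin_mm[3]),
    paste("data file:", basename(data_file)))
  writeLines(hdr, path)
  if (encoding == "raw") {
    con <- file(data_file, "wb")
    on.exit(close(con))
    writeBin(as.numeric(grid$dose_gy), con, size = 8L, endian = "little")
  } else {
    writeLines(format(as.numeric(grid$dose_gy), digits = 17,
                      scientific = TRUE, trim = TRUE), data_file)
  }
  invisible(path)
}

#' @rdname write_dose_nrrd
#' @export
read_dose_nrrd <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "NRRD")) stop("not an NRRD header: ", path)
  field <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(ln)) stop("NRRD header missing field '", key, "'")
    sub(paste0("^", key, ": "), "", ln[1])
  }
  sizes <- as.integer(strsplit(field("sizes"), " ")[[1]])
  encoding <- field("encoding")
  nums <- function(s) as.numeric(regmatches(s, gregexpr("-?[0-9.eE+]+", s))[[1]])
  dirs <- nums(field("space directions"))
  spacing <- c(dirs[1], dirs[5], dirs[9])
  origin <- nums(field("space origin"))
  data_file <- file.path(dirname(path), field("data file"))
  n <- prod(sizes)
  vals <- if (encoding == "raw") {
    con <- file(data_file, "rb")
    on.exit(close(con))
    readBin(con, "numeric", n = n, size = 8L, endian = "little")
  } else as.numeric(readLines(data_file))
  dose_grid(array(vals, dim = sizes), spacing, origin)
}
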