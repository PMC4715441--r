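## Mesh ingestion. Hull fitting depends only on the vertex set, so readers
## consume vertex records exclusively and ignore faces, normals and any
## non-manifold defects of the source mesh. OBJ, PLY (ascii and binary
## little-endian) and STL (ascii and binary) are supported, one file per
## functional unit.

#' Read mesh vertices as a point cloud
#'
#' Dispatches on file extension (`.obj`, `.ply`, `.stl`) and returns only
#' the vertex coordinates; connectivity is discarded because a convex hull
#' depends on the point set alone. Coordinates are taken to be millimetres.
#'
#' @param path mesh file path.
#' @return n x 3 numeric matrix of vertex coordinates (mm).
#' @export
read_mesh_vertices <- function(path) {
  if (!file.exists(path)) chm_error("io", sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  pts <- switch(ext,
    obj = read_obj_vertices(path),
    ply = read_ply_vertices(path),
    stl = read_stl_vertices(path),
    chm_error("io", sprintf("unsupported mesh format '.%s' (%s)", ext, path)))
  as_points(pts)
}

read_obj_vertices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  v <- lines[grepl("^v[ \t]", lines)]
  if (length(v) == 0L) chm_error("io", sprintf("no vertex records in %s", path))
  toks <- strsplit(trimws(v), "[ \t]+")
  do.call(rbind, lapply(toks, function(t) as.numeric(t[2:4])))
}

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  size <- ply_type_size[[type]]
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", 1L, size = size, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = size, signed = signed || size == 4L,
            endian = "little")
  }
}

read_ply_vertices <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  ## locate the header terminator at byte level; the body may be binary
  hit <- grepRaw("end_header", raw, fixed = TRUE)
  if (length(hit) == 0L) chm_error("io", sprintf("%s: PLY header not terminated", path))
  body_off <- hit + 10L
  if (body_off <= length(raw) && raw[body_off] == as.raw(13L)) body_off <- body_off + 1L
  if (body_off <= length(raw) && raw[body_off] == as.raw(10L)) body_off <- body_off + 1L
  hdr <- trimws(strsplit(rawToChar(raw[seq_len(hit - 1L)]), "\r?\n")[[1]])
  fmt <- sub("^format\\s+", "", hdr[grepl("^format", hdr)][1])
  is_ascii <- grepl("^ascii", fmt)
  if (!is_ascii && !grepl("^binary_little_endian", fmt)) {
    chm_error("io", sprintf("%s: unsupported PLY format '%s'", path, fmt))
  }

  ## parse element/property declarations in order
  elements <- list()
  for (line in hdr) {
    if (grepl("^element\\s", line)) {
      t <- strsplit(line, "\\s+")[[1]]
      elements[[length(elements) + 1L]] <-
        list(name = t[2], count = as.integer(t[3]), props = list())
    } else if (grepl("^property\\s", line)) {
      t <- strsplit(line, "\\s+")[[1]]
      i <- length(elements)
      p <- if (t[2] == "list") {
        list(name = t[5], type = t[4], list = TRUE, count_type = t[3])
      } else {
        list(name = t[3], type = t[2], list = FALSE)
      }
      elements[[i]]$props[[length(elements[[i]]$props) + 1L]] <- p
    }
  }
  vi <- which(vapply(elements, function(e) e$name == "vertex", logical(1)))[1]
  if (is.na(vi)) chm_error("io", sprintf("%s: PLY file has no vertex element", path))

  if (is_ascii) {
    body <- strsplit(rawToChar(raw[body_off:length(raw)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    skip <- if (vi > 1L) sum(vapply(elements[seq_len(vi - 1L)], `[[`, integer(1), "count")) else 0L
    vlines <- body[skip + seq_len(elements[[vi]]$count)]
    toks <- strsplit(trimws(vlines), "\\s+")
    pnames <- vapply(elements[[vi]]$props, `[[`, character(1), "name")
    xyz <- match(c("x", "y", "z"), pnames)
    if (anyNA(xyz)) chm_error("io", sprintf("%s: vertex element lacks x/y/z", path))
    return(do.call(rbind, lapply(toks, function(t) as.numeric(t[xyz]))))
  }

  con <- rawConnection(raw[body_off:length(raw)], "rb")
  on.exit(close(con))
  out <- NULL
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    if (i > vi) break
    fixed <- !any(vapply(el$props, `[[`, logical(1), "list"))
    if (el$name != "vertex") {
      if (!fixed) {
        chm_error("io", sprintf(
          "%s: list-typed element '%s' precedes vertices; unsupported layout",
          path, el$name))
      }
      nbytes <- sum(vapply(el$props, function(p) ply_type_size[[p$type]], integer(1)))
      readBin(con, "raw", el$count * nbytes)
      next
    }
    pnames <- vapply(el$props, `[[`, character(1), "name")
    if (!all(c("x", "y", "z") %in% pnames)) {
      chm_error("io", sprintf("%s: vertex element lacks x/y/z", path))
    }
    out <- matrix(NA_real_, el$count, 3L)
    for (v in seq_len(el$count)) {
      for (p in el$props) {
        if (p$list) {
          nitem <- ply_read_scalar(con, p$count_type)
          for (k in seq_len(nitem)) ply_read_scalar(con, p$type)
        } else {
          val <- ply_read_scalar(con, p$type)
          j <- match(p$name, c("x", "y", "z"))
          if (!is.na(j)) out[v, j] <- val
        }
      }
    }
  }
  out
}

read_stl_vertices <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  looks_ascii <- length(grepRaw("^\\s*solid", raw[seq_len(min(length(raw), 80L))])) > 0L &&
    length(grepRaw("facet", raw[seq_len(min(length(raw), 1024L))], fixed = TRUE)) > 0L
  if (looks_ascii) {
    lines <- readLines(path, warn = FALSE)
    v <- trimws(lines[grepl("^\\s*vertex\\s", lines)])
    if (length(v) > 0L) {
      toks <- strsplit(v, "\\s+")
      return(do.call(rbind, lapply(toks, function(t) as.numeric(t[2:4]))))
    }
  }
  ## binary: 80-byte header, uint32 triangle count, 50 bytes per triangle
  if (length(raw) < 84L) chm_error("io", sprintf("%s: truncated STL", path))
  con <- rawConnection(raw, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(raw) != 84L + 50L * ntri) {
    chm_error("io", sprintf("%s: STL size inconsistent with triangle count", path))
  }
  out <- matrix(NA_real_, 3L * ntri, 3L)
  for (t in seq_len(ntri)) {
    vals <- readBin(con, "double", 12L, size = 4L, endian = "little")
    out[3L * (t - 1L) + 1:3, ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", 2L) # attribute byte count
  }
  out
}

#' Read a skeleton from a directory of mesh files
#'
#' With a manifest (CSV with columns `file,label,is_foot`) segments are
#' named and feet flagged explicitly; without one, every `.obj`/`.ply`/`.stl`
#' file in the directory becomes a segment named after its filename stem and
#' no segment is treated as a foot.
#'
#' @param dir directory containing one mesh file per functional unit.
#' @param manifest optional path to a manifest CSV.
#' @param specimen specimen identifier.
#' @return a [skeleton_segments()] object.
#' @export
read_skeleton_meshes <- function(dir, manifest = NULL, specimen = basename(dir)) {
  if (!is.null(manifest)) {
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    need <- c("file", "label", "is_foot")
    if (!all(need %in% names(man))) {
      chm_error("io", sprintf("manifest must have columns %s", paste(need, collapse = ",")))
    }
    files <- ifelse(file.exists(man$file), man$file, file.path(dir, man$file))
    labels <- man$label
    feet <- man$label[as.logical(man$is_foot)]
  } else {
    files <- list.files(dir, "\\.(obj|ply|stl)$", ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L) chm_error("io", sprintf("no mesh files found in %s", dir))
    labels <- tools::file_path_sans_ext(basename(files))
    feet <- character()
  }
  segs <- lapply(seq_along(files), function(i) {
    point_set(labels[i], read_mesh_vertices(files[i]))
  })
  skeleton_segments(segs, feet_labels = feet, specimen = specimen)
}

#' Write a convex polytope as an OBJ mesh
#'
#' For visual inspection of fitted hulls in any mesh viewer.
#'
#' @param poly a `convex_polytope`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_polytope_obj <- function(poly, path) {
  v <- sprintf("v %.10g %.10g %.10g",
               poly$vertices[, 1], poly$vertices[, 2], poly$vertices[, 3])
  f <- sprintf("f %d %d %d", poly$faces[, 1], poly$faces[, 2], poly$faces[, 3])
  writeLines(c(sprintf("# convex hull%s",
                       if (is.null(poly$label)) "" else paste0(" ", poly$label)),
               v, f), path)
  invisible(path)
}
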