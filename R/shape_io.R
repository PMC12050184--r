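# Readers and writers for point clouds (XYZ, PLY, OBJ, ASCII STL),
# landmark files (CSV/JSON) and serialized model archives. All coordinates
# are mm throughout; no unit conversion is ever applied.

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "obj", "xyz", "stl")) ext
  else stopf("cannot infer point-cloud format from extension of '%s'", path)
}

#' Read a point cloud or mesh
#'
#' Reads XYZ (whitespace-separated coordinates, optional normals), PLY
#' (ASCII or binary little-endian), OBJ (`v` records) or ASCII STL. Point
#' order is preserved exactly as stored; for meshes (STL/OBJ) the unique
#' vertices are returned in file order, with STL duplicate vertices merged
#' by exact coordinate equality.
#'
#' @param path File path.
#' @param fmt One of `"auto"`, `"xyz"`, `"ply"`, `"obj"`, `"stl"`; `"auto"`
#'   infers from the file extension.
#' @param subject_id Subject identifier attached to the cloud.
#' @return A [point_cloud].
#' @export
read_point_cloud <- function(path, fmt = "auto", subject_id = "") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  fmt <- match.arg(fmt, c("auto", "xyz", "ply", "obj", "stl"))
  if (fmt == "auto") fmt <- detect_format(path)
  out <- switch(fmt,
    xyz = read_xyz(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl_ascii(path)
  )
  if (nrow(out$points) < 4L)
    stopf("%s: only %d point(s); at least 4 are required", path,
          nrow(out$points))
  point_cloud(out$points, out$normals, subject_id = subject_id)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[[i]]), "[[:space:],]+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (!(length(val) %in% c(3L, 6L)) || anyNA(val))
      stopf("%s: malformed XYZ record at line %d: '%s'", path, i, lines[[i]])
    val
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L)
    stopf("%s: mixed 3- and 6-column XYZ records", path)
  m <- do.call(rbind, rows)
  if (ncols == 6L) list(points = m[, 1:3, drop = FALSE],
                        normals = m[, 4:6, drop = FALSE])
  else list(points = m, normals = NULL)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stopf("%s: unterminated PLY header", path)
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
    if (length(header) > 200L) stopf("%s: PLY header too long", path)
  }
  if (!grepl("^ply", header[1]))
    stopf("%s: not a PLY file (missing 'ply' magic)", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) stopf("%s: missing PLY format line", path)
  fmt <- strsplit(trimws(fmt_line), "[[:space:]]+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stopf("%s: unsupported PLY format '%s'", path, fmt)

  # Parse elements/properties; we only interpret the leading vertex element.
  el_idx <- grep("^element ", header)
  if (length(el_idx) == 0L) stopf("%s: PLY file declares no elements", path)
  first_el <- strsplit(trimws(header[el_idx[1]]), "[[:space:]]+")[[1]]
  if (first_el[2] != "vertex")
    stopf("%s: first PLY element must be 'vertex', got '%s'", path,
          first_el[2])
  nvert <- as.integer(first_el[3])
  prop_end <- if (length(el_idx) > 1L) el_idx[2] - 1L else length(header) - 1L
  prop_lines <- grep("^property ", header[el_idx[1]:prop_end], value = TRUE)
  props <- lapply(prop_lines, function(p) {
    tok <- strsplit(trimws(p), "[[:space:]]+")[[1]]
    if (tok[2] == "list")
      stopf("%s: list property '%s' not supported in vertex element", path,
            tok[length(tok)])
    list(type = tok[2], name = tok[3])
  })
  pnames <- vapply(props, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% pnames))
    stopf("%s: PLY vertex element lacks x/y/z properties", path)

  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (fmt == "ascii") {
    lines <- readLines(con, n = nvert)
    if (length(lines) < nvert)
      stopf("%s: expected %d vertex records, found %d", path, nvert,
            length(lines))
    m <- matrix(NA_real_, nvert, length(props))
    for (i in seq_len(nvert)) {
      val <- suppressWarnings(as.numeric(
        strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]))
      if (length(val) < length(props) || anyNA(val[seq_along(props)]))
        stopf("%s: malformed PLY vertex record %d: '%s'", path, i, lines[[i]])
      m[i, ] <- val[seq_along(props)]
    }
  } else {
    m <- matrix(NA_real_, nvert, length(props))
    for (i in seq_len(nvert)) {
      for (j in seq_along(props)) {
        tp <- props[[j]]$type
        if (!tp %in% names(sizes))
          stopf("%s: unknown PLY property type '%s'", path, tp)
        sz <- sizes[[tp]]
        v <- if (tp %in% c("float", "float32", "double", "float64")) {
          readBin(con, "double", n = 1L, size = sz, endian = "little")
        } else {
          readBin(con, "integer", n = 1L, size = sz, endian = "little",
                  signed = !(tp %in% c("uchar", "uint8", "ushort", "uint16")))
        }
        if (length(v) == 0L)
          stopf("%s: truncated binary PLY at vertex %d", path, i)
        m[i, j] <- as.double(v)
      }
    }
  }
  pts <- m[, match(c("x", "y", "z"), pnames), drop = FALSE]
  nrm <- NULL
  if (all(c("nx", "ny", "nz") %in% pnames))
    nrm <- m[, match(c("nx", "ny", "nz"), pnames), drop = FALSE]
  list(points = pts, normals = nrm)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vidx <- grep("^v([[:space:]])", lines)
  if (length(vidx) == 0L) stopf("%s: no OBJ 'v' records found", path)
  rows <- lapply(vidx, function(i) {
    tok <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]][-1]
    val <- suppressWarnings(as.numeric(tok[1:3]))
    if (anyNA(val))
      stopf("%s: malformed OBJ vertex at line %d: '%s'", path, i, lines[[i]])
    val
  })
  list(points = do.call(rbind, rows), normals = NULL)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^\\s*solid", lines[1]))
    stopf("%s: not an ASCII STL file (missing 'solid' header)", path)
  vidx <- grep("^\\s*vertex\\s", lines)
  if (length(vidx) == 0L) stopf("%s: no STL vertex records found", path)
  rows <- lapply(vidx, function(i) {
    tok <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]][-1]
    val <- suppressWarnings(as.numeric(tok))
    if (length(val) != 3L || anyNA(val))
      stopf("%s: malformed STL vertex at line %d: '%s'", path, i, lines[[i]])
    val
  })
  m <- do.call(rbind, rows)
  # Merge duplicate vertices by exact equality, keeping first-occurrence
  # order (no tolerance: deterministic).
  keep <- !duplicated(m)
  list(points = m[keep, , drop = FALSE], normals = NULL)
}

#' Write a point cloud
#'
#' Writes XYZ, ASCII PLY or OBJ. Coordinates are formatted with 17
#' significant digits so that reading the file back reproduces them
#' bit-for-bit. PLY output includes normal properties only when the cloud
#' carries normals.
#'
#' @param cloud A [point_cloud].
#' @param path Output path.
#' @param fmt `"auto"` (from extension), `"xyz"`, `"ply"` or `"obj"`.
#' @return Invisibly, `path`.
#' @export
write_point_cloud <- function(cloud, path, fmt = "auto") {
  stopifnot(inherits(cloud, "point_cloud"))
  fmt <- match.arg(fmt, c("auto", "xyz", "ply", "obj"))
  if (fmt == "auto") fmt <- detect_format(path)
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("target directory does not exist: %s", dir)
  num <- function(m) apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                                   collapse = " "))
  ok <- tryCatch({
    if (fmt == "xyz") {
      m <- cloud$points
      if (!is.null(cloud$normals)) m <- cbind(m, cloud$normals)
      writeLines(num(m), path)
    } else if (fmt == "obj") {
      writeLines(paste("v", num(cloud$points)), path)
    } else {
      has_n <- !is.null(cloud$normals)
      header <- c("ply", "format ascii 1.0",
                  sprintf("element vertex %d", n_points(cloud)),
                  "property double x", "property double y",
                  "property double z")
      if (has_n) header <- c(header, "property double nx",
                             "property double ny", "property double nz")
      header <- c(header, "end_header")
      m <- cloud$points
      if (has_n) m <- cbind(m, cloud$normals)
      writeLines(c(header, num(m)), path)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("failed to write '%s': %s", path,
                         conditionMessage(ok))
  invisible(path)
}

#' Read a landmark file
#'
#' Accepts CSV with columns `name,x,y,z` (header optional, names matched
#' case-insensitively) or JSON mapping `A`/`B`/`C`/`D` to 3-vectors. Units
#' are mm.
#'
#' @param path File path (`.json` selects the JSON reader).
#' @return A [landmark_set].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (tolower(tools::file_ext(path)) == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    names(obj) <- toupper(names(obj))
    recs <- lapply(obj, as.numeric)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) && grepl("^\\s*name\\s*,", lines[1], ignore.case = TRUE))
      lines <- lines[-1]
    recs <- list()
    for (i in seq_along(lines)) {
      tok <- strsplit(trimws(lines[[i]]), "\\s*,\\s*")[[1]]
      if (length(tok) != 4L)
        stopf("%s: malformed landmark record at line %d: '%s'", path, i,
              lines[[i]])
      nm <- toupper(tok[1])
      val <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(val))
        stopf("%s: non-numeric landmark coordinates at line %d", path, i)
      if (nm %in% names(recs))
        stopf("%s: duplicate rows for landmark %s (ambiguous)", path, nm)
      recs[[nm]] <- val
    }
  }
  missing <- setdiff(c("A", "B", "C", "D"), names(recs))
  if (length(missing))
    stopf("%s: missing landmark(s): %s", path, paste(missing, collapse = ", "))
  landmark_set(recs$A, recs$B, recs$C, recs$D)
}

#' Write a landmark file
#'
#' @param landmarks A [landmark_set].
#' @param path Output CSV path (header `name,x,y,z`).
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  rows <- vapply(c("A", "B", "C", "D"), function(nm) {
    paste(c(nm, sprintf("%.17g", landmarks[[nm]])), collapse = ",")
  }, "")
  writeLines(c("name,x,y,z", rows), path)
  invisible(path)
}

ARCHIVE_FORMAT <- "radssm-model"
ARCHIVE_VERSION <- 1L

#' Save or load a model archive
#'
#' Serializes a [shape_model] or a neural-network classifier to a versioned
#' archive that records the creation seed and configuration. Loading
#' reproduces all numeric fields to full precision; truncated files raise an
#' integrity error and archives of the wrong type raise a type error naming
#' the expected and actual type.
#'
#' @param model A `shape_model` or `nn_classifier` object.
#' @param path Archive path.
#' @param seed,config Optional provenance recorded in the archive.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   stored model.
#' @export
save_model <- function(model, path, seed = NULL, config = NULL) {
  type <- if (inherits(model, "shape_model")) "shape_model"
  else if (inherits(model, "nn_classifier")) "nn_classifier"
  else stopf("save_model: unsupported object of class '%s'", class(model)[1])
  archive <- list(format = ARCHIVE_FORMAT, version = ARCHIVE_VERSION,
                  type = type, seed = seed, config = config, payload = model)
  saveRDS(archive, path)
  invisible(path)
}

#' @param expected_type Optional `"shape_model"` or `"nn_classifier"`; a
#'   mismatch raises a type error.
#' @rdname save_model
#' @export
load_model <- function(path, expected_type = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  archive <- tryCatch(readRDS(path), error = function(e)
    stopf("integrity error reading '%s': %s", path, conditionMessage(e)))
  if (!is.list(archive) || !identical(archive$format, ARCHIVE_FORMAT))
    stopf("integrity error: '%s' is not a %s archive", path, ARCHIVE_FORMAT)
  if (!identical(as.integer(archive$version), ARCHIVE_VERSION))
    stopf("version mismatch in '%s': archive version %s, supported version %d",
          path, archive$version, ARCHIVE_VERSION)
  if (!is.null(expected_type) && !identical(archive$type, expected_type))
    stopf("type error in '%s': expected %s, actual %s", path, expected_type,
          archive$type)
  archive$payload
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `cloud,landmarks,group` listing one
#' subject per row; `landmarks` may be empty. Group labels must come from
#' the fixed vocabulary normal/colles/smith/barton and cloud paths must be
#' unique. Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A data frame with columns `cloud`, `landmarks` (NA when absent)
#'   and `group` (factor).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cloud", "group")
  if (!all(need %in% names(df)))
    stopf("%s: manifest must have columns 'cloud' and 'group'", path)
  if (is.null(df$landmarks)) df$landmarks <- NA_character_
  df$landmarks[!nzchar(trimws(ifelse(is.na(df$landmarks), "",
                                     df$landmarks)))] <- NA_character_
  bad <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad))
    stopf("%s: unknown group label(s): %s", path, paste(bad, collapse = ", "))
  if (anyDuplicated(df$cloud))
    stopf("%s: duplicate cloud paths in manifest", path)
  base <- dirname(path)
  resolve <- function(p) ifelse(is.na(p) | grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  df$cloud <- resolve(df$cloud)
  df$landmarks <- resolve(df$landmarks)
  df$group <- factor(df$group, levels = GROUP_LEVELS)
  df
}

# Fixed group vocabulary, in the declared class order used throughout
# (normal first, then the three fracture types).
GROUP_LEVELS <- c("normal", "barton", "colles", "smith")
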