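#' Point cloud and triangle mesh containers
#'
#' Lightweight S3 carriers for the two geometry representations the package
#' works on: bare 3D point sets (the alpha-shape substrate) and triangulated
#' surfaces (the curvature-energy substrate). `size_factor` records the
#' divisor applied by [normalize_size()] so raw scale can always be recovered.
#'
#' @param points,vertices numeric matrix with 3 columns (x, y, z).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param size_factor positive scalar; 1 for unnormalised geometry.
#' @return An object of class `point_cloud` or `tri_mesh`.
#' @export
point_cloud <- function(points, size_factor = 1) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop_os("points must have 3 columns", "parameter")
  if (!is.numeric(points) || anyNA(points)) {
    stop_os("points must be numeric without missing values", "parameter")
  }
  if (size_factor <= 0) stop_os("size_factor must be > 0", "parameter")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, size_factor = size_factor),
            class = "point_cloud")
}

#' @rdname point_cloud
#' @export
tri_mesh <- function(vertices, faces, size_factor = 1) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop_os("vertices must have 3 columns", "parameter")
  if (nrow(vertices) < 4) stop_os("a mesh needs at least 4 vertices", "degenerate_geometry")
  if (anyNA(vertices) || anyNA(faces)) stop_os("mesh contains missing values", "corrupt_input")
  if (min(faces) < 1 || max(faces) > nrow(vertices)) {
    stop_os("face indices out of range", "corrupt_input")
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3])) {
    stop_os("faces with repeated vertices", "corrupt_input")
  }
  if (size_factor <= 0) stop_os("size_factor must be > 0", "parameter")
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  structure(list(vertices = vertices, faces = faces, size_factor = size_factor),
            class = "tri_mesh")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("<point_cloud> ", nrow(x$points), " points, size_factor ",
      signif(x$size_factor, 6), "\n", sep = "")
  invisible(x)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("<tri_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces, size_factor ", signif(x$size_factor, 6), "\n", sep = "")
  invisible(x)
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sqrt(rowSums(cr^2)) / 2
}

#' Total surface area of a triangle mesh
#' @param m a [tri_mesh()].
#' @return scalar area in squared mesh units.
#' @export
mesh_area <- function(m) sum(face_areas(m$vertices, m$faces))

#' Read a binarised 8-bit voxel volume
#'
#' `.raw` files carry no header, so grid dimensions and voxel spacing come
#' either from arguments or from a YAML sidecar (`<path>.yaml` with fields
#' `dims`, `spacing_um`, `order: zyx`). A voxel is occupied where its byte
#' value is greater than zero. Fastest-varying axis is x, slowest z.
#'
#' @param path path to the `.raw` file.
#' @param dims integer vector of length 3 (nx, ny, nz); `NULL` to use sidecar.
#' @param spacing voxel edge length in micrometres; `NULL` to use sidecar.
#' @return A `voxel_volume`: list of `occupancy` (3D logical array),
#'   `dims`, `spacing`.
#' @export
read_raw_volume <- function(path, dims = NULL, spacing = NULL) {
  if (!file.exists(path)) stop_os(paste0("cannot read ", path), "io")
  if (is.null(dims) || is.null(spacing)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar)) {
      stop_os("dims/spacing not given and no sidecar YAML found", "corrupt_input")
    }
    meta <- yaml::read_yaml(sidecar)
    if (is.null(dims)) dims <- as.integer(meta$dims)
    if (is.null(spacing)) spacing <- as.numeric(meta$spacing_um)
  }
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims <= 0)) stop_os("dims must be 3 positive integers", "parameter")
  if (spacing <= 0) stop_os("spacing must be > 0", "parameter")
  expected <- prod(dims)
  actual <- file.size(path)
  if (actual != expected) {
    stop_os(sprintf("file size %d bytes but dims imply %d", actual, expected),
            "corrupt_input")
  }
  bytes <- readBin(path, what = "raw", n = expected)
  occ <- array(as.integer(bytes) > 0L, dim = dims)
  if (!any(occ)) stop_os("volume has no occupied voxels", "empty_specimen")
  structure(list(occupancy = occ, dims = dims, spacing = spacing),
            class = "voxel_volume")
}

#' Convert an occupied-voxel volume to a point cloud
#'
#' One point per occupied voxel at the voxel centre, `(i - 0.5) * spacing`
#' on each axis (1-based indices), ordered lexicographically by (z, y, x).
#'
#' @param vol a `voxel_volume` from [read_raw_volume()].
#' @return A [point_cloud()] in micrometres.
#' @export
volume_to_pointcloud <- function(vol) {
  occ <- which(vol$occupancy)
  if (length(occ) == 0) stop_os("volume has no occupied voxels", "empty_specimen")
  idx <- arrayInd(occ, vol$dims)
  ord <- order(idx[, 3], idx[, 2], idx[, 1])
  idx <- idx[ord, , drop = FALSE]
  point_cloud((idx - 0.5) * vol$spacing)
}

#' Decimate a point cloud by seeded uniform subsampling
#'
#' @param pc a [point_cloud()].
#' @param n_target number of points to keep (>= 4).
#' @param seed RNG seed making the subsample reproducible.
#' @return A [point_cloud()] with at most `n_target` points.
#' @export
decimate_pointcloud <- function(pc, n_target, seed = 20230301) {
  if (n_target < 4) stop_os("n_target must be >= 4", "parameter")
  n <- nrow(pc$points)
  if (n <= n_target) return(pc)
  keep <- with_seed(seed, sort(sample.int(n, n_target)))
  point_cloud(pc$points[keep, , drop = FALSE], size_factor = pc$size_factor)
}

#' Remove the effect of size from geometry
#'
#' Translates to the centroid and divides coordinates by centroid size — the
#' root-mean-square distance of points (or mesh vertices) from their
#' centroid, the standard size measure in geometric morphometrics. The
#' divisor is recorded in `size_factor`. Idempotent.
#'
#' @param g a [point_cloud()] or [tri_mesh()].
#' @return The same class of object with centroid size 1.
#' @export
normalize_size <- function(g) UseMethod("normalize_size")

.normalize_coords <- function(xyz) {
  centroid <- colMeans(xyz)
  centred <- sweep(xyz, 2, centroid)
  cs <- sqrt(mean(rowSums(centred^2)))
  if (cs <= 1e-300) stop_os("all points coincide: centroid size is zero", "degenerate_geometry")
  list(coords = centred / cs, size = cs)
}

#' @export
normalize_size.point_cloud <- function(g) {
  nz <- .normalize_coords(g$points)
  point_cloud(nz$coords, size_factor = g$size_factor * nz$size)
}

#' @export
normalize_size.tri_mesh <- function(g) {
  nz <- .normalize_coords(g$vertices)
  tri_mesh(nz$coords, g$faces, size_factor = g$size_factor * nz$size)
}

#' Decimate a triangle mesh by shortest-edge collapse
#'
#' Collapses edges (shortest first, midpoint placement) under link-condition
#' and normal-flip guards until the face count reaches `target_faces`.
#' Deterministic for a fixed input. A mesh already at or below the target is
#' returned unchanged.
#'
#' @param m a [tri_mesh()].
#' @param target_faces desired face count (>= 4).
#' @return A [tri_mesh()] with face count within 10% of `target_faces`.
#' @export
decimate_mesh <- function(m, target_faces) {
  if (target_faces < 4) stop_os("target_faces must be >= 4", "parameter")
  if (nrow(m$faces) <= target_faces) return(m)
  out <- decimate_mesh_cpp(m$vertices, m$faces, as.integer(target_faces))
  if (nrow(out$vertices) < 4) {
    stop_os("decimation left fewer than 4 vertices", "degenerate_geometry")
  }
  if (nrow(out$faces) > 1.1 * target_faces) {
    warn(sprintf("decimation stalled at %d faces (target %d): remaining collapses illegal",
                 nrow(out$faces), target_faces))
  }
  tri_mesh(out$vertices, out$faces, size_factor = m$size_factor)
}

# ---- mesh file IO (PLY ascii / binary little-endian, OBJ triangles) --------

#' Read a triangle mesh from PLY or OBJ
#'
#' Supports ascii and binary little-endian PLY with float/double vertex
#' properties, and OBJ files with triangular faces. Non-triangle faces are
#' rejected.
#'
#' @param path file path ending in `.ply` or `.obj`.
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop_os(paste0("cannot read ", path), "io")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = .read_ply(path),
    obj = .read_obj(path),
    stop_os(paste0("unsupported mesh format: .", ext), "io")
  )
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop_os("unterminated PLY header", "corrupt_input")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (!grepl("^ply", header[1])) stop_os("not a PLY file", "corrupt_input")
  fmt_line <- grep("^format", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line)) {
    stop_os("only ascii and binary_little_endian PLY supported", "io")
  }
  elements <- list()
  cur <- NULL
  for (line in header) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (toks[1] == "element") {
      cur <- toks[2]
      elements[[cur]] <- list(count = as.integer(toks[3]), props = list())
    } else if (toks[1] == "property" && !is.null(cur)) {
      elements[[cur]]$props[[length(elements[[cur]]$props) + 1]] <- toks[-1]
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face)) {
    stop_os("PLY lacks vertex or face element", "corrupt_input")
  }
  nv <- elements$vertex$count
  nf <- elements$face$count
  vprops <- elements$vertex$props
  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
                 int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  if (binary) {
    sizes <- vapply(vprops, function(p) type_size[[p[1]]], numeric(1))
    names_v <- vapply(vprops, function(p) p[2], character(1))
    V <- matrix(NA_real_, nv, 3)
    for (i in seq_len(nv)) {
      for (j in seq_along(vprops)) {
        tp <- vprops[[j]][1]
        val <- if (tp %in% c("float", "float32")) {
          readBin(con, "numeric", 1, size = 4, endian = "little")
        } else if (tp %in% c("double", "float64")) {
          readBin(con, "numeric", 1, size = 8, endian = "little")
        } else {
          readBin(con, "integer", 1, size = sizes[j], endian = "little")
        }
        if (names_v[j] == "x") V[i, 1] <- val
        if (names_v[j] == "y") V[i, 2] <- val
        if (names_v[j] == "z") V[i, 3] <- val
      }
    }
    F <- matrix(NA_integer_, nf, 3)
    cprop <- elements$face$props[[1]]  # list <count type> <index type> name
    csz <- type_size[[cprop[2]]]
    isz <- type_size[[cprop[3]]]
    for (i in seq_len(nf)) {
      k <- readBin(con, "integer", 1, size = csz, endian = "little")
      if (k != 3) stop_os("non-triangular PLY face", "corrupt_input")
      F[i, ] <- readBin(con, "integer", 3, size = isz, endian = "little")
    }
  } else {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    if (length(body) < nv + nf) stop_os("truncated PLY body", "corrupt_input")
    names_v <- vapply(vprops, function(p) p[2], character(1))
    vt <- do.call(rbind, lapply(body[seq_len(nv)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    V <- vt[, match(c("x", "y", "z"), names_v), drop = FALSE]
    F <- do.call(rbind, lapply(body[nv + seq_len(nf)], function(l) {
      toks <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
      if (toks[1] != 3) stop_os("non-triangular PLY face", "corrupt_input")
      toks[2:4]
    }))
  }
  tri_mesh(V, F + 1L)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(flines) == 0) {
    stop_os("OBJ lacks vertices or faces", "corrupt_input")
  }
  V <- do.call(rbind, lapply(vlines, function(l) {
    as.numeric(strsplit(trimws(sub("^v", "", l)), "\\s+")[[1]][1:3])
  }))
  F <- do.call(rbind, lapply(flines, function(l) {
    toks <- strsplit(trimws(sub("^f", "", l)), "\\s+")[[1]]
    if (length(toks) != 3) stop_os("non-triangular OBJ face", "corrupt_input")
    as.integer(vapply(strsplit(toks, "/"), `[[`, character(1), 1))
  }))
  tri_mesh(V, F)
}

#' Write a triangle mesh to PLY (ascii) or OBJ
#'
#' @param m a [tri_mesh()].
#' @param path destination; format from the extension (`.ply` or `.obj`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(m, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(m$vertices)),
                 "property double x", "property double y", "property double z",
                 paste("element face", nrow(m$faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(m$vertices, 1, function(v) {
      paste(format(v, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")
    }), con)
    writeLines(paste(3, m$faces[, 1] - 1L, m$faces[, 2] - 1L, m$faces[, 3] - 1L), con)
  } else if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(apply(m$vertices, 1, function(v) {
      paste("v", paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
                       collapse = " "))
    }), con)
    writeLines(paste("f", m$faces[, 1], m$faces[, 2], m$faces[, 3]), con)
  } else {
    stop_os(paste0("unsupported mesh format: .", ext), "io")
  }
  invisible(path)
}

#' Write a point cloud as an ascii PLY
#' @param pc a [point_cloud()].
#' @param path destination `.ply` path.
#' @return `path`, invisibly.
#' @export
write_pointcloud <- function(pc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(pc$points)),
               "property double x", "property double y", "property double z",
               "end_header"), con)
  writeLines(apply(pc$points, 1, function(v) {
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")
  }), con)
  invisible(path)
}

#' Read a point cloud from a vertex-only (or full) PLY
#' @param path a `.ply` file; faces, if present, are ignored.
#' @return A [point_cloud()].
#' @export
read_pointcloud <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- which(trimws(lines) == "end_header")[1]
  if (is.na(end)) stop_os("not an ascii PLY point file", "corrupt_input")
  nv <- as.integer(sub("element vertex\\s+", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  body <- lines[(end + 1):(end + nv)]
  V <- do.call(rbind, lapply(body, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])
  }))
  point_cloud(V)
}

# ---- tabular IO ------------------------------------------------------------

.table_schemas <- list(
  life_history = c("species", "male_mass", "female_mass", "testes_mass",
                   "intromission_duration"),
  character_scores = c("species", "H1", "H2", "S1", "S2",
                       "T1", "T2", "T3", "T4", "T5"),
  specimen_manifest = c("species", "geometry_path", "geometry_kind")
)

#' Read a study table with schema validation
#'
#' CSV, UTF-8, header row required. Empty cells and the literal `NA` are
#' read as missing. Unknown columns are preserved; missing required columns
#' raise a schema error naming them.
#'
#' @param path CSV path.
#' @param schema one of `"life_history"`, `"character_scores"`,
#'   `"specimen_manifest"`.
#' @return A tibble.
#' @export
read_table <- function(path, schema = c("life_history", "character_scores",
                                        "specimen_manifest")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_os(paste0("cannot read ", path), "io")
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                 check.names = FALSE, fileEncoding = "UTF-8")
  required <- .table_schemas[[schema]]
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_os(paste0("missing required columns: ", paste(missing, collapse = ", ")),
            "schema")
  }
  if (anyDuplicated(df$species)) {
    stop_os("duplicate species identifiers", "schema")
  }
  as_tibble(df)
}
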