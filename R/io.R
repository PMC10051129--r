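# File formats: OBJ meshes with a labels sidecar CSV and a meta JSON,
# point clouds and tables as CSV, configuration as YAML or JSON.

#' Write a leaflet mesh as OBJ
#'
#' Writes plain `v`/`f` OBJ records; the per-triangle leaflet labels go to
#' a sidecar CSV (`<path>.labels.csv`) and the annulus/free-edge orderings
#' and papillary points to a meta JSON (`<path>.meta.json`), so a mesh
#' round-trips through [read_mesh_obj()] exactly (vertices to 1e-6 mm,
#' connectivity and labels identically).
#'
#' @param mesh A [loft_leaflets()] mesh.
#' @param path Output path (conventionally `.obj`).
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  v <- sprintf("v %.9g %.9g %.9g",
               mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  f <- sprintf("f %d %d %d",
               mesh$triangles[, 1], mesh$triangles[, 2], mesh$triangles[, 3])
  writeLines(c("# tvsim leaflet mesh", v, f), path)
  utils::write.csv(data.frame(triangle = seq_len(nrow(mesh$triangles)),
                              label = as.character(mesh$label)),
                   paste0(path, ".labels.csv"), row.names = FALSE)
  meta <- list(annulus_idx = mesh$annulus_idx,
               free_edge_idx = mesh$free_edge_idx,
               papillary = mesh$papillary,
               sector = as.character(mesh$sector),
               n_points = mesh$n_points, n_radial = mesh$n_radial)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA)
  invisible(path)
}

#' Read a leaflet mesh written by [write_mesh_obj()]
#'
#' @param path OBJ path.
#' @return A `leaflet_mesh` object.
#' @export
read_mesh_obj <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  parse_num <- function(ls, what) {
    fields <- strsplit(sub(paste0("^", what, " "), "", ls), "\\s+")
    bad <- which(lengths(fields) != 3)
    if (length(bad))
      stop("malformed ", what, " record in ", path, " (element ", bad[1], ")")
    m <- matrix(as.numeric(unlist(fields)), ncol = 3, byrow = TRUE)
    if (any(!is.finite(m)))
      stop("non-numeric ", what, " record in ", path)
    m
  }
  verts <- parse_num(vl, "v")
  tris <- parse_num(fl, "f")
  storage.mode(tris) <- "integer"
  lab_path <- paste0(path, ".labels.csv")
  meta_path <- paste0(path, ".meta.json")
  label <- if (file.exists(lab_path)) {
    lab <- utils::read.csv(lab_path)
    factor(lab$label, levels = c("septal", "anterior", "posterior"))
  } else factor(rep(NA_character_, nrow(tris)),
                levels = c("septal", "anterior", "posterior"))
  mesh <- list(vertices = verts, triangles = tris, label = label,
               annulus_idx = integer(0), free_edge_idx = integer(0),
               is_annulus = logical(nrow(verts)),
               is_free_edge = logical(nrow(verts)),
               papillary = NULL, sector = NULL,
               n_points = NA_integer_, n_radial = NA_integer_)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    mesh$annulus_idx <- as.integer(meta$annulus_idx)
    mesh$free_edge_idx <- as.integer(meta$free_edge_idx)
    mesh$papillary <- matrix(unlist(meta$papillary), ncol = 3)
    mesh$sector <- factor(meta$sector,
                          levels = c("septal", "anterior", "posterior"))
    mesh$n_points <- as.integer(meta$n_points)
    mesh$n_radial <- as.integer(meta$n_radial)
    mesh$is_annulus[mesh$annulus_idx] <- TRUE
    mesh$is_free_edge[mesh$free_edge_idx] <- TRUE
  }
  structure(mesh, class = "leaflet_mesh")
}

#' Write / read a 3D point cloud as CSV
#'
#' @param points N x 3 numeric matrix (mm).
#' @param path CSV path (columns `x,y,z`).
#' @return `path` invisibly / the points matrix.
#' @export
write_points <- function(points, path) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  utils::write.csv(data.frame(x = points[, 1], y = points[, 2],
                              z = points[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("point cloud file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(c("x", "y", "z"), names(df))
  if (length(missing))
    stop("point cloud CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  m <- suppressWarnings(vapply(df[c("x", "y", "z")], as.numeric,
                               numeric(nrow(df))))
  m <- matrix(m, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  bad <- which(apply(m, 1, function(r) any(!is.finite(r))))
  if (length(bad))
    stop("non-numeric point cloud row ", bad[1], " in ", path)
  m
}

#' Write / read a cohort table as CSV
#'
#' @param table Data frame.
#' @param path CSV path.
#' @param required Column names that must be present when reading.
#' @return `path` invisibly / the data frame.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("table file not found: ", path)
  df <- utils::read.csv(path)
  check_schema(df, required, context = path)
  df
}

# error if required columns are absent, naming them
check_schema <- function(table, required, context = "cohort table") {
  if (is.null(required)) return(invisible(TRUE))
  missing <- setdiff(required, names(table))
  if (length(missing))
    stop(context, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read / write a pipeline configuration (YAML or JSON by extension)
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @param config Configuration list.
#' @return The configuration list / `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config, path)
  invisible(path)
}
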