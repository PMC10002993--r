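# Readers/writers for the plain-text interchange formats (coordinate CSV,
# Wavefront OBJ meshes, analytic-shape JSON, config YAML/JSON) plus the run
# manifest. All writers are locale-independent: period decimal separator,
# fixed column order, "\n" line endings; results never go to stderr.

COORD_COLUMNS <- c("patient_id", "side", "method", "point_role",
                   "x_mm", "y_mm", "z_mm")
POINT_ROLES <- c("ventral_contact", "cranial_point", "planned_target",
                 "mean_contact", paste0("contact_", 0:3))

#' Read / write the coordinate CSV schema
#'
#' Coordinate tables use the columns `patient_id`, `side`, `method`,
#' `point_role` (one of ventral_contact, cranial_point, planned_target,
#' mean_contact, contact_0..contact_3), `x_mm`, `y_mm`, `z_mm` in the stored
#' physical AC-PC frame. Reading validates every cell and reports the first
#' offending row.
#'
#' @param path CSV file path.
#' @return `read_coordinate_csv`: the validated data.frame, row order
#'   preserved.
#' @export
read_coordinate_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(COORD_COLUMNS, names(df))
  if (length(missing))
    stop("coordinate CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[, COORD_COLUMNS]
  bad_side <- which(!df$side %in% c("left", "right"))
  if (length(bad_side))
    stop(sprintf("row %d: unknown side \"%s\"", bad_side[1L], df$side[bad_side[1L]]),
         call. = FALSE)
  bad_role <- which(!df$point_role %in% POINT_ROLES)
  if (length(bad_role))
    stop(sprintf("row %d: unknown point_role \"%s\"", bad_role[1L],
                 df$point_role[bad_role[1L]]), call. = FALSE)
  for (col in c("x_mm", "y_mm", "z_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("row %d: non-numeric %s \"%s\"", bad[1L], col, df[[col]][bad[1L]]),
           call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' @rdname read_coordinate_csv
#' @param df a data.frame with the schema columns.
#' @export
write_coordinate_csv <- function(df, path) {
  missing <- setdiff(COORD_COLUMNS, names(df))
  if (length(missing))
    stop("cannot write coordinate CSV, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  write_csv_plain(df[, COORD_COLUMNS], path)
  invisible(path)
}

# deterministic, locale-independent CSV writer
write_csv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  fmt_cell <- function(x) {
    if (is.numeric(x)) sprintf("%.10g", x) else as.character(x)
  }
  writeLines(paste(names(df), collapse = ","), con, sep = "\n")
  if (nrow(df)) {
    cells <- vapply(df, function(col) vapply(col, fmt_cell, character(1)),
                    character(nrow(df)))
    if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = ","), con, sep = "\n")
  }
  invisible(path)
}

#' Read / write Wavefront OBJ meshes
#'
#' Minimal OBJ support: `v` and (triangular) `f` records with 1-based
#' indices; `f` entries of the form `i/j/k` keep only the vertex index.
#' Reading validates closedness and orientation and lists boundary edges on
#' failure; writing emits 10-decimal coordinates so a round trip preserves
#' vertices to well below 1e-9 mm.
#'
#' @param path OBJ file path.
#' @param label,side structure metadata for the mesh read.
#' @return `read_mesh_obj`: a `structure_mesh`.
#' @export
read_mesh_obj <- function(path, label = "STN", side = "right") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (!length(vlines) || !length(flines))
    stop("OBJ file has no v/f records: ", path, call. = FALSE)
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)), "[[:space:]]+"),
                             function(x) as.numeric(x[1:3])))
  F <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", flines)), "[[:space:]]+"),
                             function(x) {
                               idx <- as.integer(sub("/.*$", "", x))
                               if (length(idx) != 3L)
                                 stop("only triangular faces are supported",
                                      call. = FALSE)
                               idx
                             }))
  mesh <- structure_mesh(V, F, label = label, side = side, validate = FALSE)
  rep <- validate_mesh(mesh)
  if (!rep$valid) {
    be <- rep$boundary_edges
    detail <- if (nrow(be)) {
      paste0("; boundary edges: ",
             paste(utils::head(apply(be, 1L, paste, collapse = "-"), 10L),
                   collapse = ", "))
    } else ""
    stop("invalid mesh in ", path, ": ", paste(rep$problems, collapse = "; "),
         detail, call. = FALSE)
  }
  mesh
}

#' @rdname read_mesh_obj
#' @param mesh a `structure_mesh`.
#' @export
write_mesh_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "structure_mesh"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# %s %s", mesh$label, mesh$side), con, sep = "\n")
  writeLines(sprintf("v %.10f %.10f %.10f", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con, sep = "\n")
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                     mesh$faces[, 3L]), con, sep = "\n")
  invisible(path)
}

#' Analytic shapes from JSON
#'
#' Alternative to OBJ meshes: `{"type": "sphere"|"ellipsoid", "center":
#' [x,y,z], "radii": [a,b,c] (or "radius": r), "label": ..., "side": ...}`;
#' a top-level JSON array yields a list of meshes.
#'
#' @param path JSON file path.
#' @param subdiv tessellation level.
#' @return a `structure_mesh` or list of them.
#' @export
read_shape_json <- function(path, subdiv = 3L) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  build <- function(sh) {
    type <- match.arg(sh$type, c("sphere", "ellipsoid"))
    radii <- if (type == "sphere") rep(as.numeric(sh$radius %||% sh$radii[1L]), 3L)
             else as.numeric(sh$radii)
    ellipsoid_mesh(as.numeric(sh$center), radii, diag(3), subdiv,
                   label = sh$label %||% "STN", side = sh$side %||% "right")
  }
  if (!is.null(x$type)) build(x) else lapply(x, build)
}

#' Read a simulation config from YAML or JSON
#'
#' Recognized fields are the arguments of [simulation_config()]; unknown
#' fields are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(simulation_config, x)
}
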