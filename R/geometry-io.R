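#' Labeled molecular geometry
#'
#' Cartesian coordinates in angstroms with unique atom labels, the container
#' for all internal-coordinate analysis.
#'
#' @param labels Character vector of unique atom labels (e.g. "C12", "O21").
#' @param elements Character vector of element symbols, same length.
#' @param coords Numeric n x 3 matrix of coordinates, angstroms.
#' @return An object of class \code{molecule_geometry}.
#' @export
molecule_geometry <- function(labels, elements, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3) stop("coords must have 3 columns (x, y, z)")
  n <- nrow(coords)
  labels <- as.character(labels)
  elements <- as.character(elements)
  if (length(labels) != n || length(elements) != n) {
    stop("labels, elements and coords must describe the same atom count")
  }
  if (anyDuplicated(labels)) {
    stop("atom labels must be unique (duplicate: ",
         labels[duplicated(labels)][1], ")")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  dimnames(coords) <- list(labels, c("x", "y", "z"))
  structure(list(labels = labels, elements = elements, coords = coords),
            class = "molecule_geometry")
}

#' @export
print.molecule_geometry <- function(x, ...) {
  cat("<molecule_geometry> ", length(x$labels), " atoms (",
      paste(utils::head(x$labels, 6), collapse = ", "),
      if (length(x$labels) > 6) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Read an XYZ geometry file
#'
#' Standard XYZ: atom-count line, comment line, then \code{element x y z}
#' records. An optional fourth data column supplies atom labels; otherwise
#' labels are auto-numbered element+index ("C1", "C2", "O3", ...), counting
#' per element.
#'
#' @param path XYZ file path.
#' @return A \code{molecule_geometry}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(length(lines))]
  if (length(lines) < 2) stop("XYZ file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("malformed atom-count line in ", path)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop("XYZ count mismatch in ", path, ": header says ", n,
         " atoms, found ", length(body))
  }
  body <- body[seq_len(n)]
  toks <- strsplit(trimws(body), "\\s+")
  elements <- vapply(toks, `[`, character(1), 1)
  coords <- t(vapply(toks, function(tk) {
    xyz <- suppressWarnings(as.numeric(tk[2:4]))
    if (any(is.na(xyz))) stop("non-numeric coordinate in ", path)
    xyz
  }, numeric(3)))
  labels <- vapply(toks, function(tk) if (length(tk) >= 5) tk[5] else NA_character_,
                   character(1))
  if (any(is.na(labels))) {
    idx <- stats::ave(seq_along(elements), elements, FUN = seq_along)
    labels <- paste0(elements, idx)
  }
  molecule_geometry(labels, elements, coords)
}

#' Write an XYZ geometry file
#'
#' Coordinates are written with enough digits that
#' \code{read_xyz(write_xyz(g))} reproduces them to 1e-6 angstrom; atom labels
#' go in a fourth column so round trips preserve them.
#'
#' @param g A \code{molecule_geometry}.
#' @param path Output path.
#' @param comment Second-line comment (default empty).
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(g, path, comment = "") {
  stopifnot(inherits(g, "molecule_geometry"))
  rows <- sprintf("%-3s %16.8f %16.8f %16.8f  %s",
                  g$elements, g$coords[, 1], g$coords[, 2], g$coords[, 3],
                  g$labels)
  writeLines(c(as.character(length(g$labels)), comment, rows), path)
  invisible(path)
}

#' Write a kinetics report
#'
#' One row per channel plus a summary row carrying the overall rate constant.
#' CSV or JSON, decided by the file extension (or \code{format}).
#'
#' @param results A \code{rate_table} (see \code{\link{evaluate_channels}}).
#' @param path Output path ending in .csv or .json.
#' @param format "csv" or "json"; default inferred from \code{path}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(results, path, format = NULL) {
  stopifnot(is.data.frame(results))
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  k_total <- overall_rate(results)
  if (format == "json") {
    payload <- list(channels = as.data.frame(results), k_overall = k_total)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    out <- as.data.frame(results)
    summary_row <- out[1, , drop = FALSE]
    summary_row[1, ] <- NA
    summary_row$site <- "OVERALL"
    summary_row$mechanism <- ""
    summary_row$k_app <- k_total
    out <- rbind(out, summary_row)
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
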