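#' Examination record
#'
#' A wrist examination: one postero-anterior and one lateral radiograph
#' sharing a fracture label and cast flag.
#'
#' @param exam_id Identifier.
#' @param pa,lat [radiograph()] objects (postero-anterior / lateral view).
#' @param fracture Logical ground-truth fracture label.
#' @param cast Logical cast flag.
#' @return An object of class `examination`.
#' @export
examination <- function(exam_id, pa, lat, fracture, cast = FALSE) {
  stopifnot(inherits(pa, "radiograph"), inherits(lat, "radiograph"))
  if (pa$view != "postero_anterior" || lat$view != "lateral")
    stop("examination needs exactly one view of each projection")
  structure(list(exam_id = exam_id, pa = pa, lat = lat,
                 fracture = isTRUE(fracture), cast = isTRUE(cast)),
            class = "examination")
}

manifest_required_cols <- c("exam_id", "view", "path", "mask_path",
                            "fracture", "cast")

#' Load a dataset manifest
#'
#' Reads a CSV manifest (columns `exam_id, view, path, mask_path, fracture,
#' cast`; paths relative to the manifest's directory), groups rows into
#' examinations and validates the grouping. All structural problems (missing
#' or duplicate views, unreadable files) are collected and reported in a
#' single aggregated error.
#'
#' @param path Manifest CSV path.
#' @param read_pixels If `TRUE`, image (and mask) files are read; otherwise
#'   the returned radiographs carry `NULL` pixels and a `path` field, which is
#'   sufficient for label-level work.
#' @return List of `examination` objects (with `pa_mask`/`lat_mask` fields
#'   attached when masks exist and `read_pixels = TRUE`), plus the parsed
#'   manifest as attribute `"manifest"`.
#' @export
load_manifest <- function(path, read_pixels = FALSE) {
  if (!file.exists(path)) stop("manifest does not exist: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(manifest_required_cols, names(man))
  if (length(missing_cols))
    stop("manifest is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  base <- dirname(path)
  man$fracture <- as.logical(man$fracture)
  man$cast <- as.logical(man$cast)

  problems <- character()
  exams <- list()
  for (id in unique(man$exam_id)) {
    rows <- man[man$exam_id == id, , drop = FALSE]
    for (v in c("postero_anterior", "lateral")) {
      n <- sum(rows$view == v)
      if (n == 0) problems <- c(problems, sprintf("exam %s: missing %s view", id, v))
      if (n > 1) problems <- c(problems, sprintf("exam %s: duplicate %s view", id, v))
    }
    for (k in seq_len(nrow(rows))) {
      f <- file.path(base, rows$path[k])
      if (!file.exists(f))
        problems <- c(problems, sprintf("exam %s: unreadable file %s", id, rows$path[k]))
    }
    if (length(unique(rows$fracture)) > 1)
      problems <- c(problems, sprintf("exam %s: inconsistent fracture labels", id))
  }
  if (length(problems))
    stop("manifest validation failed:\n  ",
         paste(problems, collapse = "\n  "))

  for (id in unique(man$exam_id)) {
    rows <- man[man$exam_id == id, , drop = FALSE]
    get_view <- function(v) {
      r <- rows[rows$view == v, , drop = FALSE]
      f <- file.path(base, r$path[1])
      if (read_pixels) {
        read_image(f, view = v, cast = r$cast[1], exam_id = id)
      } else {
        rg <- structure(list(pixels = NULL, pixel_spacing_mm = c(NA, NA),
                             view = v, cast = r$cast[1], exam_id = id,
                             path = f),
                        class = "radiograph")
        rg
      }
    }
    ex <- list(exam_id = id,
               pa = get_view("postero_anterior"),
               lat = get_view("lateral"),
               fracture = rows$fracture[1],
               cast = any(rows$cast))
    if (read_pixels) {
      masks <- lapply(c("postero_anterior", "lateral"), function(v) {
        mp <- rows$mask_path[rows$view == v][1]
        if (is.na(mp) || !nzchar(mp)) return(NULL)
        read_mask(file.path(base, mp))
      })
      ex$pa_mask <- masks[[1]]
      ex$lat_mask <- masks[[2]]
    }
    class(ex) <- "examination"
    exams[[length(exams) + 1L]] <- ex
  }
  attr(exams, "manifest") <- man
  exams
}

#' Write a dataset manifest
#'
#' @param manifest Data frame with the manifest columns (`exam_id, view,
#'   path, mask_path, fracture, cast`).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  missing_cols <- setdiff(manifest_required_cols, names(manifest))
  if (length(missing_cols))
    stop("manifest is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
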