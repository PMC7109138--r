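#' Write a volumetric field as NIfTI-1
#'
#' @param field 3D or 4D array on the phantom grid.
#' @param phantom The `cortical_phantom` supplying the affine.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(field, phantom, path) {
  img <- RNifti::asNifti(field)
  img <- RNifti::`sform<-`(img, structure(phantom$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path Input path.
#' @return List with `data` (array) and `affine` (4 x 4 matrix).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = structure(RNifti::xform(img),
                                                code = NULL))
}

need_xml2 <- function() {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("GIFTI support needs the xml2 package", call. = FALSE)
}

gifti_data_array <- function(doc, values, intent, datatype, dims) {
  da <- xml2::xml_add_child(doc, "DataArray",
                            Intent = intent, DataType = datatype,
                            ArrayIndexingOrder = "RowMajorOrder",
                            Dimensionality = as.character(length(dims)),
                            Encoding = "ASCII", Endian = "LittleEndian")
  for (k in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", k - 1), as.character(dims[k]))
  xml2::xml_add_child(da, "Data", paste(t(values), collapse = " "))
  da
}

#' Write the phantom surface as a GIFTI file
#'
#' Minimal ASCII-encoded GIFTI (coordinates plus triangle topology),
#' readable by standard neuroimaging surface tools.
#'
#' @param phantom A `cortical_phantom` (or list with `vertices`,
#'   `triangles`).
#' @param path Output path (conventionally `.surf.gii`).
#' @return The path, invisibly.
#' @export
write_surface_gifti <- function(phantom, path) {
  need_xml2()
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "2")
  gifti_data_array(doc, phantom$vertices, "NIFTI_INTENT_POINTSET",
                   "NIFTI_TYPE_FLOAT32", dim(phantom$vertices))
  gifti_data_array(doc, phantom$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                   "NIFTI_TYPE_INT32", dim(phantom$triangles))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a per-vertex map as a GIFTI functional file
#'
#' @param map Numeric vector (one value per vertex) or matrix
#'   (vertices x maps).
#' @param path Output path (conventionally `.func.gii`).
#' @return The path, invisibly.
#' @export
write_map_gifti <- function(map, path) {
  need_xml2()
  m <- if (is.matrix(map)) map else matrix(map, ncol = 1L)
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(ncol(m)))
  for (k in seq_len(ncol(m)))
    gifti_data_array(doc, m[, k], "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32",
                     nrow(m))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GIFTI file written by this package
#'
#' @param path Input path.
#' @return For surface files, list with `vertices` and `triangles`
#'   (1-based); for functional files, a numeric matrix vertices x maps.
#' @export
read_gifti <- function(path) {
  need_xml2()
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  parse_da <- function(da) {
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(da, ".//Data")),
                 quiet = TRUE)
    dims <- as.integer(vapply(seq_len(
      as.integer(xml2::xml_attr(da, "Dimensionality"))),
      function(k) xml2::xml_attr(da, paste0("Dim", k - 1)), character(1)))
    if (length(dims) > 1) matrix(vals, nrow = dims[1], byrow = TRUE) else vals
  }
  intents <- vapply(das, xml2::xml_attr, character(1), attr = "Intent")
  if ("NIFTI_INTENT_POINTSET" %in% intents) {
    tri <- parse_da(das[[which(intents == "NIFTI_INTENT_TRIANGLE")]]) + 1L
    storage.mode(tri) <- "integer"
    list(vertices = parse_da(das[[which(intents == "NIFTI_INTENT_POINTSET")]]),
         triangles = tri)
  } else {
    do.call(cbind, lapply(das, parse_da))
  }
}

#' Write an event design as a BIDS-style events table
#'
#' Tab-separated file with `onset`, `duration` and `trial_type` columns.
#'
#' @param design An `event_design`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(design, path) {
  df <- data.frame(onset = design$onsets, duration = design$durations,
                   trial_type = as.character(design$condition))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events table
#'
#' @param path Input path.
#' @param n_volumes,tr Acquisition length the design belongs to.
#' @return An `event_design`.
#' @export
read_events_tsv <- function(path, n_volumes, tr = 2.52) {
  df <- utils::read.delim(path)
  new_event_design(df$onset, df$duration, n_volumes, tr,
                   condition = factor(df$trial_type))
}

#' Serialise an experiment report to JSON
#'
#' Inference results are reduced to their summary fields (counts, overlap
#' metrics, correlation tables, group statistics, parameters); the heavy
#' per-element maps are omitted.
#'
#' @param report An `experiment_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  slim <- report[setdiff(names(report), "results")]
  slim$overlap <- lapply(slim$overlap, unclass)
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(path)
}

#' Read back a serialised experiment report
#'
#' @param path Input path.
#' @return A list mirroring the serialised report fields.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
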