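#' Read a per-well readout table
#'
#' Reads a CSV with columns \code{plate_id}, \code{replicate_id},
#' \code{well}, \code{value} (percent GFP-positive, 0-100) into a list of
#' \linkS4class{PlateReadout} objects, one per (plate, replicate). Unknown
#' columns are preserved as a metadata attribute.
#'
#' @param path CSV file path.
#' @param layouts optional named list of \linkS4class{PlateLayout} keyed by
#'   plate id; plates without a supplied layout get the default control
#'   layout.
#' @return list of \linkS4class{PlateReadout}, named "plate:replicate".
#' @export
readReadoutTable <- function(path, layouts = list()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("plate_id", "replicate_id", "well", "value")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("readout table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  key <- paste(tab$plate_id, tab$replicate_id, tab$well, sep = "\r")
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (plate, replicate, well) in rows: ",
         paste(utils::head(rows, 10), collapse = ", "))
  }
  bad <- which(!is.finite(tab$value) | tab$value < 0 | tab$value > 100)
  if (length(bad))
    stop("value outside [0, 100] in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  extra <- tab[setdiff(names(tab), needed)]
  split_key <- paste(tab$plate_id, tab$replicate_id, sep = ":")
  out <- lapply(split(tab, split_key), function(chunk) {
    pid <- chunk$plate_id[1]
    layout <- if (pid %in% names(layouts)) layouts[[pid]]
              else defaultControlLayout(pid)
    PlateReadout(layout,
                 stats::setNames(chunk$value, chunk$well),
                 replicateId = chunk$replicate_id[1])
  })
  if (ncol(extra)) attr(out, "metadata") <- extra
  out
}

#' Write a per-well readout table
#'
#' Inverse of \code{\link{readReadoutTable}}; the round trip is
#' value-exact (values serialized with 17 significant digits).
#'
#' @param readouts list of \linkS4class{PlateReadout}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeReadoutTable <- function(readouts, path) {
  rows <- do.call(rbind, lapply(readouts, function(r) {
    v <- wellValues(r)
    data.frame(plate_id = plateId(r), replicate_id = replicateId(r),
               well = names(v),
               value = formatC(v, digits = 17, format = "g"),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct and validate a library map
#'
#' The library map links each esiRNA to its target gene and silencing
#' trigger index (1 or 2; two independent, non-overlapping esiRNAs per
#' gene).
#'
#' @param esirna_id,gene_id,trigger_index equal-length vectors, or a
#'   single data.frame passed as \code{esirna_id}.
#' @return data.frame with class "libraryMap".
#' @export
libraryMap <- function(esirna_id, gene_id = NULL, trigger_index = NULL) {
  if (is.data.frame(esirna_id)) {
    tab <- esirna_id
    needed <- c("esirna_id", "gene_id", "trigger_index")
    if (!all(needed %in% names(tab)))
      stop("library map needs columns: ", paste(needed, collapse = ", "))
    tab <- tab[needed]
  } else {
    tab <- data.frame(esirna_id = as.character(esirna_id),
                      gene_id = as.character(gene_id),
                      trigger_index = as.integer(trigger_index),
                      stringsAsFactors = FALSE)
  }
  if (!all(tab$trigger_index %in% c(1L, 2L)))
    stop("trigger_index must be 1 or 2")
  if (anyDuplicated(tab$esirna_id))
    stop("duplicate esirna_id in library map")
  if (anyDuplicated(paste(tab$gene_id, tab$trigger_index)))
    stop("a gene may have at most one esiRNA per trigger index")
  class(tab) <- c("libraryMap", "data.frame")
  tab
}

#' Read / write a library map TSV
#'
#' @param path TSV with columns esirna_id, gene_id, trigger_index.
#' @return \code{readLibraryMap}: a validated library map data.frame.
#' @export
readLibraryMap <- function(path) {
  libraryMap(utils::read.delim(path, stringsAsFactors = FALSE,
                               encoding = "UTF-8"))
}

#' @rdname readLibraryMap
#' @param map a library map data.frame.
#' @export
writeLibraryMap <- function(map, path) {
  utils::write.table(map, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
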