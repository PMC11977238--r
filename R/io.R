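#' @include AllClasses.R
NULL

## Columns of the plate-map interchange schema.
plateMapColumns <- c("plate", "well", "role", "treatment", "compound_id",
                     "dose", "phase")

#' Read and write plate-map tables
#'
#' The plate map is a CSV with columns plate, well, role, treatment,
#' compound_id, dose, phase. Reading validates the schema; writing
#' emits exactly those columns.
#'
#' @param path CSV file path.
#' @param layout plate-map data.frame.
#' @return `readPlateMap` returns the validated data.frame;
#'   `writePlateMap` returns `path` invisibly.
#' @export
readPlateMap <- function(path) {
  if (!file.exists(path)) stop("plate map not found: ", path)
  pm <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(plateMapColumns, names(pm))
  if (length(missing))
    stop("plate map lacks column(s): ", paste(missing, collapse = ", "))
  pm
}

#' @rdname readPlateMap
#' @export
writePlateMap <- function(layout, path) {
  for (col in setdiff(plateMapColumns, names(layout))) layout[[col]] <- NA
  utils::write.csv(layout[plateMapColumns], path, row.names = FALSE)
  invisible(path)
}

#' Read and write well-level quantification tables
#'
#' Plain-CSV round trip for the well tables produced by
#' [simulatePlate()] and [quantifyWell()].
#'
#' @param wells well table.
#' @param path CSV file path.
#' @return `readWellTable` returns the data.frame; `writeWellTable`
#'   returns `path` invisibly.
#' @export
writeWellTable <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWellTable
#' @export
readWellTable <- function(path) {
  if (!file.exists(path)) stop("well table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write and read a simulated field as 16-bit TIFF pairs
#'
#' Channels are written as single-channel 16-bit TIFFs with suffixes
#' `_egfp.tif` and `_tom.tif` (intensities stored as 16-bit counts in
#' arbitrary units), plus the planted label mask as `_mask.tif` and
#' the truth table as `_truth.csv`.
#'
#' @param field a [SimulatedField-class] (writing) — reading returns a
#'   list with `egfp` and `tomato` matrices (and `labelMask`/`truth`
#'   when present on disk).
#' @param prefix path prefix for the four files.
#' @return `writeFieldTIFF` returns `prefix` invisibly.
#' @export
writeFieldTIFF <- function(field, prefix) {
  writeChan <- function(m, suffix) {
    m <- pmin(pmax(round(m), 0), 65535) / 65535
    tiff::writeTIFF(m, paste0(prefix, suffix), bits.per.sample = 16L)
  }
  writeChan(egfpChannel(field), "_egfp.tif")
  writeChan(tomatoChannel(field), "_tom.tif")
  writeChan(labelMask(field), "_mask.tif")
  utils::write.csv(groundTruth(field), paste0(prefix, "_truth.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' @rdname writeFieldTIFF
#' @export
readFieldTIFF <- function(prefix) {
  readChan <- function(suffix) {
    p <- paste0(prefix, suffix)
    if (!file.exists(p)) return(NULL)
    round(tiff::readTIFF(p) * 65535)
  }
  egfp <- readChan("_egfp.tif")
  tom <- readChan("_tom.tif")
  if (is.null(egfp) || is.null(tom))
    stop("field TIFF pair not found at prefix: ", prefix)
  out <- list(egfp = egfp, tomato = tom, labelMask = readChan("_mask.tif"))
  truthPath <- paste0(prefix, "_truth.csv")
  if (file.exists(truthPath))
    out$truth <- utils::read.csv(truthPath, stringsAsFactors = FALSE)
  out
}
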