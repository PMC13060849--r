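# Readers/writers for the plain-text dialects shared across modules:
#   - intensity/TPM matrix: TSV, first column id, remaining columns samples,
#     missing cells empty
#   - contaminant list / surface catalog: one id per line, '#' comments,
#     optional second TSV column (confidence) for catalogs
#   - GMT gene sets: name <tab> description <tab> members...
#   - plate readings: long CSV (plate, well, row, col, role, drug, dose,
#     intensity)
#   - bead lot: CSV (peak, pe_per_bead[, mfi])

#' Write an intensity (or TPM) matrix as TSV
#'
#' @param x an \linkS4class{LFQExperiment} or named numeric matrix.
#' @param path output file; missing cells are written empty.
#' @param idColumn header for the id column.
#' @return invisibly, the path.
#' @export
writeIntensityMatrix <- function(x, path, idColumn = "protein") {
  v <- if (is(x, "LFQExperiment")) intensities(x) else x
  df <- data.frame(id = rownames(v), as.data.frame(v), check.names = FALSE)
  colnames(df)[1] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read an intensity matrix TSV
#'
#' @param path TSV file (first column ids, remaining columns samples; empty
#'   cells are missing).
#' @param group,condition optional per-sample labels; with \code{group} an
#'   \linkS4class{LFQExperiment} is returned, otherwise a plain matrix.
#' @return matrix or \linkS4class{LFQExperiment}.
#' @export
readIntensityMatrix <- function(path, group = NULL, condition = NULL) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  if (is.null(group)) m else LFQExperiment(m, group, condition)
}

#' Read a contaminant list (one id per line, '#' comments allowed)
#'
#' @param path text file.
#' @return character vector of ids.
#' @examples
#' readContaminantList(system.file("extdata", "contaminants_example.txt",
#'                                 package = "surfkit"))
#' @export
readContaminantList <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Read a surface catalog (one id per line or two-column TSV)
#'
#' @param path text file; an optional second tab-separated column carries a
#'   confidence label.
#' @param confidence if given, keep only entries whose confidence label is
#'   in this set.
#' @return character vector of catalog ids.
#' @examples
#' f <- system.file("extdata", "surface_catalog_example.tsv",
#'                  package = "surfkit")
#' readSurfaceCatalog(f, confidence = "high")
#' @export
readSurfaceCatalog <- function(path, confidence = NULL) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x <- x[nzchar(x)]
  parts <- strsplit(x, "\t")
  ids <- vapply(parts, `[[`, "", 1L)
  conf <- vapply(parts, function(p) if (length(p) > 1L) p[[2]] else NA_character_, "")
  if (!is.null(confidence)) ids <- ids[!is.na(conf) & conf %in% confidence]
  ids
}

#' Read gene sets in GMT format
#'
#' @param path tab-separated GMT file: set name, description, member ids.
#' @return named list of character vectors; descriptions kept in the
#'   \code{"description"} attribute.
#' @examples
#' readGMT(system.file("extdata", "genesets_example.gmt",
#'                     package = "surfkit"))
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- lengths(parts) < 3L
  if (any(bad)) .stopData("GMT lines need name, description and >= 1 member")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) .stopData("duplicate GMT set names")
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2L),
                                        names(sets))
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional per-set descriptions.
#' @return invisibly, the path.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, ds, mem)
    paste(c(nm, ds, mem), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read/write plate readings (long CSV)
#'
#' @param plate plate data.frame (see
#'   \code{\link{simulateViabilityPlate}}).
#' @param path CSV file.
#' @return \code{readPlate}: the plate data.frame; \code{writePlate}:
#'   invisibly, the path.
#' @export
writePlate <- function(plate, path) {
  write.csv(plate, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writePlate
#' @export
readPlate <- function(path) {
  df <- read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
  need <- c("plate", "well", "role", "dose", "intensity")
  if (!all(need %in% colnames(df)))
    .stopData(sprintf("plate CSV needs columns: %s",
                      paste(need, collapse = ", ")))
  df
}

#' Read a bead lot CSV (columns peak, pe_per_bead and optionally mfi)
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readBeadLot <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("peak", "pe_per_bead") %in% colnames(df)))
    .stopData("bead lot CSV needs columns peak, pe_per_bead")
  df[order(df$pe_per_bead), , drop = FALSE]
}
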