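#' Read an expression matrix into a SingleCellExperiment
#'
#' Reads either a 10x-style Matrix Market directory (\code{matrix.mtx[.gz]},
#' \code{features.tsv[.gz]}, \code{barcodes.tsv[.gz]}; genes x cells on disk)
#' or a dense delimited file (cells x genes: header row of gene names, first
#' column the cell ids). The result is a
#' \link[SingleCellExperiment]{SingleCellExperiment} with genes as rows and
#' cells as columns (the Bioconductor convention), a \code{"counts"} assay,
#' and \code{metadata(x)$layer == "raw"}.
#'
#' @param path directory (for \code{format = "mtx_dir"}) or file path.
#' @param format one of \code{"mtx_dir"}, \code{"csv"}, \code{"tsv"}. Guessed
#'   from \code{path} when missing (directory -> mtx_dir, else by extension).
#' @return a \code{SingleCellExperiment} holding raw counts.
#' @examples
#' sim <- simulateCounts(simConfig(nCells = 20, nGenes = 10, K = 2, seed = 1))
#' d <- tempfile(); writeTenx(sim$sce, d)
#' sce <- readExpressionMatrix(d)
#' dim(sce)
#' @export
readExpressionMatrix <- function(path,
                                 format = c("auto", "mtx_dir", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx_dir"
      else if (grepl("\\.tsv(\\.gz)?$", path, ignore.case = TRUE)) "tsv"
      else "csv"
  }
  if (format == "mtx_dir") {
    readTenxDir(path)
  } else {
    readDenseMatrix(path, sep = if (format == "tsv") "\t" else ",")
  }
}

findTenxFile <- function(dir, base) {
  for (f in c(base, paste0(base, ".gz"))) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stopf("required file '%s[.gz]' not found in '%s'", base, dir)
}

readTenxDir <- function(dir) {
  if (!dir.exists(dir)) stopf("matrix directory '%s' does not exist", dir)
  mtxPath <- findTenxFile(dir, "matrix.mtx")
  featPath <- findTenxFile(dir, "features.tsv")
  bcPath <- findTenxFile(dir, "barcodes.tsv")
  m <- as(Matrix::readMM(mtxPath), "CsparseMatrix")
  feats <- data.table::fread(featPath, header = FALSE, sep = "\t")
  bcs <- data.table::fread(bcPath, header = FALSE, sep = "\t")
  if (nrow(feats) != nrow(m)) {
    stopf("features file '%s' has %d entries but matrix has %d rows",
          featPath, nrow(feats), nrow(m))
  }
  if (nrow(bcs) != ncol(m)) {
    stopf("barcodes file '%s' has %d entries but matrix has %d columns",
          bcPath, nrow(bcs), ncol(m))
  }
  geneNames <- as.character(feats[[1L]])
  cellIds <- as.character(bcs[[1L]])
  buildSCE(m, geneNames, cellIds,
           geneFile = featPath, cellFile = bcPath)
}

readDenseMatrix <- function(path, sep) {
  if (!file.exists(path)) stopf("matrix file '%s' does not exist", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE)
  cellIds <- as.character(dt[[1L]])
  geneNames <- colnames(dt)[-1L]
  m <- as(t(as.matrix(dt[, -1L, with = FALSE])), "CsparseMatrix")
  buildSCE(m, geneNames, cellIds, geneFile = path, cellFile = path)
}

buildSCE <- function(m, geneNames, cellIds, geneFile = "input",
                     cellFile = "input") {
  if (anyDuplicated(geneNames)) {
    stopf("duplicate gene names in '%s'", geneFile)
  }
  if (anyDuplicated(cellIds)) {
    stopf("duplicate cell ids in '%s'", cellFile)
  }
  vals <- if (methods::is(m, "sparseMatrix")) m@x else m
  if (any(!is.finite(vals))) stopf("expression matrix contains NaN/Inf")
  if (any(vals < 0)) stopf("expression matrix contains negative values")
  dimnames(m) <- list(geneNames, cellIds)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m)
  )
  S4Vectors::metadata(sce)$layer <- "raw"
  sce
}

#' Read per-cell type labels
#'
#' Reads a tab-separated file with columns \code{cell_id} and
#' \code{cell_type} (header optional) and returns a factor aligned to the
#' cells of \code{sce}. Every cell of \code{sce} must be labelled.
#'
#' @param path path to the labels TSV.
#' @param sce optional \code{SingleCellExperiment}; when given, labels are
#'   reordered to match \code{colnames(sce)} and missing cells are an error.
#' @param labelLevels optional character vector fixing the cell-type order;
#'   defaults to order of first appearance in the file.
#' @return a named factor of cell types.
#' @export
readCellLabels <- function(path, sce = NULL, labelLevels = NULL) {
  if (!file.exists(path)) stopf("labels file '%s' does not exist", path)
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          colClasses = "character")
  if (ncol(dt) < 2L) stopf("labels file '%s' needs 2 columns", path)
  ids <- as.character(dt[[1L]])
  types <- as.character(dt[[2L]])
  if (anyDuplicated(ids)) stopf("duplicate cell ids in labels file '%s'", path)
  if (is.null(labelLevels)) labelLevels <- unique(types)
  unknown <- setdiff(types, labelLevels)
  if (length(unknown)) {
    stopf("labels file contains types outside the label order: %s",
          paste(unknown, collapse = ", "))
  }
  lab <- factor(types, levels = labelLevels)
  names(lab) <- ids
  if (!is.null(sce)) {
    missing <- setdiff(colnames(sce), ids)
    if (length(missing)) {
      stopf("no label for cell '%s' (%d unlabelled cells in total)",
            missing[1L], length(missing))
    }
    lab <- lab[colnames(sce)]
  }
  lab
}

#' Write an expression matrix to delimited text or a 10x-style directory
#'
#' \code{writeExpressionCSV} writes the cells x genes orientation used by the
#' dense reader (first column \code{cell_id}, then one column per gene).
#' \code{writeTenx} writes \code{matrix.mtx}, \code{features.tsv} and
#' \code{barcodes.tsv} (uncompressed, genes x cells) readable by
#' [readExpressionMatrix()].
#'
#' @param sce a \code{SingleCellExperiment}.
#' @param path output file (CSV) or directory (10x).
#' @param assay assay name to write, default \code{"counts"}.
#' @return the output path, invisibly.
#' @export
writeExpressionCSV <- function(sce, path, assay = "counts") {
  m <- SummarizedExperiment::assay(sce, assay)
  dt <- data.table::data.table(cell_id = colnames(sce))
  dense <- t(as.matrix(m))
  for (j in seq_len(ncol(dense))) {
    data.table::set(dt, j = rownames(sce)[j], value = dense[, j])
  }
  data.table::fwrite(dt, path, sep = ",")
  invisible(path)
}

#' @rdname writeExpressionCSV
#' @export
writeTenx <- function(sce, path, assay = "counts") {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  m <- as(SummarizedExperiment::assay(sce, assay), "CsparseMatrix")
  Matrix::writeMM(m, file.path(path, "matrix.mtx"))
  writeLines(rownames(sce), file.path(path, "features.tsv"))
  writeLines(colnames(sce), file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Write cell labels as TSV
#'
#' @param labels a named factor or character vector (names = cell ids).
#' @param path output path.
#' @return the output path, invisibly.
#' @export
writeCellLabels <- function(labels, path) {
  stopifnot(!is.null(names(labels)))
  data.table::fwrite(
    data.table::data.table(cell_id = names(labels),
                           cell_type = as.character(labels)),
    path, sep = "\t"
  )
  invisible(path)
}
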