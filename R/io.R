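#' @importFrom Matrix readMM writeMM Matrix
#' @importFrom utils write.table read.delim packageVersion
#' @importFrom jsonlite write_json read_json toJSON
#' @importFrom tools md5sum
NULL

#' Write a count matrix directory
#'
#' Matrix Market counts plus TSV sidecars: \code{matrix.mtx},
#' \code{genes.tsv} (id, length in bp) and \code{cells.tsv} (id).
#'
#' @param sce a \code{SingleCellExperiment} with a \code{"counts"} assay
#'   and gene lengths in \code{rowData}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCountsDir <- function(sce, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- Matrix(as.matrix(assay(sce, "counts")), sparse = TRUE)
    writeMM(m, file.path(dir, "matrix.mtx"))
    write.table(data.frame(id = rownames(sce),
                           length = rowData(sce)$length),
                file.path(dir, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(data.frame(id = colnames(sce)),
                file.path(dir, "cells.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(dir)
}

#' Read a count matrix directory
#'
#' @param dir directory holding \code{matrix.mtx}, \code{genes.tsv} and
#'   \code{cells.tsv}.
#' @return a \code{SingleCellExperiment} (integer counts round-trip
#'   losslessly).
#' @export
readCountsDir <- function(dir) {
    mtx <- file.path(dir, "matrix.mtx")
    gf <- file.path(dir, "genes.tsv")
    cf <- file.path(dir, "cells.tsv")
    for (f in c(mtx, gf, cf))
        if (!file.exists(f)) stop("missing file: ", f)
    m <- as.matrix(readMM(mtx))
    genes <- read.delim(gf, header = FALSE, stringsAsFactors = FALSE)
    cells <- read.delim(cf, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m))
        stop("dimension mismatch between matrix.mtx and sidecar tables")
    storage.mode(m) <- "integer"
    dimnames(m) <- list(genes[[1]], cells[[1]])
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m),
        rowData = S4Vectors::DataFrame(gene_id = genes[[1]],
                                       length = as.integer(genes[[2]]),
                                       row.names = genes[[1]]),
        colData = S4Vectors::DataFrame(cell_id = cells[[1]],
                                       row.names = cells[[1]]))
}

#' Write a TraceSet as a plain-text bundle
#'
#' One directory with a JSON manifest (per trace: cell, name, protocol,
#' units, sampling rate, stimulus parameters, signal file) and one
#' single-column CSV per trace.  Round-trips signals losslessly at full
#' double precision.
#'
#' @param ts a \linkS4class{TraceSet}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeTraceDir <- function(ts, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list()
    for (cell in names(ts)) {
        for (nm in names(ts[[cell]])) {
            tr <- ts[[cell]][[nm]]
            fn <- sprintf("%s__%s.csv", cell, nm)
            writeLines(format(traceSignal(tr), digits = 17, trim = TRUE,
                              scientific = TRUE),
                       file.path(dir, fn))
            manifest[[length(manifest) + 1L]] <- list(
                cell = cell, name = nm, protocol = traceProtocol(tr),
                units = traceUnits(tr), samplingRate = samplingRate(tr),
                stimParams = stimParams(tr), file = fn)
        }
    }
    write_json(manifest, file.path(dir, "manifest.json"),
               auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Read a TraceSet bundle
#'
#' @param dir directory written by \code{\link{writeTraceDir}}.
#' @return a \linkS4class{TraceSet}.  Entries with an unknown protocol tag
#'   are skipped with a warning; a missing units field is an error.
#' @export
readTraceDir <- function(dir) {
    mf <- file.path(dir, "manifest.json")
    if (!file.exists(mf)) stop("missing manifest.json in ", dir)
    manifest <- read_json(mf, simplifyVector = FALSE)
    known <- c("rest", "step", "triangle", "vc_step", "psc")
    cells <- list()
    for (e in manifest) {
        if (is.null(e$units)) stop("trace entry without units: ", e$file)
        if (!e$protocol %in% known) {
            warning("skipping trace with unknown protocol: ", e$protocol)
            next
        }
        sig <- as.numeric(readLines(file.path(dir, e$file)))
        sp <- lapply(e$stimParams, function(x) unlist(x, use.names = FALSE))
        tr <- Trace(sig, e$samplingRate, e$units, e$protocol, sp)
        cells[[e$cell]][[e$name]] <- tr
    }
    do.call(TraceSet, lapply(cells, function(l) do.call(CellTraces, l)))
}

#' Write / read an ephys feature table
#'
#' CSV with one row per cell; missing values are empty fields.
#'
#' @param features data.frame from \code{\link{extractFeatures}}.
#' @param file CSV path.
#' @return \code{writeFeatures}: the path, invisibly;
#'   \code{readFeatures}: the data.frame.
#' @export
writeFeatures <- function(features, file) {
    write.csv(features, file, row.names = FALSE, na = "")
    invisible(file)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(file) {
    df <- read.csv(file, stringsAsFactors = FALSE)
    rownames(df) <- df$cell
    df
}

# manifest of an output directory: file hashes + parameters + versions
.runManifest <- function(dir, seed, params) {
    files <- setdiff(dir(dir, recursive = TRUE), "manifest.json")
    hashes <- md5sum(file.path(dir, files))
    names(hashes) <- files
    list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         package = as.character(packageVersion("olivoseq")),
         r_version = as.character(getRversion()),
         seed = seed, params = params,
         files = as.list(hashes))
}
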