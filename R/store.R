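STORE_TABLES <- c("/abund/depth", "/abund/rel", "/cags/partition",
                  "/cags/abund", "/stats/cag_fits", "/stats/aggregates",
                  "/islands/records", "/meta/params")

# matrix -> long-format data.frame with id columns (exact round-trip)
.matrixToTable <- function(m, row_name, col_name, value_name) {
    df <- data.frame(rep(rownames(m), times = ncol(m)),
                     rep(colnames(m), each = nrow(m)),
                     as.vector(m), stringsAsFactors = FALSE)
    colnames(df) <- c(row_name, col_name, value_name)
    df
}

.tableToMatrix <- function(df, row_name, col_name, value_name) {
    rows <- unique(df[[row_name]]); cols <- unique(df[[col_name]])
    m <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
    m[cbind(match(df[[row_name]], rows), match(df[[col_name]], cols))] <-
        df[[value_name]]
    m
}

#' Write one table into an HDF5 results store
#'
#' @param path HDF5 file (created if absent).
#' @param name dataset name, e.g. \code{"/cags/partition"}.
#' @param table a data.frame (character/numeric/integer/logical columns).
#' @return Invisibly, the path.
#' @export
writeStoreTable <- function(path, name, table) {
    stopifnot(is.data.frame(table))
    if (!file.exists(path))
        rhdf5::h5createFile(path)
    parts <- strsplit(sub("^/", "", name), "/")[[1]]
    fid <- rhdf5::H5Fopen(path)
    on.exit(rhdf5::H5Fclose(fid), add = TRUE)
    grp <- ""
    for (p in parts[-length(parts)]) {
        grp <- paste0(grp, "/", p)
        if (!rhdf5::H5Lexists(fid, grp))
            rhdf5::h5createGroup(fid, grp)
    }
    if (rhdf5::H5Lexists(fid, name))
        rhdf5::h5delete(fid, name)
    rhdf5::h5write(table, fid, name)
    invisible(path)
}

#' Read one table from an HDF5 results store
#'
#' @param path HDF5 file.
#' @param name dataset name.
#' @return data.frame.
#' @export
readStoreTable <- function(path, name) {
    out <- rhdf5::h5read(path, name)
    out <- lapply(out, function(col) {
        dim(col) <- NULL  # h5read returns 1-d arrays for columns
        col
    })
    as.data.frame(out, stringsAsFactors = FALSE)
}

#' List the tables of a results store
#'
#' @param path HDF5 file.
#' @return Character vector of dataset names (with leading slash).
#' @export
listStore <- function(path) {
    info <- rhdf5::h5ls(path)
    ds <- info[info$otype == "H5I_DATASET", , drop = FALSE]
    paste0(ifelse(ds$group == "/", "", ds$group), "/", ds$name)
}

#' Write a full pipeline result into an HDF5 store
#'
#' Lays the tables out under \code{/abund/depth}, \code{/abund/rel},
#' \code{/cags/partition}, \code{/cags/abund}, \code{/stats/cag_fits},
#' \code{/stats/aggregates}, \code{/islands/records} (if islands were
#' computed) and \code{/meta/params} (all thresholds and seeds used).
#' Matrices are stored in long format (id columns + value) so every table
#' round-trips exactly through write-then-read.
#'
#' @param result list from [runPipeline()].
#' @param path output HDF5 file (overwritten).
#' @return Invisibly, the path.
#' @export
writeResultsStore <- function(result, path) {
    if (file.exists(path)) unlink(path)
    writeStoreTable(path, "/abund/depth",
                    .matrixToTable(depthMatrix(result$abundance),
                                   "gene_id", "specimen", "depth"))
    writeStoreTable(path, "/abund/rel",
                    .matrixToTable(relAbundance(result$abundance),
                                   "gene_id", "specimen", "rel_abund"))
    m <- membership(result$partition)
    writeStoreTable(path, "/cags/partition",
                    data.frame(gene_id = names(m), cag_id = unname(m),
                               stringsAsFactors = FALSE))
    writeStoreTable(path, "/cags/abund",
                    .matrixToTable(result$cag_abundance,
                                   "cag_id", "specimen", "abund"))
    writeStoreTable(path, "/stats/cag_fits", result$fits)
    if (!is.null(result$aggregates) && nrow(result$aggregates))
        writeStoreTable(path, "/stats/aggregates", result$aggregates)
    if (!is.null(result$islands) && nrow(result$islands))
        writeStoreTable(path, "/islands/records", result$islands)
    pl <- result$params
    writeStoreTable(path, "/meta/params",
                    data.frame(param = names(pl),
                               value = vapply(pl, function(x)
                                   paste(as.character(x), collapse = ","),
                                   character(1)),
                               stringsAsFactors = FALSE))
    if (!is.null(result$status))
        writeStoreTable(path, "/meta/status",
                        data.frame(stage = names(result$status),
                                   status = unname(unlist(result$status)),
                                   stringsAsFactors = FALSE))
    invisible(path)
}
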