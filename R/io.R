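## Tab-delimited interchange formats. All tables carry a header row; column
## order is free; extra columns are ignored with a warning; missing values
## are written as "NA" but any NA intensity fails dataset validation.

.readTsv <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      check.names = FALSE, stringsAsFactors = FALSE)
}

.requireCols <- function(df, cols, what, path, optional = character(0)) {
    missing <- setdiff(cols, colnames(df))
    if (length(missing) > 0)
        stop(sprintf("%s %s is missing required column(s): %s",
                     what, path, paste(missing, collapse = ", ")),
             call. = FALSE)
    extra <- setdiff(colnames(df), c(cols, optional))
    if (length(extra) > 0 && what == "manifest")
        warning(sprintf("%s %s: ignoring extra column(s): %s",
                        what, path, paste(extra, collapse = ", ")),
                call. = FALSE)
    invisible(df)
}

#' Read a probe manifest
#'
#' Reads a tab-delimited manifest with columns \code{probe_id},
#' \code{design_type}, \code{body_cpg_count}, \code{chromosome},
#' \code{position} and optionally \code{island}, validates it, and preserves
#' the row order.
#'
#' @param path file path.
#' @return validated manifest data.frame.
#' @export
readManifest <- function(path) {
    df <- .readTsv(path)
    .requireCols(df, .MANIFEST_COLS, "manifest", path, optional = "island")
    bad <- which(!df$design_type %in% c("I", "II"))
    if (length(bad) > 0)
        stop(sprintf("manifest %s: design_type outside {I, II} at row %d ('%s')",
                     path, bad[1], df$design_type[bad[1]]), call. = FALSE)
    if (anyDuplicated(df$probe_id))
        stop(sprintf("manifest %s: duplicate probe_id '%s'", path,
                     df$probe_id[anyDuplicated(df$probe_id)]), call. = FALSE)
    keep <- intersect(c(.MANIFEST_COLS, "island"), colnames(df))
    df <- df[, keep, drop = FALSE]
    if ("island" %in% colnames(df)) df$island <- as.logical(df$island)
    v <- .manifestViolations(df)
    if (length(v) > 0)
        stop(sprintf("manifest %s invalid:\n  - %s", path,
                     paste(v, collapse = "\n  - ")), call. = FALSE)
    df
}

#' Write a probe manifest
#' @param manifest manifest data.frame; @param path output file path.
#' @export
writeManifest <- function(manifest, path) {
    utils::write.table(as.data.frame(manifest), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

.readMatrix <- function(path, key, manifest = NULL, what = "intensity") {
    df <- .readTsv(path)
    if (!key %in% colnames(df))
        stop(sprintf("%s file %s is missing key column %s", what, path, key),
             call. = FALSE)
    ids <- df[[key]]
    m <- as.matrix(df[, setdiff(colnames(df), key), drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (!is.null(manifest)) {
        missing <- setdiff(manifest$probe_id, ids)
        if (length(missing) > 0)
            stop(sprintf("%s file %s lacks manifest probe(s): %s%s",
                         what, path,
                         paste(utils::head(missing, 3), collapse = ", "),
                         if (length(missing) > 3) ", ..." else ""),
                 call. = FALSE)
        m <- m[manifest$probe_id, , drop = FALSE]
    }
    m
}

#' Read intensity and negative-control files into a MethylArraySet
#'
#' Intensity files are tab-delimited with a \code{probe_id} key column and
#' one column per sample; control files use \code{control_id}. Probe rows may
#' appear in any order — they are realigned to the manifest. Sample columns
#' must agree across the four files.
#'
#' @param methPath,unmethPath per-channel intensity file paths.
#' @param negMethPath,negUnmethPath per-channel negative-control file paths.
#' @param manifest manifest data.frame (see [readManifest()]).
#' @return a validated \linkS4class{MethylArraySet}.
#' @export
readIntensities <- function(methPath, unmethPath, negMethPath, negUnmethPath,
                            manifest) {
    manifest <- as.data.frame(manifest)
    meth <- .readMatrix(methPath, "probe_id", manifest)
    unmeth <- .readMatrix(unmethPath, "probe_id", manifest)
    if (!setequal(colnames(meth), colnames(unmeth)))
        stop(sprintf("sample columns disagree between %s and %s: %s",
                     methPath, unmethPath,
                     paste(union(setdiff(colnames(meth), colnames(unmeth)),
                                 setdiff(colnames(unmeth), colnames(meth))),
                           collapse = ", ")), call. = FALSE)
    unmeth <- unmeth[, colnames(meth), drop = FALSE]
    negMeth <- .readMatrix(negMethPath, "control_id", what = "control")
    negUnmeth <- .readMatrix(negUnmethPath, "control_id", what = "control")
    for (nm in list(c("negMeth", negMethPath), c("negUnmeth", negUnmethPath))) {
        cm <- get(nm[1])
        if (!setequal(colnames(cm), colnames(meth)))
            stop(sprintf("sample columns of control file %s disagree with %s",
                         nm[2], methPath), call. = FALSE)
    }
    MethylArraySet(manifest, meth, unmeth,
                   negMeth[, colnames(meth), drop = FALSE],
                   negUnmeth[, colnames(meth), drop = FALSE])
}

#' Write a MethylArraySet as tab-delimited files
#'
#' Writes \code{<prefix>_manifest.tsv}, \code{<prefix>_meth.tsv},
#' \code{<prefix>_unmeth.tsv}, \code{<prefix>_neg_meth.tsv} and
#' \code{<prefix>_neg_unmeth.tsv}.
#'
#' @param object a \linkS4class{MethylArraySet}; @param prefix path prefix.
#' @return invisibly, the five paths written.
#' @export
writeDataset <- function(object, prefix) {
    man <- probeManifest(object)
    paths <- c(manifest = paste0(prefix, "_manifest.tsv"),
               meth = paste0(prefix, "_meth.tsv"),
               unmeth = paste0(prefix, "_unmeth.tsv"),
               neg_meth = paste0(prefix, "_neg_meth.tsv"),
               neg_unmeth = paste0(prefix, "_neg_unmeth.tsv"))
    writeManifest(man, paths["manifest"])
    .writeMatrix(getMeth(object), "probe_id", paths["meth"])
    .writeMatrix(getUnmeth(object), "probe_id", paths["unmeth"])
    nm <- negControls(object, "Meth"); nu <- negControls(object, "Unmeth")
    rownames(nm) <- rownames(nu) <- paste0("neg", seq_len(nrow(nm)))
    .writeMatrix(nm, "control_id", paths["neg_meth"])
    .writeMatrix(nu, "control_id", paths["neg_unmeth"])
    invisible(paths)
}

.writeMatrix <- function(m, key, path) {
    df <- data.frame(rownames(m), .fmtNum(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c(key, colnames(m))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## >= 10 significant digits so read-write round trips are stable to 1e-9
.fmtNum <- function(m) {
    out <- sprintf("%.12g", m)
    dim(out) <- dim(m)
    colnames(out) <- colnames(m)
    out
}

#' Write a result table
#'
#' Tab-delimited with header; numeric columns serialized with 12 significant
#' digits so downstream comparisons are stable to well below 1e-9.
#'
#' @param table non-empty data.frame; @param path output path.
#' @export
writeResults <- function(table, path) {
    table <- as.data.frame(table)
    if (nrow(table) == 0)
        stop("refusing to write an empty result table", call. = FALSE)
    num <- vapply(table, is.numeric, logical(1))
    table[num] <- lapply(table[num], function(x) sprintf("%.12g", x))
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a result table written by [writeResults()]
#' @param path file path.
#' @return data.frame.
#' @export
readResults <- function(path) .readTsv(path)

#' Read a truth table of reference beta values
#'
#' Columns: \code{probe_id}, \code{ref_beta_group1}, \code{ref_beta_group2}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readTruth <- function(path) {
    df <- .readTsv(path)
    .requireCols(df, c("probe_id", "ref_beta_group1", "ref_beta_group2"),
                 "truth table", path)
    df[, c("probe_id", "ref_beta_group1", "ref_beta_group2")]
}
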