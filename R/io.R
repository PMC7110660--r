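#' @importFrom GenomicRanges GRanges start strand seqnames
#' @importFrom utils read.delim write.table head
NULL

.read_tsv <- function(path, header = TRUE) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0) stop("empty file: ", path)
    read.delim(path, header = header, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE, colClasses = NA, comment.char = "")
}

#' Read an sgRNA library annotation table
#'
#' Reads a tab-separated guide table with header columns `sgrna_id`,
#' `target_id` and `protospacer`. Rows whose `target_id` equals
#' `control_label` are flagged as non-targeting controls.
#'
#' @param path path to the TSV file.
#' @param control_label reserved target label of non-targeting sgRNAs.
#' @return data.frame with columns `sgrna_id`, `target_id`, `protospacer`,
#'   `is_control`.
#' @export
readGuideTable <- function(path, control_label = "negative_control") {
    df <- .read_tsv(path)
    need <- c("sgrna_id", "target_id", "protospacer")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("guide table is missing columns: ", paste(miss, collapse = ", "))
    if (!nrow(df)) stop("guide table has no rows: ", path)
    dup <- unique(df$sgrna_id[duplicated(df$sgrna_id)])
    if (length(dup))
        stop("duplicated sgrna_id in guide table: ",
             paste(head(dup, 5), collapse = ", "))
    ps <- as.character(df$protospacer)
    ps[is.na(ps)] <- ""
    bad <- ps != "" & !grepl("^[ACGT]{18,23}$", ps)
    if (any(bad))
        stop("invalid protospacer (must be A/C/G/T of length 18-23 or empty) for: ",
             paste(head(df$sgrna_id[bad], 5), collapse = ", "))
    data.frame(sgrna_id = as.character(df$sgrna_id),
               target_id = as.character(df$target_id),
               protospacer = ps,
               is_control = as.character(df$target_id) == control_label,
               stringsAsFactors = FALSE)
}

#' Write an sgRNA library annotation table
#'
#' @param guides guide table data.frame (`sgrna_id`, `target_id`,
#'   `protospacer`).
#' @param path output TSV path.
#' @export
writeGuideTable <- function(guides, path) {
    out <- guides[, c("sgrna_id", "target_id", "protospacer")]
    .write_tsv(out, path)
    invisible(path)
}

#' Read an sgRNA count table into a ScreenExperiment
#'
#' The file must be tab-separated with first column `sgrna_id` and one
#' integer column per sequenced sample. `sample_spec` maps file columns to
#' sample keys. Rows are kept in file order and never dropped; sgRNAs
#' absent from the guide table are a hard error.
#'
#' @param path path to the counts TSV.
#' @param sample_spec data.frame with columns `column`, `timepoint`,
#'   `replicate`, `arm` describing each count column to load.
#' @param guides guide table from [readGuideTable()].
#' @param control_label reserved non-targeting label.
#' @return A [ScreenExperiment-class].
#' @export
readCounts <- function(path, sample_spec, guides,
                       control_label = "negative_control") {
    df <- .read_tsv(path)
    if (colnames(df)[1] != "sgrna_id")
        stop("first column of a counts table must be 'sgrna_id'")
    miss <- setdiff(sample_spec$column, colnames(df))
    if (length(miss))
        stop("columns named in sample_spec are missing from ", path, ": ",
             paste(miss, collapse = ", "))
    cnt <- as.matrix(df[, as.character(sample_spec$column), drop = FALSE])
    storage.mode(cnt) <- "double"
    bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt), arr.ind = TRUE)
    if (nrow(bad)) {
        i <- bad[1, 1]; j <- bad[1, 2]
        stop(sprintf(
            "invalid count (negative, non-integer or non-numeric) at row %d (sgRNA '%s'), column '%s'",
            i, df$sgrna_id[i], colnames(cnt)[j]))
    }
    rownames(cnt) <- df$sgrna_id
    ScreenExperiment(cnt, guides,
                     sample_spec[, c("timepoint", "replicate", "arm")],
                     control_label = control_label)
}

#' Write the count assay of a ScreenExperiment
#'
#' @param se a [ScreenExperiment-class].
#' @param path output TSV path.
#' @return Invisibly, a `sample_spec` data.frame suitable for
#'   [readCounts()] on the written file.
#' @export
writeCounts <- function(se, path) {
    cnt <- assay(se, "counts")
    out <- data.frame(sgrna_id = rownames(cnt), cnt, check.names = FALSE,
                      stringsAsFactors = FALSE)
    .write_tsv(out, path)
    cd <- colData(se)
    invisible(data.frame(column = colnames(cnt),
                         timepoint = cd$timepoint,
                         replicate = cd$replicate,
                         arm = cd$arm, stringsAsFactors = FALSE))
}

#' Read TSS records from a BED6(+1) file
#'
#' Each record is resolved to a single genomic base: `chromStart` for
#' `+`-strand records and `chromEnd - 1` for `-`-strand records (both
#' 0-based on disk; single-base features may use
#' `chromEnd = chromStart + 1`). Positions are returned 1-based in a
#' width-1 [GenomicRanges::GRanges]; point distances are unaffected by the
#' coordinate base. The gene biotype is taken from an optional 7th column,
#' or from a sidecar TSV (`gene_id  biotype`); records covered by neither
#' get biotype `"other"`.
#'
#' @param path path to the BED file (no header).
#' @param biotype_path optional sidecar TSV with columns `gene_id`,
#'   `biotype`.
#' @return `GRanges` with metadata columns `gene_id` and `biotype`.
#' @export
readTssBed <- function(path, biotype_path = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 6)
        stop("TSS BED must have at least 6 columns (BED6): ", path)
    colnames(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
    if (any(is.na(df$start)) || any(is.na(df$end)))
        stop("non-numeric coordinates in ", path)
    bad <- which(df$end <= df$start)
    if (length(bad))
        stop(sprintf("chromEnd <= chromStart at line %d of %s", bad[1], path))
    badstr <- which(!df$strand %in% c("+", "-"))
    if (length(badstr))
        stop(sprintf("unknown strand symbol '%s' at line %d of %s",
                     df$strand[badstr[1]], badstr[1], path))
    pos0 <- ifelse(df$strand == "+", df$start, df$end - 1)
    biotype <- if (ncol(df) >= 7) as.character(df[[7]]) else NA_character_
    if (!is.null(biotype_path)) {
        side <- .read_tsv(biotype_path)
        if (!all(c("gene_id", "biotype") %in% colnames(side)))
            stop("biotype sidecar must have columns gene_id, biotype")
        biotype <- as.character(side$biotype[match(df$name, side$gene_id)])
    }
    biotype[is.na(biotype)] <- "other"
    ok <- biotype %in% c("lncRNA", "protein_coding", "other")
    if (!all(ok))
        stop("unknown biotype value(s): ",
             paste(unique(biotype[!ok]), collapse = ", "))
    GRanges(df$chrom, IRanges(pos0 + 1, width = 1), strand = df$strand,
            gene_id = as.character(df$name), biotype = biotype)
}

#' Write TSS records to BED6+1
#'
#' Single-base features are written with `chromEnd = chromStart + 1`; the
#' 7th column carries the biotype.
#'
#' @param tss `GRanges` with `gene_id` and `biotype` metadata columns.
#' @param path output path.
#' @export
writeTssBed <- function(tss, path) {
    pos0 <- start(tss) - 1
    out <- data.frame(chrom = as.character(seqnames(tss)),
                      start = pos0, end = pos0 + 1,
                      name = tss$gene_id, score = 0,
                      strand = as.character(strand(tss)),
                      biotype = tss$biotype)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a gene expression (TPM) table
#'
#' Tab-separated, first column `gene_id`, one numeric TPM column per cell
#' line.
#'
#' @param path path to the TSV.
#' @return data.frame with `gene_id` and one column per cell line.
#' @export
readExpression <- function(path) {
    df <- .read_tsv(path)
    if (colnames(df)[1] != "gene_id")
        stop("first column of an expression table must be 'gene_id'")
    if (anyDuplicated(df$gene_id))
        stop("duplicated gene_id in expression table: ", path)
    num <- df[, -1, drop = FALSE]
    if (!all(vapply(num, is.numeric, logical(1))) ||
        anyNA(as.matrix(num)) || any(as.matrix(num) < 0))
        stop("TPM values must be non-negative numbers: ", path)
    df$gene_id <- as.character(df$gene_id)
    df
}

.write_tsv <- function(df, path, digits = 6) {
    num <- vapply(df, function(x) is.numeric(x) && !is.integer(x), logical(1))
    for (j in which(num)) {
        x <- df[[j]]
        s <- ifelse(is.na(x), NA_character_,
                    ifelse(is.finite(x), formatC(x, digits = digits,
                                                 format = "g"),
                           as.character(x)))
        df[[j]] <- s
    }
    con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
        stop("cannot write to ", path, ": ", conditionMessage(e)))
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, na = "NA")
    invisible(path)
}

#' Write a results table
#'
#' Writes any of the pipeline's result tables (guide phenotypes, gene
#' scores, FDR curves, neighbor calls, screen comparisons) as TSV with a
#' header, floating point values at 6 significant digits and missing
#' values as `"NA"`.
#'
#' @param scores a data.frame of results.
#' @param path output TSV path.
#' @export
writeResults <- function(scores, path) {
    .write_tsv(as.data.frame(scores), path)
}

#' Read back a results table written by [writeResults()]
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readResults <- function(path) {
    .read_tsv(path)
}
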