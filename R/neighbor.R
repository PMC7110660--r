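#' @importFrom GenomicRanges distanceToNearest
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Classify hits near expressed protein-coding TSSs
#'
#' CRISPRi represses transcription within roughly 1 kb of the targeted
#' TSS, so a hit whose lncRNA TSS lies within `window_bp` of an expressed
#' protein-coding TSS may act through the coding neighbor and is
#' conservatively labelled a "neighbor hit".
#'
#' For every lncRNA TSS the minimum absolute point distance to any
#' protein-coding TSS with TPM >= `tpm_min` on the same chromosome is
#' computed (strand-agnostic); the lncRNA is a neighbor iff that distance
#' is <= `window_bp` (inclusive). When a gene has several annotated TSSs
#' it is a neighbor if ANY of them triggers the rule. When no expressed
#' protein-coding TSS shares the chromosome, the nearest unexpressed one
#' is reported with `pc_expressed = FALSE`; with no protein-coding TSS on
#' the chromosome at all, the distance is `NA` (logged via `message()`).
#'
#' @param lnc_tss `GRanges` of lncRNA TSS records (`gene_id` metadata
#'   column), e.g. from [readTssBed()].
#' @param pc_tss `GRanges` of protein-coding TSS records.
#' @param expression expression table (data.frame with `gene_id` and one
#'   TPM column per cell line) from [readExpression()].
#' @param line name of the expression column defining "expressed" (the
#'   screened cell line); defaults to the table's first TPM column.
#' @param tpm_min TPM floor defining expression (default 1).
#' @param window_bp neighbor window in bp (default 1000, inclusive).
#' @return data.frame with one row per lncRNA `gene_id`: `target_id`,
#'   `nearest_pc_gene`, `distance_bp`, `pc_expressed`, `is_neighbor`.
#' @export
classifyNeighbors <- function(lnc_tss, pc_tss, expression, line = NULL,
                              tpm_min = 1, window_bp = 1000) {
    if (window_bp <= 0) stop("window_bp must be > 0")
    if (tpm_min < 0) stop("tpm_min must be >= 0")
    if (is.null(line)) line <- colnames(expression)[2]
    if (!line %in% colnames(expression))
        stop("expression table has no column '", line, "'")
    expressed <- expression$gene_id[expression[[line]] >= tpm_min]
    pc_e <- pc_tss[pc_tss$gene_id %in% expressed]
    pc_u <- pc_tss[!pc_tss$gene_id %in% expressed]

    nearest_of <- function(query, subject) {
        res <- data.frame(gene = rep(NA_character_, length(query)),
                          dist = rep(NA_real_, length(query)))
        if (!length(subject)) return(res)
        # absent shared seqlevels are handled below via NA distances
        h <- suppressWarnings(
            distanceToNearest(query, subject, ignore.strand = TRUE))
        qi <- queryHits(h); si <- subjectHits(h)
        res$gene[qi] <- subject$gene_id[si]
        # point distance between single-base TSSs, not the inter-range gap
        res$dist[qi] <- abs(start(query)[qi] - start(subject)[si])
        res
    }
    ne <- nearest_of(lnc_tss, pc_e)
    nu <- nearest_of(lnc_tss, pc_u)
    use_e <- !is.na(ne$dist)
    rec <- data.frame(
        target_id = lnc_tss$gene_id,
        nearest_pc_gene = ifelse(use_e, ne$gene, nu$gene),
        distance_bp = ifelse(use_e, ne$dist, nu$dist),
        pc_expressed = use_e,
        stringsAsFactors = FALSE)
    rec$is_neighbor <- rec$pc_expressed & !is.na(rec$distance_bp) &
        rec$distance_bp <= window_bp
    orphan <- unique(rec$target_id[is.na(rec$distance_bp)])
    if (length(orphan))
        message("no protein-coding TSS on the chromosome of: ",
                paste(utils::head(orphan, 5), collapse = ", "))
    # aggregate over multiple TSSs per gene: any TSS may trigger the rule
    agg <- lapply(split(rec, rec$target_id), function(d) {
        pick <- if (any(d$pc_expressed)) d[d$pc_expressed, , drop = FALSE]
                else d
        best <- pick[order(pick$distance_bp, na.last = TRUE)[1], , drop = FALSE]
        best$is_neighbor <- any(d$is_neighbor)
        best
    })
    out <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
    out[match(unique(lnc_tss$gene_id), out$target_id), , drop = FALSE]
}

#' Split hits into lncRNA hits and neighbor hits
#'
#' @param hits a hit-called gene score table ([callHits()] output); rows
#'   with `hit == FALSE` are ignored if a `hit` column is present.
#' @param calls neighbor call table from [classifyNeighbors()] covering
#'   every hit.
#' @return list with elements `lncrna_hits` and `neighbor_hits`, a
#'   disjoint partition of the hits.
#' @export
partitionHits <- function(hits, calls) {
    if ("hit" %in% colnames(hits)) hits <- hits[hits$hit, , drop = FALSE]
    missing_ids <- setdiff(hits$target_id, calls$target_id)
    if (length(missing_ids))
        stop("hits lacking a TSS/neighbor record: ",
             paste(utils::head(missing_ids, 10), collapse = ", "))
    nb <- calls$target_id[calls$is_neighbor]
    is_nb <- hits$target_id %in% nb
    list(lncrna_hits = hits[!is_nb, , drop = FALSE],
         neighbor_hits = hits[is_nb, , drop = FALSE])
}
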