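#' Compare radiation-arm and growth-arm screens
#'
#' Joins two gene score tables on shared targets and computes, per gene,
#' both screen scores, hit flags at a common threshold, the sensitizer
#' score (ratio of radiation score to growth score) and the sensitizer
#' call. A gene is a sensitizer iff it is a hit in both screens, its
#' radiation score exceeds its growth score in magnitude, and its
#' radiation phenotype is growth-inhibiting (negative `avg_top3`) — so
#' that protective hits can never classify as sensitizers.
#'
#' @param radiation gene score table of the irradiated screen
#'   ([scoreGenes()] or [callHits()] output).
#' @param growth gene score table of the non-irradiated growth screen.
#' @param threshold common |score| hit threshold applied to both screens
#'   (default 5, the operating point at empirical FDR 0.25%).
#' @return data.frame with columns `target_id`, `growth_score`,
#'   `radiation_score`, `growth_hit`, `radiation_hit`, `sensitizer_score`
#'   (`NA` when the growth score is 0), `is_sensitizer`, `rank` (`NA`
#'   until [rankLncgrs()]).
#' @export
compareScreens <- function(radiation, growth, threshold = 5) {
    r <- radiation[!radiation$is_pseudogene, , drop = FALSE]
    g <- growth[!growth$is_pseudogene, , drop = FALSE]
    shared <- intersect(r$target_id, g$target_id)
    if (!length(shared))
        stop("no shared targets between the two screens")
    r <- r[match(shared, r$target_id), , drop = FALSE]
    g <- g[match(shared, g$target_id), , drop = FALSE]
    growth_hit <- abs(g$score) >= threshold
    radiation_hit <- abs(r$score) >= threshold
    ss <- ifelse(g$score != 0, r$score / g$score, NA_real_)
    is_sens <- growth_hit & radiation_hit &
        abs(r$score) > abs(g$score) & r$avg_top3 < 0
    data.frame(target_id = shared,
               growth_score = g$score,
               radiation_score = r$score,
               growth_hit = growth_hit,
               radiation_hit = radiation_hit,
               sensitizer_score = ss,
               is_sensitizer = is_sens,
               rank = NA_integer_,
               stringsAsFactors = FALSE)
}

#' Rank sensitizer hits by sensitizer score across an expression panel
#'
#' Retains sensitizer hits expressed (TPM >= `tpm_min`) in ALL required
#' cell lines, sorts them by descending sensitizer score and assigns
#' ranks 1..k with `lncGRS-1 .. lncGRS-k` labels. Targets absent from the
#' expression table count as unexpressed.
#'
#' @param comparison output of [compareScreens()].
#' @param expression expression table (`gene_id` + one TPM column per
#'   line).
#' @param tpm_min TPM floor defining expression (default 1).
#' @param required_lines character vector of expression columns that must
#'   all pass the floor.
#' @return data.frame of retained sensitizers ordered by rank, with added
#'   `rank` and `lncgrs_id` columns.
#' @export
rankLncgrs <- function(comparison, expression, tpm_min = 1,
                       required_lines) {
    miss <- setdiff(required_lines, colnames(expression))
    if (length(miss))
        stop("expression table is missing required line(s): ",
             paste(miss, collapse = ", "))
    sens <- comparison[comparison$is_sensitizer, , drop = FALSE]
    idx <- match(sens$target_id, expression$gene_id)
    tpm <- as.matrix(expression[idx, required_lines, drop = FALSE])
    keep <- !is.na(idx) & apply(tpm >= tpm_min, 1, all)
    keep[is.na(keep)] <- FALSE
    out <- sens[keep, , drop = FALSE]
    out <- out[order(-out$sensitizer_score), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    out$lncgrs_id <- sprintf("lncGRS-%d", out$rank)
    rownames(out) <- NULL
    out
}
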