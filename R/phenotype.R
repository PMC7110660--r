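#' @importFrom stats median sd
NULL

#' Per-sgRNA screen phenotypes
#'
#' The phenotype of an sgRNA is its relative log2 enrichment between the
#' final and initial timepoints, centered on the non-targeting controls:
#' for sgRNA s in replicate r and arm a,
#' \deqn{raw(s) = \log_2\frac{c_{final}+pc}{N_{final}} -
#'               \log_2\frac{c_{T0}+pc}{N_{T0}}}
#' where \eqn{N} is the sample's total raw count, and
#' \eqn{phenotype(s) = raw(s) - \mathrm{median}_{controls}(raw)}.
#' The per-replicate centered phenotypes are combined by arithmetic mean.
#' After centering, the median phenotype of non-targeting sgRNAs is exactly
#' 0 in each (replicate, arm), and phenotypes are invariant to rescaling
#' any sample's sequencing depth.
#'
#' @param se a [ScreenExperiment-class] containing `T0` and `Tfinal` for
#'   every (replicate, arm).
#' @param pseudocount value added to every count before frequencies are
#'   formed (default 1; negligible at 1000x coverage, guards against
#'   log of zero).
#' @param per_doubling if `TRUE`, divide phenotypes by the arm's number of
#'   population doublings, yielding growth-rate units.
#' @param doublings named numeric vector of doublings per arm (required
#'   when `per_doubling = TRUE`).
#' @return data.frame with columns `sgrna_id`, `target_id`, `is_control`,
#'   `arm`, `rep1..repR` and `mean`, one block of rows per arm. Attributes
#'   `pseudocount` and `control_median` (the per-(replicate, arm) median
#'   raw control enrichment that was subtracted) record the centering.
#' @export
guidePhenotypes <- function(se, pseudocount = 1, per_doubling = FALSE,
                            doublings = NULL) {
    stopifnot(is(se, "ScreenExperiment"))
    if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
        pseudocount < 0)
        stop("pseudocount must be a single non-negative number")
    cnt <- assay(se, "counts")
    cd <- colData(se)
    ctrl <- isControl(se)
    if (!any(ctrl))
        stop("no non-targeting control sgRNAs in the library")
    blocks <- list()
    centers <- list()
    for (a in unique(cd$arm)) {
        reps <- sort(unique(cd$replicate[cd$arm == a]))
        mat <- matrix(NA_real_, nrow(cnt), length(reps))
        colnames(mat) <- paste0("rep", reps)
        for (j in seq_along(reps)) {
            i0 <- which(cd$arm == a & cd$replicate == reps[j] &
                        cd$timepoint == "T0")
            i1 <- which(cd$arm == a & cd$replicate == reps[j] &
                        cd$timepoint == "Tfinal")
            if (length(i0) != 1 || length(i1) != 1)
                stop(sprintf(
                    "arm '%s' replicate %d: need exactly one T0 and one Tfinal sample",
                    a, reps[j]))
            n0 <- sum(cnt[, i0]); n1 <- sum(cnt[, i1])
            if (n0 == 0 || n1 == 0)
                stop(sprintf("sample with total count 0 (arm '%s', replicate %d)",
                             a, reps[j]))
            raw <- log2((cnt[, i1] + pseudocount) / n1) -
                   log2((cnt[, i0] + pseudocount) / n0)
            med <- median(raw[ctrl])
            ph <- raw - med
            if (per_doubling) {
                d <- doublings[[a]]
                if (is.null(d) || !is.finite(d) || d <= 0)
                    stop("per_doubling = TRUE requires doublings['", a,
                         "'] > 0")
                ph <- ph / d
            }
            mat[, j] <- ph
            centers[[length(centers) + 1L]] <-
                data.frame(arm = a, replicate = reps[j], control_median = med)
        }
        blocks[[a]] <- data.frame(sgrna_id = rownames(cnt),
                                  target_id = guideTargets(se),
                                  is_control = ctrl,
                                  arm = a, mat,
                                  mean = rowMeans(mat),
                                  stringsAsFactors = FALSE,
                                  row.names = NULL)
    }
    out <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
    attr(out, "pseudocount") <- pseudocount
    attr(out, "control_median") <- do.call(rbind, centers)
    out
}

#' Z-standardize gene-level phenotypes against pseudogenes
#'
#' Divides gene-level phenotypes by the sample standard deviation
#' (denominator n - 1) of negative-control pseudogene phenotypes. No mean
#' is subtracted: the phenotypes are already centered on the non-targeting
#' controls.
#'
#' @param gene_phenotypes numeric vector of gene-level phenotypes.
#' @param pseudogene_phenotypes numeric vector (length >= 2) of pseudogene
#'   phenotypes with positive standard deviation.
#' @return numeric vector of z-standardized phenotypes.
#' @export
zStandardize <- function(gene_phenotypes, pseudogene_phenotypes) {
    if (length(pseudogene_phenotypes) < 2)
        stop("need at least 2 pseudogene phenotypes")
    s <- sd(pseudogene_phenotypes)
    if (!is.finite(s) || s <= 0)
        stop("standard deviation of pseudogene phenotypes must be > 0")
    gene_phenotypes / s
}
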