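#' @importFrom stats wilcox.test
NULL

#' Mann-Whitney U test of a gene's sgRNAs against the controls
#'
#' Two-sided Mann-Whitney U p-value comparing the phenotypes of one gene's
#' sgRNAs with the non-targeting control phenotypes. The exact null
#' distribution is used when the pooled sample size is at most 12 and no
#' ties are present; otherwise the tie-corrected normal approximation
#' (with continuity correction). The p-value is clamped to (0, 1].
#'
#' @param gene_phens numeric vector of the gene's sgRNA phenotypes
#'   (length >= 1).
#' @param control_phens numeric vector of control sgRNA phenotypes
#'   (length >= 2).
#' @return a single p-value in (0, 1].
#' @export
mannWhitneyVsControls <- function(gene_phens, control_phens) {
    if (!length(gene_phens) || length(control_phens) < 2)
        stop("need >= 1 gene phenotype and >= 2 control phenotypes")
    n <- length(gene_phens); m <- length(control_phens)
    ties <- anyDuplicated(c(gene_phens, control_phens)) > 0
    p <- if (n + m <= 12 && !ties) {
        wilcox.test(gene_phens, control_phens, exact = TRUE)$p.value
    } else {
        suppressWarnings(
            wilcox.test(gene_phens, control_phens, exact = FALSE,
                        correct = TRUE)$p.value)
    }
    min(1, max(p, .Machine$double.xmin))
}

#' Screen score of one gene
#'
#' The screen score is the signed mean of the gene's three
#' largest-magnitude sgRNA phenotypes multiplied by -log10 of its
#' Mann-Whitney U p-value. With fewer than three sgRNAs all are used (and
#' flagged via `n_top`).
#'
#' @param phens numeric vector of the gene's sgRNA phenotypes.
#' @param mw_p Mann-Whitney U p-value from [mannWhitneyVsControls()].
#' @return list with `n_guides`, `n_top`, `avg_top3` (signed mean of the
#'   top guides) and `score`.
#' @export
geneScore <- function(phens, mw_p) {
    if (!length(phens)) stop("empty phenotype vector")
    if (!is.finite(mw_p) || mw_p <= 0 || mw_p > 1)
        stop("mw_p must be in (0, 1]")
    k <- min(3L, length(phens))
    top <- phens[order(abs(phens), decreasing = TRUE)[seq_len(k)]]
    avg <- mean(top)
    list(n_guides = length(phens), n_top = k, avg_top3 = avg,
         score = avg * (-log10(mw_p)))
}

#' Score all genes of one screen arm
#'
#' Collapses a guide phenotype table (one arm) to per-gene statistics:
#' Mann-Whitney p against all non-targeting controls and the screen score
#' of [geneScore()], using the replicate-mean phenotype.
#'
#' @param phens guide phenotype data.frame from [guidePhenotypes()],
#'   optionally pre-filtered to one arm.
#' @param arm if given, subset `phens` to this arm first.
#' @return data.frame with columns `target_id`, `n_guides`, `avg_top3`,
#'   `mw_p`, `score`, `is_pseudogene` (always `FALSE` here).
#' @export
scoreGenes <- function(phens, arm = NULL) {
    if (!is.null(arm)) phens <- phens[phens$arm == arm, , drop = FALSE]
    if (length(unique(phens$arm)) > 1)
        stop("phenotypes from several arms; pass arm= to select one")
    ctrl <- phens$mean[phens$is_control]
    if (length(ctrl) < 2) stop("need >= 2 control sgRNA phenotypes")
    tg <- split(phens$mean[!phens$is_control],
                phens$target_id[!phens$is_control])
    rows <- lapply(names(tg), function(id) {
        x <- tg[[id]]
        p <- mannWhitneyVsControls(x, ctrl)
        gs <- geneScore(x, p)
        data.frame(target_id = id, n_guides = gs$n_guides,
                   avg_top3 = gs$avg_top3, mw_p = p,
                   score = gs$score, is_pseudogene = FALSE,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Partition non-targeting sgRNAs into pseudogenes
#'
#' Per round, the control sgRNAs are shuffled (seeded) and partitioned
#' into `floor(N / group_size)` disjoint groups; groups from all rounds
#' are concatenated. Pseudogenes calibrate the empirical FDR: they are
#' "genes" whose sgRNAs are known to be inert.
#'
#' @param control_ids character vector of non-targeting sgRNA ids (or a
#'   named vector whose names are used).
#' @param group_size sgRNAs per pseudogene (>= 2; default 10, matching a
#'   10-guides-per-TSS library design).
#' @param n_rounds number of independent shuffling rounds (default 5).
#' @param seed integer seed; the global RNG state is left untouched.
#' @return named list of character vectors of member sgRNA ids; names are
#'   pseudogene ids of the form `pseudo_r<round>_g<k>`.
#' @export
makePseudogenes <- function(control_ids, group_size = 10, n_rounds = 5,
                            seed) {
    if (!is.null(names(control_ids))) control_ids <- names(control_ids)
    control_ids <- as.character(control_ids)
    if (group_size < 2) stop("group_size must be >= 2")
    if (n_rounds < 1) stop("n_rounds must be >= 1")
    if (length(control_ids) < 2 * group_size)
        stop(sprintf("too few control sgRNAs (%d) for group_size %d",
                     length(control_ids), group_size))
    if (missing(seed)) stop("seed is required for pseudogene construction")
    n_groups <- length(control_ids) %/% group_size
    withr::with_seed(as.integer(seed), {
        out <- list()
        for (r in seq_len(n_rounds)) {
            perm <- sample(control_ids)
            for (g in seq_len(n_groups)) {
                out[[sprintf("pseudo_r%02d_g%04d", r, g)]] <-
                    perm[((g - 1) * group_size + 1):(g * group_size)]
            }
        }
        out
    })
}

#' Score pseudogenes
#'
#' Builds pseudogenes with [makePseudogenes()] from the non-targeting
#' sgRNAs of a phenotype table and scores each exactly like a real gene,
#' except that its own member sgRNAs are excluded from the control pool of
#' its Mann-Whitney test (avoiding self-comparison bias).
#'
#' @inheritParams scoreGenes
#' @inheritParams makePseudogenes
#' @return data.frame in the shape of [scoreGenes()] output, with
#'   `is_pseudogene = TRUE`.
#' @export
scorePseudogenes <- function(phens, group_size = 10, n_rounds = 5, seed,
                             arm = NULL) {
    if (!is.null(arm)) phens <- phens[phens$arm == arm, , drop = FALSE]
    if (length(unique(phens$arm)) > 1)
        stop("phenotypes from several arms; pass arm= to select one")
    ctrl <- phens$mean[phens$is_control]
    names(ctrl) <- phens$sgrna_id[phens$is_control]
    groups <- makePseudogenes(ctrl, group_size = group_size,
                              n_rounds = n_rounds, seed = seed)
    rows <- lapply(names(groups), function(id) {
        members <- groups[[id]]
        x <- unname(ctrl[members])
        pool <- unname(ctrl[setdiff(names(ctrl), members)])
        p <- mannWhitneyVsControls(x, pool)
        gs <- geneScore(x, p)
        data.frame(target_id = id, n_guides = gs$n_guides,
                   avg_top3 = gs$avg_top3, mw_p = p, score = gs$score,
                   is_pseudogene = TRUE, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Empirical-FDR score threshold from pseudogenes
#'
#' For every candidate threshold T (the sorted distinct |score| values of
#' the real genes), the empirical FDR is the pseudogene pass rate scaled
#' to the number of real genes, over the observed number of passing genes:
#' \deqn{FDR(T) = \frac{\#\{pseudo: |s| \ge T\} / n_{pseudo} \times n_{genes}}
#'                    {\max(1, \#\{genes: |s| \ge T\})}}
#' The chosen threshold is the smallest T with FDR(T) <= `target_fdr`; if
#' none qualifies it is `+Inf` (zero hits).
#'
#' @param gene_scores data.frame from [scoreGenes()].
#' @param pseudo_scores data.frame from [scorePseudogenes()].
#' @param target_fdr target empirical FDR in (0, 1); default 0.0025, the
#'   operating point corresponding to a screen score threshold of 5 in the
#'   radiation modifier screen this package models.
#' @return list with `curve` (data.frame `threshold`, `n_genes_pass`,
#'   `n_pseudo_pass`, `fdr`), `chosen_threshold` and `target_fdr`.
#' @export
empiricalFdrThreshold <- function(gene_scores, pseudo_scores,
                                  target_fdr = 0.0025) {
    if (!nrow(gene_scores) || !nrow(pseudo_scores))
        stop("gene and pseudogene score tables must be non-empty")
    if (target_fdr <= 0 || target_fdr >= 1)
        stop("target_fdr must be in (0, 1)")
    g <- abs(gene_scores$score)
    p <- abs(pseudo_scores$score)
    grid <- sort(unique(g))
    n_gene_pass <- vapply(grid, function(t) sum(g >= t), numeric(1))
    n_pseudo_pass <- vapply(grid, function(t) sum(p >= t), numeric(1))
    fdr <- (n_pseudo_pass / length(p) * length(g)) / pmax(1, n_gene_pass)
    ok <- which(fdr <= target_fdr)
    chosen <- if (length(ok)) grid[min(ok)] else Inf
    list(curve = data.frame(threshold = grid,
                            n_genes_pass = n_gene_pass,
                            n_pseudo_pass = n_pseudo_pass,
                            fdr = fdr),
         chosen_threshold = chosen,
         target_fdr = target_fdr)
}

#' Call screen hits at a score threshold
#'
#' A gene is a hit iff its |score| is at least the threshold. The hit
#' direction follows the sign of `avg_top3`: negative phenotypes are
#' growth-inhibiting/sensitizing, positive ones protective.
#'
#' @param gene_scores data.frame from [scoreGenes()].
#' @param threshold score threshold (finite, or `+Inf` for zero hits);
#'   typically `chosen_threshold` from [empiricalFdrThreshold()].
#' @return the input with added columns `hit` and `direction`
#'   (`"sensitizing"`, `"protective"` or `"none"`).
#' @export
callHits <- function(gene_scores, threshold) {
    if (is.na(threshold)) stop("threshold must be a number or +Inf")
    hit <- abs(gene_scores$score) >= threshold
    dir <- ifelse(!hit, "none",
                  ifelse(gene_scores$avg_top3 < 0, "sensitizing",
                         "protective"))
    gene_scores$hit <- hit
    gene_scores$direction <- dir
    gene_scores
}
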