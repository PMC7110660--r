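#' @importFrom utils packageVersion
NULL

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
             call. = FALSE))
}

.need_file <- function(path, what) {
    if (is.null(path) || !file.exists(path))
        stop(sprintf("%s file not found: %s", what,
                     if (is.null(path)) "<unset>" else path))
    path
}

#' Write a simulated screen to disk in the pipeline's input formats
#'
#' @param sim output of [simulateScreen()].
#' @param dir output directory (created if needed).
#' @param annotation optional output of [simulateAnnotation()]; when
#'   given, TSS BED and expression TSV are written too.
#' @return list of written paths plus the `sample_spec` data.frame for
#'   [readCounts()].
#' @export
writeSimulatedScreen <- function(sim, dir, annotation = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- list(guides = file.path(dir, "guides.tsv"),
              counts = file.path(dir, "counts.tsv"),
              truth = file.path(dir, "truth.tsv"))
    writeGuideTable(sim$guides, p$guides)
    spec <- writeCounts(sim$experiment, p$counts)
    writeResults(sim$truth, p$truth)
    if (!is.null(annotation)) {
        p$tss <- file.path(dir, "tss.bed")
        p$expression <- file.path(dir, "expression.tsv")
        writeTssBed(c(annotation$lnc_tss, annotation$pc_tss), p$tss)
        writeResults(annotation$expression, p$expression)
    }
    p$sample_spec <- spec
    p
}

.as_sample_spec <- function(x) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(s)
        data.frame(column = s$column, timepoint = s$timepoint,
                   replicate = as.integer(s$replicate), arm = s$arm,
                   stringsAsFactors = FALSE)))
}

#' Run the full screen analysis pipeline
#'
#' Executes phenotype computation, per-arm gene and pseudogene scoring,
#' empirical-FDR threshold selection, hit calling, neighbor filtering,
#' sensitizer comparison and lncGRS ranking, writing all result tables
#' and a run manifest to the output directory. Re-running with an
#' identical config reproduces byte-identical outputs.
#'
#' @param config either a path to a YAML file or a config list with
#'   elements: `paths` (`guides`, `counts`, `tss`, `expression`,
#'   `output_dir`), `sample_spec` (list of column/timepoint/replicate/arm
#'   records or a data.frame), and optionally `control_label`,
#'   `pseudocount`, `pseudogenes` (`group_size`, `n_rounds`, `seed`),
#'   `target_fdr`, `threshold` (override; skips FDR selection),
#'   `neighbor` (`window_bp`, `tpm_min`, `line`), `lncgrs` (`tpm_min`,
#'   `lines`).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
runFullAnalysis <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    paths <- config$paths
    out_dir <- paths$output_dir
    if (is.null(out_dir)) stop("config paths$output_dir is required")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    control_label <- config$control_label %||% "negative_control"
    pseudocount <- config$pseudocount %||% 1
    pg <- config$pseudogenes %||% list()
    pg_size <- pg$group_size %||% 10
    pg_rounds <- pg$n_rounds %||% 5
    pg_seed <- pg$seed %||% stop("config pseudogenes$seed is required")
    target_fdr <- config$target_fdr %||% 0.0025
    nb <- config$neighbor %||% list()
    lg <- config$lncgrs %||% list()

    se <- .stage("screen_io", {
        guides <- readGuideTable(.need_file(paths$guides, "guide table"),
                                 control_label)
        readCounts(.need_file(paths$counts, "counts"),
                   .as_sample_spec(config$sample_spec), guides,
                   control_label)
    })
    phens <- .stage("phenotype", guidePhenotypes(se, pseudocount))
    arms <- unique(phens$arm)
    if (!all(c("no_radiation", "radiation") %in% arms))
        stop("stage 'phenotype': both arms (no_radiation, radiation) are required")

    scores <- list(); fdr <- list(); thr <- list()
    for (a in c("no_radiation", "radiation")) {
        scores[[a]] <- .stage("gene_scoring", {
            gs <- scoreGenes(phens, arm = a)
            ps <- scorePseudogenes(phens, group_size = pg_size,
                                   n_rounds = pg_rounds, seed = pg_seed,
                                   arm = a)
            list(genes = gs, pseudo = ps)
        })
        fdr[[a]] <- .stage("empirical_fdr",
            empiricalFdrThreshold(scores[[a]]$genes, scores[[a]]$pseudo,
                                  target_fdr))
        thr[[a]] <- config$threshold %||% fdr[[a]]$chosen_threshold
        scores[[a]]$genes <- .stage("call_hits",
            callHits(scores[[a]]$genes, thr[[a]]))
    }
    common_thr <- max(unlist(thr))

    neighbor <- .stage("neighbor_filter", {
        tss <- readTssBed(.need_file(paths$tss, "TSS BED"))
        expr <- readExpression(.need_file(paths$expression, "expression"))
        lnc <- tss[tss$biotype == "lncRNA"]
        pc <- tss[tss$biotype == "protein_coding"]
        calls <- classifyNeighbors(lnc, pc, expr,
                                   line = nb$line %||% NULL,
                                   tpm_min = nb$tpm_min %||% 1,
                                   window_bp = nb$window_bp %||% 1000)
        parts <- partitionHits(scores$radiation$genes, calls)
        list(calls = calls, parts = parts, expression = expr)
    })

    comparison <- .stage("sensitizer", {
        cmp <- compareScreens(scores$radiation$genes,
                              scores$no_radiation$genes,
                              threshold = common_thr)
        lines <- lg$lines %||%
            colnames(neighbor$expression)[-1]
        ranked <- rankLncgrs(cmp, neighbor$expression,
                             tpm_min = lg$tpm_min %||% 1,
                             required_lines = lines)
        cmp$rank[match(ranked$target_id, cmp$target_id)] <- ranked$rank
        list(comparison = cmp, lncgrs = ranked)
    })

    files <- c(phenotypes = "phenotypes.tsv",
               gene_scores_growth = "gene_scores_growth.tsv",
               gene_scores_radiation = "gene_scores_radiation.tsv",
               fdr_curve_growth = "fdr_curve_growth.tsv",
               fdr_curve_radiation = "fdr_curve_radiation.tsv",
               neighbor_calls = "neighbor_calls.tsv",
               screen_comparison = "screen_comparison.tsv",
               lncgrs = "lncgrs_ranking.tsv")
    .stage("write_results", {
        writeResults(phens, file.path(out_dir, files["phenotypes"]))
        writeResults(rbind(scores$no_radiation$genes,
                           callHits(scores$no_radiation$pseudo,
                                    thr$no_radiation)),
                     file.path(out_dir, files["gene_scores_growth"]))
        writeResults(rbind(scores$radiation$genes,
                           callHits(scores$radiation$pseudo,
                                    thr$radiation)),
                     file.path(out_dir, files["gene_scores_radiation"]))
        writeResults(fdr$no_radiation$curve,
                     file.path(out_dir, files["fdr_curve_growth"]))
        writeResults(fdr$radiation$curve,
                     file.path(out_dir, files["fdr_curve_radiation"]))
        writeResults(neighbor$calls,
                     file.path(out_dir, files["neighbor_calls"]))
        writeResults(comparison$comparison,
                     file.path(out_dir, files["screen_comparison"]))
        writeResults(comparison$lncgrs,
                     file.path(out_dir, files["lncgrs"]))
    })

    cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE)
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    manifest <- list(
        package = "radmod",
        version = as.character(packageVersion("radmod")),
        config_md5 = unname(tools::md5sum(tmp)),
        control_label = control_label,
        pseudogene_seed = pg_seed,
        target_fdr = target_fdr,
        thresholds = list(no_radiation = thr$no_radiation,
                          radiation = thr$radiation,
                          comparison = common_thr),
        rows = list(
            guides = nrow(se),
            samples = ncol(se),
            phenotypes = nrow(phens),
            genes = nrow(scores$radiation$genes),
            pseudogenes = nrow(scores$radiation$pseudo),
            radiation_hits = sum(scores$radiation$genes$hit),
            growth_hits = sum(scores$no_radiation$genes$hit),
            lncrna_hits = nrow(neighbor$parts$lncrna_hits),
            neighbor_hits = nrow(neighbor$parts$neighbor_hits),
            sensitizers = sum(comparison$comparison$is_sensitizer),
            lncgrs = nrow(comparison$lncgrs)),
        files = as.list(files))
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(experiment = se, phenotypes = phens, scores = scores,
                   fdr = fdr, neighbor = neighbor,
                   comparison = comparison$comparison,
                   lncgrs = comparison$lncgrs, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
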