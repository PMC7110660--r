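#' @importFrom stats rlnorm rnbinom rpois rbeta runif rnorm
NULL

#' Configuration of the synthetic screen generator
#'
#' The defaults emulate the library geometry and culture conditions of a
#' genome-scale CRISPRi lncRNA radiation modifier screen: 1000 targeted
#' TSSs x 10 sgRNAs plus 1202 non-targeting controls, sequenced at 1000x
#' library coverage, grown for ~7.1 population doublings under
#' fractionated radiation and twice that without (fractionated 8 Gy
#' roughly doubles the doubling time). Per-doubling log2 fitness effects
#' `gamma` (growth) and radiation-interaction effects `delta` are planted
#' in configurable fractions of genes; per-guide potency is Beta
#' distributed; counts are negative-binomial at configurable depth and
#' dispersion.
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene sgRNAs per gene (default 10).
#' @param n_controls non-targeting control sgRNAs (default 1202).
#' @param frac_growth_hits fraction of genes with a pure growth effect
#'   (`gamma` < 0, `delta` = 0).
#' @param frac_interaction_hits fraction of genes planted as radiation
#'   sensitizers (`gamma` < 0 and `delta` < 0).
#' @param frac_protective fraction of genes whose knockdown protects
#'   against radiation (`gamma` = 0, `delta` > 0).
#' @param gamma_range interval (both endpoints <= 0) of per-doubling log2
#'   growth effects.
#' @param delta_range interval (both endpoints <= 0) of per-doubling log2
#'   radiation-interaction effects for sensitizers; protective genes draw
#'   from the mirrored positive interval.
#' @param active_guides_mean mean per-guide activity (Beta distributed in
#'   \[0, 1\]).
#' @param activity_concentration Beta concentration (a + b) of the guide
#'   activity distribution.
#' @param doublings_no_rad,doublings_rad population doublings between T0
#'   and Tfinal in each arm.
#' @param depth sequencing reads per sample; default 1000x the library
#'   size. A warning is issued below 10x.
#' @param abundance_sigma lognormal sigma of the initial library skew.
#' @param dispersion negative-binomial overdispersion of the count draw
#'   (variance `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param n_replicates infection replicates (default 2).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return validated config list of class `"SimConfig"`.
#' @export
simConfig <- function(n_genes = 1000, guides_per_gene = 10,
                      n_controls = 1202,
                      frac_growth_hits = 0.10,
                      frac_interaction_hits = 0.05,
                      frac_protective = 0.02,
                      gamma_range = c(-0.20, -0.05),
                      delta_range = c(-0.50, -0.25),
                      active_guides_mean = 0.75,
                      activity_concentration = 4,
                      doublings_no_rad = 14.2,
                      doublings_rad = 7.1,
                      depth = NULL,
                      abundance_sigma = 0.5,
                      dispersion = 0.01,
                      n_replicates = 2,
                      seed = 1) {
    lib_size <- n_genes * guides_per_gene + n_controls
    if (is.null(depth)) depth <- 1000 * lib_size
    cfg <- list(n_genes = n_genes, guides_per_gene = guides_per_gene,
                n_controls = n_controls,
                frac_growth_hits = frac_growth_hits,
                frac_interaction_hits = frac_interaction_hits,
                frac_protective = frac_protective,
                gamma_range = sort(gamma_range),
                delta_range = sort(delta_range),
                active_guides_mean = active_guides_mean,
                activity_concentration = activity_concentration,
                doublings_no_rad = doublings_no_rad,
                doublings_rad = doublings_rad,
                depth = depth, abundance_sigma = abundance_sigma,
                dispersion = dispersion, n_replicates = n_replicates,
                seed = as.integer(seed))
    bad <- character()
    if (n_genes < 1 || guides_per_gene < 1) bad <- c(bad, "n_genes/guides_per_gene")
    if (n_controls < 2) bad <- c(bad, "n_controls")
    fr <- c(frac_growth_hits, frac_interaction_hits, frac_protective)
    if (any(fr < 0 | fr > 1) || sum(fr) > 1)
        bad <- c(bad, "hit fractions")
    if (active_guides_mean <= 0 || active_guides_mean > 1)
        bad <- c(bad, "active_guides_mean")
    if (activity_concentration <= 0) bad <- c(bad, "activity_concentration")
    if (doublings_no_rad <= 0 || doublings_rad <= 0) bad <- c(bad, "doublings")
    if (depth <= 0) bad <- c(bad, "depth")
    if (abundance_sigma < 0) bad <- c(bad, "abundance_sigma")
    if (dispersion < 0) bad <- c(bad, "dispersion")
    if (n_replicates < 1) bad <- c(bad, "n_replicates")
    if (length(bad))
        stop("invalid SimConfig field(s): ", paste(bad, collapse = ", "))
    if (depth < 10 * lib_size)
        warning("sequencing depth below 10x library size; counts will be very noisy")
    class(cfg) <- "SimConfig"
    cfg
}

.rcounts <- function(mu, dispersion) {
    if (dispersion > 0) rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else rpois(length(mu), mu)
}

#' Simulate a paired (+/- radiation) CRISPRi screen with known truth
#'
#' Initial guide frequencies are lognormal; each guide's frequency grows
#' as \eqn{f_0 \times 2^{D \cdot a \cdot (\gamma + \delta \cdot
#' 1[arm=radiation])}} over the arm's D doublings (a = guide activity),
#' is renormalized, and read counts are drawn negative-binomially at the
#' configured depth, independently per replicate. Both arms share the
#' same T0 counts per replicate (cultures are split after selection) and
#' the same ground truth.
#'
#' @param config a [simConfig()].
#' @return list with `experiment` (a [ScreenExperiment-class] with 2 arms
#'   x 2 timepoints x replicates), `guides` (guide table data.frame),
#'   `truth` (per-gene `target_id`, `label` in
#'   \{null, growth_hit, sensitizer, protective\}, `gamma`, `delta`) and
#'   `guide_activity` (per-guide activity in \[0, 1\]).
#' @export
simulateScreen <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    withr::with_seed(config$seed, .simulate_screen(config))
}

.simulate_screen <- function(cfg) {
    genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
    n <- cfg$n_genes
    n_s <- round(cfg$frac_interaction_hits * n)
    n_p <- round(cfg$frac_protective * n)
    n_g <- round(cfg$frac_growth_hits * n)
    label <- rep("null", n)
    pick <- sample(n, n_s + n_p + n_g)
    label[pick[seq_len(n_s)]] <- "sensitizer"
    if (n_p) label[pick[n_s + seq_len(n_p)]] <- "protective"
    if (n_g) label[pick[n_s + n_p + seq_len(n_g)]] <- "growth_hit"
    gamma <- numeric(n); delta <- numeric(n)
    has_growth <- label %in% c("growth_hit", "sensitizer")
    gamma[has_growth] <- runif(sum(has_growth), cfg$gamma_range[1],
                               cfg$gamma_range[2])
    delta[label == "sensitizer"] <- runif(n_s, cfg$delta_range[1],
                                          cfg$delta_range[2])
    delta[label == "protective"] <- runif(n_p, -cfg$delta_range[2],
                                          -cfg$delta_range[1])
    truth <- data.frame(target_id = genes, label = label,
                        gamma = gamma, delta = delta,
                        stringsAsFactors = FALSE)

    gpg <- cfg$guides_per_gene
    t_ids <- sprintf("%s_sg%02d", rep(genes, each = gpg),
                     rep(seq_len(gpg), n))
    c_ids <- sprintf("ctrl_sg%04d", seq_len(cfg$n_controls))
    ids <- c(t_ids, c_ids)
    targets <- c(rep(genes, each = gpg), rep("negative_control",
                                             cfg$n_controls))
    ab <- cfg$activity_concentration *
        c(cfg$active_guides_mean, 1 - cfg$active_guides_mean)
    act <- c(rbeta(length(t_ids), ab[1], ab[2]), numeric(cfg$n_controls))
    g_gamma <- c(rep(gamma, each = gpg), numeric(cfg$n_controls))
    g_delta <- c(rep(delta, each = gpg), numeric(cfg$n_controls))

    f0 <- rlnorm(length(ids), 0, cfg$abundance_sigma)
    f0 <- f0 / sum(f0)
    dbl <- c(no_radiation = cfg$doublings_no_rad,
             radiation = cfg$doublings_rad)
    cols <- list(); cd <- list()
    for (r in seq_len(cfg$n_replicates)) {
        t0 <- .rcounts(f0 * cfg$depth, cfg$dispersion)
        for (arm in names(dbl)) {
            cols[[sprintf("%s_T0_r%d", arm, r)]] <- t0
            cd[[length(cd) + 1L]] <- data.frame(timepoint = "T0",
                                                replicate = r, arm = arm)
            ff <- f0 * 2^(dbl[[arm]] * act *
                          (g_gamma + g_delta * (arm == "radiation")))
            ff <- ff / sum(ff)
            cols[[sprintf("%s_Tfinal_r%d", arm, r)]] <-
                .rcounts(ff * cfg$depth, cfg$dispersion)
            cd[[length(cd) + 1L]] <- data.frame(timepoint = "Tfinal",
                                                replicate = r, arm = arm)
        }
    }
    cnt <- do.call(cbind, cols)
    rownames(cnt) <- ids
    guides <- data.frame(sgrna_id = ids, target_id = targets,
                         protospacer = "", is_control = targets ==
                             "negative_control",
                         stringsAsFactors = FALSE)
    se <- ScreenExperiment(cnt, guides, do.call(rbind, cd))
    list(experiment = se, guides = guides, truth = truth,
         guide_activity = data.frame(sgrna_id = ids, target_id = targets,
                                     activity = act,
                                     stringsAsFactors = FALSE))
}

#' Simulate TSS annotation and an expression panel for a simulated screen
#'
#' Places one lncRNA TSS per simulated target on synthetic chromosomes
#' and plants, for a chosen fraction, an expressed protein-coding TSS
#' within the neighbor window (the remaining protein-coding TSSs are
#' placed well outside it; some near-TSSs are planted unexpressed to
#' exercise the expression filter). Also draws a TPM table across a panel
#' of cell lines for all genes.
#'
#' @param target_ids character vector of simulated target ids.
#' @param frac_neighbor fraction of targets with a planted expressed
#'   protein-coding neighbor.
#' @param frac_decoy fraction of targets with a planted UNexpressed
#'   near protein-coding TSS (never neighbors).
#' @param window_bp neighbor window used for planting.
#' @param lines cell line names of the expression panel; the first is the
#'   screened line used for the neighbor rule.
#' @param frac_line_expressed probability that a lncRNA target is
#'   expressed in any one panel line (independent across lines; with the
#'   default 0.77 over 5 lines roughly a quarter of sensitizers survive
#'   the all-lines filter, as in real glioma panels).
#' @param tpm_expressed TPM range of expressed genes.
#' @param seed integer seed.
#' @return list with `lnc_tss` and `pc_tss` (`GRanges`), `expression`
#'   (data.frame `gene_id` + one TPM column per line; protein-coding and
#'   lncRNA genes together) and `truth` (data.frame `target_id`,
#'   `is_neighbor`).
#' @export
simulateAnnotation <- function(target_ids, frac_neighbor = 0.15,
                               frac_decoy = 0.10, window_bp = 1000,
                               lines = c("U87", "SF10360", "SF10281",
                                         "SF8628", "SF10218"),
                               frac_line_expressed = 0.77,
                               tpm_expressed = c(2, 100), seed = 1) {
    withr::with_seed(as.integer(seed), {
        n <- length(target_ids)
        chrom <- paste0("chr", 1 + (seq_len(n) - 1) %% 5)
        pos <- 50000 * (1 + (seq_len(n) - 1) %/% 5)
        strand <- sample(c("+", "-"), n, replace = TRUE)
        lnc <- GRanges(chrom, IRanges(pos, width = 1), strand = strand,
                       gene_id = target_ids, biotype = "lncRNA")
        is_nb <- runif(n) < frac_neighbor
        is_decoy <- !is_nb & runif(n) < frac_decoy
        pc_chrom <- character(); pc_pos <- integer(); pc_id <- character()
        pc_expressed <- logical()
        k <- 0
        for (i in seq_len(n)) {
            if (is_nb[i] || is_decoy[i]) {
                k <- k + 1
                pc_chrom <- c(pc_chrom, chrom[i])
                pc_pos <- c(pc_pos, pos[i] +
                                sample(c(-1, 1), 1) * sample.int(window_bp, 1))
                pc_id <- c(pc_id, sprintf("pc%04d", k))
                pc_expressed <- c(pc_expressed, is_nb[i])
            }
            # a distant expressed pc gene on the same chromosome
            k <- k + 1
            pc_chrom <- c(pc_chrom, chrom[i])
            pc_pos <- c(pc_pos, pos[i] + 20000 + sample.int(5000, 1))
            pc_id <- c(pc_id, sprintf("pc%04d", k))
            pc_expressed <- c(pc_expressed, TRUE)
        }
        pc <- GRanges(pc_chrom, IRanges(pc_pos, width = 1), strand = "+",
                      gene_id = pc_id, biotype = "protein_coding")
        all_ids <- c(target_ids, pc_id)
        expr <- data.frame(gene_id = all_ids, stringsAsFactors = FALSE)
        for (ln in lines) {
            on <- c(runif(n) < frac_line_expressed, pc_expressed)
            expr[[ln]] <- ifelse(on,
                                 runif(length(all_ids), tpm_expressed[1],
                                       tpm_expressed[2]),
                                 runif(length(all_ids), 0, 0.5))
        }
        # planted decoys/neighbors key off the screened (first) line only
        expr[[lines[1]]][match(pc_id, expr$gene_id)] <-
            ifelse(pc_expressed,
                   runif(length(pc_id), tpm_expressed[1], tpm_expressed[2]),
                   runif(length(pc_id), 0, 0.5))
        list(lnc_tss = lnc, pc_tss = pc, expression = expr,
             truth = data.frame(target_id = target_ids,
                                is_neighbor = is_nb,
                                stringsAsFactors = FALSE))
    })
}

#' Simulate a control/A/B/AB growth assay
#'
#' Replicate proliferation values under no treatment, each single
#' treatment, and the combination, with combined survival
#' \eqn{(1-f_a)(1-f_b) \times 2^{-interaction}} and lognormal
#' (log2-Gaussian) measurement noise.
#'
#' @param f_a,f_b single-treatment fractional decreases in \[0, 1\].
#' @param interaction excess combined effect in log2 units (0 = exactly
#'   additive; > 0 = synergy).
#' @param noise_sd standard deviation of the log2-scale noise.
#' @param n_reps replicates per condition (>= 2).
#' @param seed integer seed.
#' @param baseline mean control proliferation value.
#' @return data.frame `condition` (control/A/B/AB), `replicate`, `value`,
#'   ready for [analyzeSynergy()].
#' @export
simulateGrowthAssay <- function(f_a, f_b, interaction = 0,
                                noise_sd = 0.05, n_reps = 2, seed = 1,
                                baseline = 1000) {
    stopifnot(f_a >= 0, f_a <= 1, f_b >= 0, f_b <= 1, n_reps >= 2)
    withr::with_seed(as.integer(seed), {
        noise <- function() 2^rnorm(n_reps, 0, noise_sd)
        surv <- c(control = 1, A = 1 - f_a, B = 1 - f_b,
                  AB = (1 - f_a) * (1 - f_b) * 2^(-interaction))
        do.call(rbind, lapply(names(surv), function(cond) {
            data.frame(condition = cond, replicate = seq_len(n_reps),
                       value = baseline * surv[[cond]] * noise(),
                       stringsAsFactors = FALSE)
        }))
    })
}
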