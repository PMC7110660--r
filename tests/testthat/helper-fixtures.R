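# A minimal hand-built screen: one arm, one replicate, counts chosen so
# that depth is constant, the control raw enrichment is exactly zero and
# geneA's guide quadruples (phenotype 2 at pseudocount 0).
tiny_screen <- function(arm = "radiation") {
    guides <- data.frame(
        sgrna_id = c("sgA", "sgB", "c1", "c2", "c3"),
        target_id = c("geneA", "geneB", rep("negative_control", 3)),
        protospacer = "",
        is_control = c(FALSE, FALSE, TRUE, TRUE, TRUE))
    cnt <- cbind(t0 = c(100, 700, 100, 100, 100),
                 t1 = c(400, 400, 100, 100, 100))
    rownames(cnt) <- guides$sgrna_id
    samples <- data.frame(timepoint = c("T0", "Tfinal"), replicate = 1L,
                          arm = arm)
    ScreenExperiment(cnt, guides, samples)
}

# guide table for n genes x g guides + c controls
sim_guides <- function(n_genes = 3, gpg = 2, n_ctrl = 2) {
    genes <- sprintf("gene%02d", seq_len(n_genes))
    data.frame(
        sgrna_id = c(sprintf("%s_sg%d", rep(genes, each = gpg),
                             rep(seq_len(gpg), n_genes)),
                     sprintf("ctrl%02d", seq_len(n_ctrl))),
        target_id = c(rep(genes, each = gpg),
                      rep("negative_control", n_ctrl)),
        protospacer = "",
        is_control = rep(c(FALSE, TRUE), c(n_genes * gpg, n_ctrl)))
}

# small simulator configuration used by property tests (scaled-down
# library so that seeded batches stay fast)
small_cfg <- function(seed, ...) {
    simConfig(n_genes = 200, n_controls = 300, seed = seed, ...)
}

# score one arm of a simulated screen and call hits at the empirical-FDR
# threshold
score_arm <- function(phens, arm, target_fdr = 0.05, pg_seed = 1,
                      n_rounds = 3) {
    gs <- scoreGenes(phens, arm = arm)
    ps <- scorePseudogenes(phens, arm = arm, seed = pg_seed,
                           n_rounds = n_rounds)
    f <- empiricalFdrThreshold(gs, ps, target_fdr)
    list(genes = callHits(gs, f$chosen_threshold), pseudo = ps, fdr = f)
}
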