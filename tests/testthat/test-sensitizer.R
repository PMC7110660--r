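mk_scores <- function(ids, score, avg = sign(score) * abs(score) / 2) {
    data.frame(target_id = ids, n_guides = 10, avg_top3 = avg,
               mw_p = 0.01, score = score, is_pseudogene = FALSE)
}

test_that("screen comparison computes sensitizer scores and calls", {
    rad <- mk_scores(c("a", "b", "c", "d"), c(-10, -4, -8, 12))
    gro <- mk_scores(c("a", "b", "c", "d"), c(-5, -6, 0, 6))
    cmp <- compareScreens(rad, gro, threshold = 5)
    a <- cmp[cmp$target_id == "a", ]
    expect_equal(a$sensitizer_score, 2)
    expect_true(a$is_sensitizer)

    # radiation weaker than growth -> not a sensitizer
    expect_false(cmp$is_sensitizer[cmp$target_id == "b"])
    # growth score 0: ratio NA and no sensitizer call
    cc <- cmp[cmp$target_id == "c", ]
    expect_true(is.na(cc$sensitizer_score))
    expect_false(cc$is_sensitizer)
    # protective in the radiation arm (positive phenotype) never qualifies
    expect_false(cmp$is_sensitizer[cmp$target_id == "d"])

    # every shared target is classified exactly once
    expect_equal(sum(cmp$is_sensitizer) + sum(!cmp$is_sensitizer),
                 nrow(cmp))
    expect_error(compareScreens(rad, mk_scores("zzz", 1)), "shared")
})

test_that("sensitizer score is invariant to common phenotype rescaling", {
    rad <- mk_scores(c("a", "b"), c(-10, -7))
    gro <- mk_scores(c("a", "b"), c(-5, -2))
    c1 <- compareScreens(rad, gro, threshold = 5)
    rad2 <- transform(rad, score = score * 3, avg_top3 = avg_top3 * 3)
    gro2 <- transform(gro, score = score * 3, avg_top3 = avg_top3 * 3)
    c2 <- compareScreens(rad2, gro2, threshold = 15)
    expect_equal(c2$sensitizer_score, c1$sensitizer_score)
    expect_equal(c2$is_sensitizer, c1$is_sensitizer)
})

test_that("lncGRS ranking requires expression in all panel lines", {
    cmp <- data.frame(target_id = c("a", "b", "c"),
                      growth_score = -5, radiation_score = c(-15, -7.5, -20),
                      growth_hit = TRUE, radiation_hit = TRUE,
                      sensitizer_score = c(3, 1.5, 4),
                      is_sensitizer = TRUE, rank = NA_integer_)
    lines <- c("U87", "SF10360", "SF8628")
    expr <- data.frame(gene_id = c("a", "b", "c"),
                       U87 = c(5, 9, 4), SF10360 = c(2, 3, 8),
                       SF8628 = c(7, 4, 0.2))  # c fails one line
    rk <- rankLncgrs(cmp, expr, tpm_min = 1, required_lines = lines)
    expect_equal(rk$target_id, c("a", "b"))  # by descending ratio
    expect_equal(rk$rank, c(1, 2))
    expect_equal(rk$lncgrs_id, c("lncGRS-1", "lncGRS-2"))
    expect_error(rankLncgrs(cmp, expr, required_lines = c("U87", "HeLa")),
                 "HeLa")
    # a target absent from the expression table counts as unexpressed
    expr2 <- expr[-1, ]
    expect_equal(rankLncgrs(cmp, expr2, required_lines = lines)$target_id,
                 "b")
})

test_that("planted sensitizers are recovered with controlled error", {
    tp <- 0; fp <- 0; called <- 0; planted <- 0; prot_called <- 0
    for (s in 1:20) {
        sim <- simulateScreen(small_cfg(seed = 300 + s))
        ph <- guidePhenotypes(sim$experiment)
        gro <- score_arm(ph, "no_radiation", pg_seed = s)
        rad <- score_arm(ph, "radiation", pg_seed = s)
        thr <- max(gro$fdr$chosen_threshold, rad$fdr$chosen_threshold)
        cmp <- compareScreens(rad$genes, gro$genes, threshold = thr)
        m <- merge(cmp, sim$truth)
        tp <- tp + sum(m$is_sensitizer & m$label == "sensitizer")
        fp <- fp + sum(m$is_sensitizer & m$label != "sensitizer")
        called <- called + sum(m$is_sensitizer)
        planted <- planted + sum(m$label == "sensitizer")
        prot_called <- prot_called +
            sum(m$is_sensitizer & m$label == "protective")
    }
    expect_equal(prot_called, 0)
    expect_gte(tp / planted, 0.7)          # sensitivity
    expect_lte(fp / max(1, called), 0.10)  # realized FDR <= 2x nominal
})

test_that("the top-ranked lncGRS usually carries the largest planted effect ratio", {
    ok <- 0; n_runs <- 50
    for (s in 1:n_runs) {
        cfg <- small_cfg(seed = 500 + s)
        sim <- simulateScreen(cfg)
        ann <- simulateAnnotation(sim$truth$target_id, frac_neighbor = 0,
                                  seed = 500 + s)
        ph <- guidePhenotypes(sim$experiment)
        gro <- score_arm(ph, "no_radiation", pg_seed = s)
        rad <- score_arm(ph, "radiation", pg_seed = s)
        thr <- max(gro$fdr$chosen_threshold, rad$fdr$chosen_threshold)
        cmp <- compareScreens(rad$genes, gro$genes, threshold = thr)
        rk <- rankLncgrs(cmp, ann$expression,
                         required_lines = colnames(ann$expression)[-1])
        if (!nrow(rk)) next
        tr <- sim$truth[match(rk$target_id, sim$truth$target_id), ]
        # planted radiation:growth phenotype ratio of the ranked set
        ratio <- (cfg$doublings_rad * (tr$gamma + tr$delta)) /
                 (cfg$doublings_no_rad * tr$gamma)
        ok <- ok + (which.max(ratio) == 1)
    }
    expect_gte(ok / n_runs, 0.9)
})
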