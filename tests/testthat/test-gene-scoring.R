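test_that("Mann-Whitney p-values match the worked rank arithmetic", {
    # all three gene guides below all five controls: 2/56 two-sided
    p <- mannWhitneyVsControls(c(-2, -1.5, -1),
                               c(-0.1, -0.05, 0, 0.05, 0.1))
    expect_equal(p, 2 / 56)
    # identical interleaved values -> no shift, p at 1
    p1 <- mannWhitneyVsControls(c(1, 2, 3, 4), c(1, 2, 3, 4))
    expect_gte(p1, 0.99)
    expect_error(mannWhitneyVsControls(numeric(), 1:5), "need")
    expect_error(mannWhitneyVsControls(1, 2), "need")
})

test_that("the approximate branch tracks the exact test at screen-like pool sizes", {
    # a handful of guides against a large non-targeting pool, the regime
    # in which the normal approximation is actually used
    set.seed(202)
    worst <- 0
    for (i in 1:1000) {
        n <- sample(3:6, 1)
        m <- sample(100, 1) + 100
        x <- rnorm(n); y <- rnorm(m)
        p_approx <- mannWhitneyVsControls(x, y)
        p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
        worst <- max(worst, abs(p_approx - p_exact))
    }
    expect_lte(worst, 0.02)
})

test_that("gene score is the signed top-3 mean times -log10 p", {
    gs <- geneScore(c(-2, -1.5, -1, 0.1, 0), 2 / 56)
    expect_equal(gs$avg_top3, -1.5)
    expect_equal(gs$score, -1.5 * -log10(2 / 56))
    expect_equal(round(gs$score, 3), -2.171)
    expect_equal(gs$n_top, 3)

    expect_equal(geneScore(rep(0, 5), 0.01)$score, 0)
    expect_equal(geneScore(c(-2, 3, 1), 1)$score, 0)  # p = 1 kills any phenotype
    # fewer than 3 guides: all used and flagged
    two <- geneScore(c(-2, -1), 0.5)
    expect_equal(two$n_top, 2)
    expect_equal(two$avg_top3, -1.5)
    # top 3 ranked by magnitude, sign preserved
    expect_equal(geneScore(c(4, -5, 0.1, -6), 0.1)$avg_top3,
                 mean(c(-6, -5, 4)))
    expect_error(geneScore(numeric(), 0.5), "empty")

    # bilinearity: doubling phenotypes doubles avg_top3 and score
    ph <- c(-1.2, 0.4, -0.8, 2)
    expect_equal(geneScore(ph * 2, 0.01)$score, 2 * geneScore(ph, 0.01)$score)
})

test_that("pseudogene construction is a seeded disjoint partition", {
    ids <- sprintf("c%04d", 1:1202)
    g1 <- makePseudogenes(ids, group_size = 10, n_rounds = 1, seed = 9)
    expect_length(g1, 120)
    expect_true(all(lengths(g1) == 10))
    expect_equal(anyDuplicated(unlist(g1)), 0)  # disjoint within a round

    g3 <- makePseudogenes(sprintf("c%02d", 1:20), 10, 3, seed = 9)
    expect_length(g3, 6)

    expect_identical(makePseudogenes(ids, 10, 2, seed = 4),
                     makePseudogenes(ids, 10, 2, seed = 4))
    expect_false(identical(makePseudogenes(ids, 10, 2, seed = 4),
                           makePseudogenes(ids, 10, 2, seed = 5)))
    expect_error(makePseudogenes(ids[1:15], 10, 1, seed = 1), "too few")
    expect_error(makePseudogenes(ids, 1, 1, seed = 1), "group_size")
})

test_that("pseudogenes exclude their own members from the control pool", {
    # 20 controls in two groups of 10: each pseudogene is tested against
    # exactly the other group, so the two p-values must be identical
    phens <- data.frame(sgrna_id = sprintf("c%02d", 1:20),
                        target_id = "negative_control",
                        is_control = TRUE, arm = "radiation",
                        rep1 = 1:20 / 10, mean = 1:20 / 10)
    ps <- scorePseudogenes(phens, group_size = 10, n_rounds = 1, seed = 2)
    expect_equal(nrow(ps), 2)
    expect_equal(ps$mw_p[1], ps$mw_p[2])
})

test_that("empirical FDR estimator follows the pseudogene-scaled formula", {
    genes <- data.frame(target_id = sprintf("g%04d", 1:1000),
                        score = c(rep(10, 100), rep(1, 900)),
                        avg_top3 = -1, is_pseudogene = FALSE)
    pseudo <- data.frame(target_id = sprintf("p%03d", 1:120),
                         score = c(10, rep(0.5, 119)),
                         avg_top3 = 0, is_pseudogene = TRUE)
    f <- empiricalFdrThreshold(genes, pseudo, target_fdr = 0.1)
    row <- f$curve[f$curve$threshold == 10, ]
    expect_equal(row$n_genes_pass, 100)
    expect_equal(row$n_pseudo_pass, 1)
    expect_equal(row$fdr, (1 / 120 * 1000) / 100)
    expect_equal(f$chosen_threshold, 1)  # FDR at T=1 is 1/120*1000/1000 = 0.0833

    # no pseudogene passing anywhere: threshold = smallest gene |score|
    pseudo0 <- transform(pseudo, score = 0.1)
    f0 <- empiricalFdrThreshold(genes, pseudo0, target_fdr = 0.01)
    expect_true(all(f0$curve$fdr[f0$curve$threshold >= 1] == 0))
    expect_equal(f0$chosen_threshold, min(abs(genes$score)))

    # nothing qualifies -> +Inf and zero hits
    fInf <- empiricalFdrThreshold(genes, transform(pseudo, score = 20),
                                  target_fdr = 0.01)
    expect_equal(fInf$chosen_threshold, Inf)
    expect_equal(sum(callHits(genes, fInf$chosen_threshold)$hit), 0)

    expect_error(empiricalFdrThreshold(genes[0, ], pseudo, 0.1),
                 "non-empty")
    expect_error(empiricalFdrThreshold(genes, pseudo, 1.5), "target_fdr")
})

test_that("hit calling respects the inclusive boundary, signs and monotonicity", {
    gs <- data.frame(target_id = c("a", "b", "c"),
                     avg_top3 = c(-2, 1, 0.5),
                     score = c(-6.2, 4.99, 5))
    h <- callHits(gs, 5)
    expect_equal(h$hit, c(TRUE, FALSE, TRUE))
    expect_equal(h$direction, c("sensitizing", "none", "protective"))

    set.seed(11)
    rnd <- data.frame(target_id = sprintf("g%d", 1:50),
                      avg_top3 = rnorm(50), score = rnorm(50, sd = 3))
    lo <- callHits(rnd, 2)$hit
    hi <- callHits(rnd, 4)$hit
    expect_true(all(lo[hi]))  # raising the threshold never adds hits
})

test_that("pseudogene and real null-gene scores are exchangeable on null screens", {
    cfg <- small_cfg(seed = 23, frac_growth_hits = 0,
                     frac_interaction_hits = 0, frac_protective = 0)
    sim <- simulateScreen(cfg)
    ph <- guidePhenotypes(sim$experiment)
    gs <- scoreGenes(ph, arm = "radiation")
    ps <- scorePseudogenes(ph, arm = "radiation", seed = 6, n_rounds = 3)
    ks <- suppressWarnings(stats::ks.test(gs$score, ps$score))
    expect_gt(ks$p.value, 0.01)
})
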