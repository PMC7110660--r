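test_that("phenotypes are depth-normalized, control-centered log2 enrichments", {
    se <- tiny_screen()
    ph <- guidePhenotypes(se, pseudocount = 0)
    # geneA guide went 100 -> 400 at constant depth with inert controls
    expect_equal(ph$mean[ph$sgrna_id == "sgA"], 2)
    # control median is exactly zero after centering
    expect_equal(median(ph$mean[ph$is_control]), 0)
    expect_equal(attr(ph, "control_median")$control_median, 0)

    # identical counts at both timepoints -> all phenotypes zero
    guides <- sim_guides(2, 2, 3)
    cnt <- matrix(rep(c(10, 20, 30, 40, 5, 5, 5), 2), ncol = 2,
                  dimnames = list(guides$sgrna_id, c("a", "b")))
    samples <- data.frame(timepoint = c("T0", "Tfinal"), replicate = 1L,
                          arm = "no_radiation")
    se0 <- ScreenExperiment(cnt, guides, samples)
    expect_equal(guidePhenotypes(se0)$mean, rep(0, nrow(cnt)))
})

test_that("phenotypes are invariant to per-sample depth scaling and antisymmetric", {
    se <- tiny_screen()
    ph <- guidePhenotypes(se)
    cnt <- SummarizedExperiment::assay(se)
    cnt10 <- cnt
    cnt10[, 2] <- cnt10[, 2] * 10
    se10 <- ScreenExperiment(cnt10,
                             data.frame(sgrna_id = rownames(cnt),
                                        target_id = guideTargets(se),
                                        protospacer = "",
                                        is_control = isControl(se)),
                             data.frame(timepoint = c("T0", "Tfinal"),
                                        replicate = 1L, arm = "radiation"))
    # pseudocount perturbs exact invariance; at pc = 0 it is exact
    expect_equal(guidePhenotypes(se10, pseudocount = 0)$mean,
                 guidePhenotypes(se, pseudocount = 0)$mean)

    # relabeling T0 as Tfinal (and vice versa) negates every phenotype
    swapped <- ScreenExperiment(cnt,
                                data.frame(sgrna_id = rownames(cnt),
                                           target_id = guideTargets(se),
                                           protospacer = "",
                                           is_control = isControl(se)),
                                data.frame(timepoint = c("Tfinal", "T0"),
                                           replicate = 1L,
                                           arm = "radiation"))
    expect_equal(guidePhenotypes(swapped, pseudocount = 0)$mean,
                 -guidePhenotypes(se, pseudocount = 0)$mean)
})

test_that("degenerate inputs are hard errors", {
    se <- tiny_screen()
    cnt <- SummarizedExperiment::assay(se)
    cnt[, 1] <- 0
    gdf <- data.frame(sgrna_id = rownames(cnt),
                      target_id = guideTargets(se), protospacer = "",
                      is_control = isControl(se))
    sdf <- data.frame(timepoint = c("T0", "Tfinal"), replicate = 1L,
                      arm = "radiation")
    expect_error(guidePhenotypes(ScreenExperiment(cnt, gdf, sdf)),
                 "total count 0")
    # missing Tfinal
    se1 <- ScreenExperiment(SummarizedExperiment::assay(se)[, 1,
                                                            drop = FALSE],
                            gdf, sdf[1, ])
    expect_error(guidePhenotypes(se1), "exactly one T0 and one Tfinal")
    expect_error(guidePhenotypes(se, pseudocount = -1), "non-negative")
})

test_that("z-standardization divides by the pseudogene SD only", {
    expect_equal(zStandardize(c(-2, 2), c(-0.5, 0, 0.5, 1)),
                 c(-2, 2) / sd(c(-0.5, 0, 0.5, 1)))
    expect_equal(zStandardize(c(-2, 2), c(0, 1) * 0.5 / sd(c(0, 1))),
                 c(-4, 4))
    expect_error(zStandardize(1, c(1, 1)), "must be > 0")
    expect_error(zStandardize(1, 1), "at least 2")
})

test_that("on a pure-null screen targeting and control phenotypes are exchangeable", {
    cfg <- simConfig(n_genes = 400, n_controls = 1202,
                     frac_growth_hits = 0, frac_interaction_hits = 0,
                     frac_protective = 0, seed = 41)
    sim <- simulateScreen(cfg)
    ph <- guidePhenotypes(sim$experiment)
    ph <- ph[ph$arm == "radiation", ]
    ks <- suppressWarnings(
        stats::ks.test(ph$mean[!ph$is_control], ph$mean[ph$is_control]))
    expect_gt(ks$p.value, 0.01)

    # and pseudogene z-scores have unit-ish SD
    ps <- scorePseudogenes(ph, seed = 5, n_rounds = 1)
    z <- zStandardize(ps$avg_top3, ps$avg_top3)
    expect_equal(sd(z), 1)
})
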