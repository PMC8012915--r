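test_that("site test matches Welch oracles and stats::t.test", {
    expect_equal(siteTest(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)), 1)
    p <- siteTest(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))
    expect_equal(p, welchOracle(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4)),
                 tolerance = 1e-10)
    expect_equal(p, t.test(c(0.2, 0.3, 0.4), c(0.1, 0.2, 0.3))$p.value,
                 tolerance = 1e-10)
    set.seed(31)
    for (i in 1:20) {
        x <- runif(sample(3:12, 1)); y <- runif(sample(3:12, 1))
        expect_equal(siteTest(x, y), t.test(y, x)$p.value,
                     tolerance = 1e-10)
    }
    # extreme separation
    x <- rnorm(30, 0.1, 0.01); y <- rnorm(30, 0.6, 0.01)
    expect_lt(siteTest(x, y), 1e-6)
    expect_error(siteTest(0.5, c(0.1, 0.2)), "2 values")
    expect_message(p1 <- siteTest(c(0.2, 0.2), c(0.2, 0.2)), "degenerate")
    expect_equal(p1, 1)
})

test_that("BH adjustment reproduces the hand step-up rule", {
    expect_equal(adjustFdr(0.04), 0.04)
    expect_equal(adjustFdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(adjustFdr(c(0.005, 0.5)), c(0.01, 0.5))
    expect_error(adjustFdr(c(0.1, 1.2)), "\\[0, 1\\]")
    # all permutations of 4 p-values: order preserved, oracle agreement
    p4 <- c(0.002, 0.011, 0.04, 0.9)
    perms <- rbind(
        c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3),
        c(1,4,3,2), c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1),
        c(2,4,1,3), c(2,4,3,1), c(3,1,2,4), c(3,1,4,2), c(3,2,1,4),
        c(3,2,4,1), c(3,4,1,2), c(3,4,2,1), c(4,1,2,3), c(4,1,3,2),
        c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
    base <- adjustFdr(p4)
    for (i in seq_len(nrow(perms))) {
        perm <- perms[i, ]
        got <- adjustFdr(p4[perm])
        expect_equal(got, bhOracle(p4[perm]))
        expect_equal(got, base[perm])  # permutation-equivariant
        expect_true(all(got >= p4[perm]))
    }
})

test_that("auroc matches the exhaustive pair-counting oracle", {
    expect_equal(auroc(c(0.1, 0.2), c(0.3, 0.4)), 1)
    expect_equal(auroc(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)), 0.5)
    expect_equal(auroc(c(0.1, 0.2, 0.3), c(0.25, 0.35)), 5 / 6)
    set.seed(77)
    for (i in 1:200) {
        n <- sample(1:20, 1); m <- sample(1:20, 1)
        # discretized scores so ties occur often
        x <- sample(seq(0, 1, 0.1), n, replace = TRUE)
        y <- sample(seq(0, 1, 0.1), m, replace = TRUE)
        expect_identical(auroc(x, y), aurocOracle(x, y))
        expect_equal(auroc(x, y), 1 - auroc(y, x))
    }
    expect_error(auroc(numeric(), c(0.5)), "at least one")
})

test_that("auroc agrees with pROC on untied data", {
    skip_if_not_installed("pROC")
    set.seed(5)
    x <- runif(25); y <- runif(17)
    ref <- as.numeric(pROC::auc(pROC::roc(
        response = rep(c(0, 1), c(25, 17)), predictor = c(x, y),
        direction = "<", quiet = TRUE)))
    expect_equal(auroc(x, y), ref, tolerance = 1e-12)
})

test_that("per-cohort stats flag a planted run and control the null", {
    mf <- generateManifest(300, "chr1", 150, seed = 8)
    pl <- plantedDMR("chr1", start(mf)[100], start(mf)[111], 12, 0.3)
    bcs <- generateBetaCohorts(mf, nCohorts = 1, nNormal = 40, nTumor = 40,
                               planted = pl, seed = 12)
    st <- cohortSiteStats(bcs)
    ids <- S4Vectors::metadata(bcs)$planted_probes
    planted <- st[st$probe_id %in% ids, ]
    expect_true(all(planted$q < 0.01))
    expect_true(all(planted$auc > 0.9))
    expect_true(all(planted$delta_beta > 0.15))
    expect_true(all(st$q >= st$p))
    null <- st[!st$probe_id %in% ids, ]
    expect_lte(mean(null$q < 0.01), 0.02)
})

test_that("pan-cancer DMS gating applies inclusive boundaries", {
    mf <- GRanges(rep("chr1", 3), IRanges(c(100, 200, 300), width = 1))
    names(mf) <- c("cgA", "cgB", "cgC")
    mkstats <- function(q, auc, delta = 0.2) {
        do.call(rbind, lapply(1:3, function(co)
            S4Vectors::DataFrame(probe_id = c("cgA", "cgB", "cgC"),
                chrom = "chr1", pos = c(100L, 200L, 300L),
                cohort = paste0("c", co), p = q[, co] / 2, q = q[, co],
                auc = auc[, co], delta_beta = delta)))
    }
    q <- matrix(0.001, 3, 3)
    # cgA clear pass; cgB mean auc exactly 0.75 (inclusive); cgC auc 0.6
    auc <- rbind(c(0.8, 0.8, 0.8), c(0.7, 0.8, 0.75), c(0.6, 0.6, 0.6))
    dms <- panCancerDms(mkstats(q, auc), mf)
    expect_identical(names(dms), c("cgA", "cgB"))
    expect_identical(unique(mcols(dms)$direction), "hyper")
    # q gate: one cohort at the boundary q = 0.01 fails the strict cut
    q2 <- q; q2[1, 2] <- 0.01
    expect_identical(names(panCancerDms(mkstats(q2, auc), mf)), "cgB")
    # fraction rule: 2/3 cohorts significant passes at 2/3
    dms23 <- panCancerDms(mkstats(q2, auc), mf,
                          minSignificantFraction = 2 / 3)
    expect_true("cgA" %in% names(dms23))
    # symmetric mode admits a strong hypomethylation discriminator
    aucLow <- rbind(c(0.2, 0.2, 0.2), c(0.7, 0.8, 0.75), c(0.6, 0.6, 0.6))
    dmsSym <- panCancerDms(mkstats(q, aucLow, delta = -0.2), mf,
                           directionMode = "symmetric")
    expect_true("cgA" %in% names(dmsSym))
    expect_identical(mcols(dmsSym)$direction[names(dmsSym) == "cgA"],
                     "hypo")
    expect_false("cgA" %in% names(panCancerDms(mkstats(q, aucLow), mf)))
})

test_that("pan-cancer DMS selection is monotone in its thresholds", {
    mf <- generateManifest(100, "chr1", 150, seed = 14)
    pl <- plantedDMR("chr1", start(mf)[30], start(mf)[41], 12, 0.25)
    bcs <- generateBetaCohorts(mf, nCohorts = 2, nNormal = 20, nTumor = 20,
                               planted = pl, seed = 15)
    st <- cohortSiteStats(bcs)
    base <- names(panCancerDms(st, mf))
    expect_true(all(names(panCancerDms(st, mf, qThreshold = 0.001))
                    %in% base))
    expect_true(all(names(panCancerDms(st, mf, meanAucThreshold = 0.9))
                    %in% base))
    expect_true(all(names(panCancerDms(st, mf, qThreshold = 0.001,
                                       meanAucThreshold = 0.9)) %in% base))
})
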