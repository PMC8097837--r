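test_that("count table tallies resolved reads per CAG", {
    part <- CAGPartition(c(g1 = "c1", g2 = "c1", g3 = "c2"))
    asn <- data.frame(specimen = rep("s1", 10),
                      read_id = paste0("r", 1:10),
                      gene_id = c(rep("g1", 4), rep("g2", 3), rep("g3", 3)),
                      aligned_bases = 150L)
    ct <- buildCountTable(asn, part)
    expect_equal(ct$W["s1", "c1"], 7L)
    expect_equal(ct$W["s1", "c2"], 3L)
    expect_equal(unname(ct$M["s1"]), 10L)
    # all reads on one CAG
    one <- buildCountTable(asn[1:4, ], part)
    expect_equal(unname(one$M), 4L)
    expect_equal(one$W[1, "c1"], 4L)
    # unassigned gene is an error
    bad <- asn; bad$gene_id[1] <- "gX"
    expect_error(buildCountTable(bad, part), "gX")
    expect_error(buildCountTable(asn[0, ], part), "positive")
})

test_that("planted per-CAG allocation is reproduced exactly", {
    ex0 <- generateExperiment(
        syntheticConfig(n_genes = 60L, n_cags = 10L,
                        n_specimens_per_group = 4L, n_associated = 4L,
                        reads_per_specimen = 1500L,
                        multimap_fraction = 0),
        seed = 5)
    res <- resolveMultimappers(ex0$alignments, ex0$catalog)
    ct <- buildCountTable(res, ex0$truth$partition)
    # oracle: tabulate the generator's per-read truth directly
    tm <- membership(ex0$truth$partition)
    truth_tab <- table(ex0$truth$read_truth$specimen,
                       tm[ex0$truth$read_truth$gene_id])
    expect_equal(unname(ct$W[rownames(truth_tab), colnames(truth_tab)]),
                 unname(matrix(as.integer(truth_tab), nrow(truth_tab))))
})

test_that("the binomial limit reproduces the logistic MLE", {
    set.seed(10)
    X <- cbind(`(Intercept)` = 1, grp = rep(0:1, each = 30))
    mu <- plogis(-2 + 0.8 * X[, "grp"])
    M <- rep(5000L, 60)
    W <- rbinom(60, M, mu)  # no overdispersion
    f <- fitBetaBinomial(W, M, X)
    gl <- glm(cbind(W, M - W) ~ X - 1, family = binomial())
    expect_true(f$converged)
    expect_equal(unname(f$beta), unname(coef(gl)), tolerance = 1e-3)
    # intercept-only on homogeneous binomial data: inverse-logit(beta0)
    # equals the pooled proportion in the phi -> 0 limit
    W0 <- rbinom(60, M, plogis(-2))
    f0 <- fitBetaBinomial(W0, M, X[, 1, drop = FALSE])
    expect_equal(plogis(unname(f0$beta[1])), sum(W0) / sum(M),
                 tolerance = 1e-4)
})

test_that("fitted likelihood beats the warm start and has flat gradient", {
    set.seed(11)
    X <- cbind(`(Intercept)` = 1, grp = rep(0:1, each = 25))
    mu <- plogis(-3 + X[, "grp"])
    W <- rbetabinom_sim(50, 2000L, mu, 0.02)
    M <- rep(2000L, 50)
    f <- fitBetaBinomial(W, M, X)
    expect_true(f$converged)
    ll <- function(beta, phi) {
        m <- plogis(drop(X %*% beta))
        a <- m * (1 - phi) / phi; b <- (1 - m) * (1 - phi) / phi
        sum(lchoose(M, W) + lbeta(W + a, M - W + b) - lbeta(a, b))
    }
    # likelihood at the optimum >= likelihood at the null start
    gl <- glm(cbind(W, M - W) ~ X - 1, family = binomial())
    expect_gte(f$logLik, ll(coef(gl), 0.01))
    # numerical gradient in beta near zero at the optimum
    eps <- 1e-5
    for (j in 1:2) {
        bp <- f$beta; bp[j] <- bp[j] + eps
        bm <- f$beta; bm[j] <- bm[j] - eps
        expect_lt(abs(ll(bp, f$phi) - ll(bm, f$phi)) / (2 * eps), 0.05)
    }
    # degenerate counts are flagged, not fitted
    sep <- fitBetaBinomial(rep(0L, 50), M, X)
    expect_false(sep$converged)
    expect_equal(sep$flag, "separation")
})

test_that("effect estimates recover the simulated truth", {
    set.seed(3)
    X <- cbind(`(Intercept)` = 1, grp = rep(0:1, each = 100))
    mu <- plogis(-3 + 1 * X[, "grp"])
    est <- replicate(200, {
        W <- rbetabinom_sim(200, 3000L, mu, 0.02)
        f <- fitBetaBinomial(W, rep(3000L, 200), X)
        c(f$beta["grp"], f$se["grp"], f$converged)
    })
    conv <- est[3, ] == 1
    expect_gt(mean(conv), 0.95)
    b1 <- est[1, conv]; se1 <- est[2, conv]
    # each estimate within 3 SE of truth in almost all replicates
    expect_gt(mean(abs(b1 - 1) <= 3 * se1), 0.95)
    # mean estimate within 0.1 of the truth
    expect_lt(abs(mean(b1) - 1), 0.1)
})

test_that("the null Wald test is calibrated at the nominal level", {
    set.seed(4)
    X <- cbind(`(Intercept)` = 1, grp = rep(0:1, each = 25))
    mu <- rep(plogis(-3), 50)
    rej <- replicate(1000, {
        W <- rbetabinom_sim(50, 2000L, mu, 0.02)
        f <- fitBetaBinomial(W, rep(2000L, 50), X)
        f$converged && f$p["grp"] < 0.05
    })
    expect_gte(mean(rej), 0.03)
    expect_lte(mean(rej), 0.07)
})

test_that("BH adjustment matches the brute-force step-up definition", {
    expect_equal(bhAdjust(0.37), 0.37)
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    set.seed(9)
    for (rep in 1:50) {
        p <- runif(sample(2:40, 1))^sample(1:3, 1)
        q <- bhAdjust(p)
        expect_equal(q, bh_bruteforce(p))
        expect_true(all(q >= p))
    }
})

test_that("aggregation reduces to the fixed-effect closed form", {
    # single contributing CAG: aggregate equals the CAG itself
    cat1 <- GeneCatalog(c("g1", "g2"), c(100L, 100L),
                        taxon = c("tA", "tA"))
    part1 <- CAGPartition(c(g1 = "c1", g2 = "c1"))
    fits1 <- data.frame(cag_id = "c1", estimate = 0.7, se = 0.2,
                        converged = TRUE)
    agg1 <- aggregateByAnnotation(fits1, part1, cat1, "taxon")
    expect_equal(agg1$beta0_hat, 0.7)
    expect_equal(agg1$se0, 0.2)
    expect_equal(agg1$sigma2_hat, 0)

    # equal known variances, homogeneous effects: mean with SE sqrt(v/k)
    k <- 8
    set.seed(12)
    y <- rnorm(k, 0.5, 0.02)  # near-identical: sigma2 clamps at 0
    genes <- sprintf("g%02d", 1:k)
    catk <- GeneCatalog(genes, rep(100L, k), taxon = rep("tA", k))
    partk <- CAGPartition(setNames(sprintf("c%02d", 1:k), genes))
    fitsk <- data.frame(cag_id = sprintf("c%02d", 1:k), estimate = y,
                        se = 0.3, converged = TRUE)
    aggk <- aggregateByAnnotation(fitsk, partk, catk, "taxon")
    expect_equal(aggk$sigma2_hat, 0)
    expect_equal(aggk$beta0_hat, mean(y), tolerance = 1e-8)
    expect_equal(aggk$se0, sqrt(0.3^2 / k), tolerance = 1e-8)
})

test_that("aggregation agrees with an independent meta-analysis fit", {
    set.seed(13)
    k <- 25
    se <- runif(k, 0.1, 0.3)
    y <- rnorm(k, 0.8, sqrt(0.1 + se^2))
    genes <- sprintf("g%02d", 1:k)
    catk <- GeneCatalog(genes, rep(100L, k), taxon = rep("tA", k))
    partk <- CAGPartition(setNames(sprintf("c%02d", 1:k), genes))
    fitsk <- data.frame(cag_id = sprintf("c%02d", 1:k), estimate = y,
                        se = se, converged = TRUE)
    agg <- aggregateByAnnotation(fitsk, partk, catk, "taxon")
    rma <- metafor::rma(yi = y, sei = se, method = "ML")
    expect_equal(agg$beta0_hat, unname(coef(rma)), tolerance = 1e-4)
    expect_equal(agg$sigma2_hat, rma$tau2, tolerance = 1e-3)
    expect_equal(agg$se0, rma$se, tolerance = 1e-4)
})

test_that("label-level estimates recover the simulated truth", {
    set.seed(5)
    n_lab <- 50; k <- 20
    b0 <- numeric(n_lab)
    genes_all <- character(0); cags_all <- character(0)
    taxa_all <- character(0)
    fits <- NULL
    for (l in seq_len(n_lab)) {
        se <- runif(k, 0.1, 0.3)
        y <- 0.8 + rnorm(k, 0, sqrt(0.1)) + rnorm(k, 0, se)
        cg <- sprintf("L%02d_c%02d", l, 1:k)
        gn <- sprintf("L%02d_g%02d", l, 1:k)
        genes_all <- c(genes_all, gn); cags_all <- c(cags_all, cg)
        taxa_all <- c(taxa_all, rep(sprintf("tax%02d", l), k))
        fits <- rbind(fits, data.frame(cag_id = cg, estimate = y, se = se,
                                       converged = TRUE))
    }
    catk <- GeneCatalog(genes_all, rep(100L, length(genes_all)),
                        taxon = taxa_all)
    partk <- CAGPartition(setNames(cags_all, genes_all))
    agg <- aggregateByAnnotation(fits, partk, catk, "taxon")
    expect_equal(nrow(agg), n_lab)
    expect_lt(abs(mean(agg$beta0_hat) - 0.8), 0.05)
    expect_true(all(agg$sigma2_hat >= 0))
})

test_that("the label-level intercept test is calibrated under the null", {
    set.seed(6)
    n_lab <- 400; k <- 15
    p0 <- numeric(n_lab)
    for (l in seq_len(n_lab)) {
        se <- runif(k, 0.1, 0.3)
        y <- rnorm(k, 0, sqrt(0.05)) + rnorm(k, 0, se)
        genes <- sprintf("g%02d", 1:k)
        catk <- GeneCatalog(genes, rep(100L, k), taxon = rep("tA", k))
        partk <- CAGPartition(setNames(sprintf("c%02d", 1:k), genes))
        fits <- data.frame(cag_id = sprintf("c%02d", 1:k), estimate = y,
                           se = se, converged = TRUE)
        p0[l] <- aggregateByAnnotation(fits, partk, catk, "taxon")$p0
    }
    # ML heterogeneity + plug-in Wald is mildly anti-conservative at k=15;
    # accept within Monte-Carlo error of that known small-sample behaviour
    expect_gt(mean(p0 < 0.05), 0.02)
    expect_lt(mean(p0 < 0.05), 0.10)
})

test_that("significant CAGs split correctly by sign", {
    fits <- data.frame(cag_id = paste0("c", 1:5),
                       estimate = c(2, -1.5, 0.3, -0.2, 1),
                       q = c(0.001, 0.005, 0.5, 0.02, NA))
    s <- significantCags(fits, 0.01)
    expect_equal(s$positive, "c1")
    expect_equal(s$negative, "c2")
    expect_equal(significantCags(fits, 0)$n_positive, 0L)
})

test_that("a CAG with multiple taxa contributes to every one", {
    catk <- GeneCatalog(c("g1", "g2", "g3"), rep(100L, 3),
                        taxon = c("tA", "tB", "tB"))
    part <- CAGPartition(c(g1 = "c1", g2 = "c1", g3 = "c2"))
    fits <- data.frame(cag_id = c("c1", "c2"), estimate = c(1, 2),
                       se = c(0.1, 0.1), converged = TRUE)
    agg <- aggregateByAnnotation(fits, part, catk, "taxon")
    expect_setequal(agg$label, c("tA", "tB"))
    expect_equal(agg$n_cags[agg$label == "tB"], 2L)
    expect_equal(agg$n_cags[agg$label == "tA"], 1L)
    expect_equal(agg$beta0_hat[agg$label == "tA"], 1)
})
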