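# Independent oracles, kept free of the package's own code paths.

# brute-force step-up BH: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
bh_bruteforce <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m))
        q[i] <- min(1, min(ps[i:m] * m / (i:m)))
    out <- numeric(m)
    out[o] <- q
    out
}

# per-base bitmap union coverage of [start, end] intervals (1-based incl.)
bitmap_union_bases <- function(start, end, total_length) {
    bit <- logical(total_length)
    for (i in seq_along(start))
        bit[start[i]:end[i]] <- TRUE
    sum(bit)
}

# average-linkage clustering oracle via hclust on the exact cosine distance
# matrix, cut at the threshold
hclust_partition <- function(profiles, threshold) {
    nrm <- sqrt(rowSums(profiles^2))
    D <- 1 - tcrossprod(profiles / nrm)
    D[D < 0] <- 0
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    stats::cutree(hc, h = threshold)
}

# two labelings induce the same partition?
same_partition <- function(a, b) {
    stopifnot(length(a) == length(b))
    ta <- table(a, b)
    all(rowSums(ta > 0) == 1) && all(colSums(ta > 0) == 1)
}

# beta-binomial sampler for simulation truth (mean/correlation form)
rbetabinom_sim <- function(n, size, mu, phi) {
    q <- rbeta(n, mu * (1 - phi) / phi, (1 - mu) * (1 - phi) / phi)
    rbinom(n, size, q)
}
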