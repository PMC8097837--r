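#' Cosine distance between two abundance profiles
#'
#' \code{1 - (u . v) / (||u|| ||v||)}, clamped to [0, 1] for non-negative
#' profiles. The distance is 0 for parallel vectors and 1 for profiles with
#' disjoint support.
#'
#' @param u,v non-negative numeric vectors of equal length with positive
#'   norm.
#' @return Numeric scalar in [0, 1].
#' @examples
#' cosineDistance(c(1, 1, 0), c(0, 1, 1))  # 0.5
#' @export
cosineDistance <- function(u, v) {
    if (length(u) != length(v))
        stop("profiles must have equal length")
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0)
        stop("cosine distance undefined for the zero vector")
    min(max(1 - sum(u * v) / (nu * nv), 0), 1)
}

# pairwise cosine distance matrix over rows of P
.cosineDistMatrix <- function(P) {
    nrm <- sqrt(rowSums(P^2))
    if (any(nrm == 0))
        stop("cosine distance undefined for all-zero profile(s): ",
             paste(utils::head(rownames(P)[nrm == 0], 5), collapse = ", "))
    D <- 1 - tcrossprod(P / nrm)
    D[D < 0] <- 0
    D[D > 1] <- 1
    D
}

# Agglomerative average-linkage engine under cosine distance.
# Merges the globally closest pair while its average distance <= threshold
# (inclusive), via the exact Lance-Williams average-linkage update. Rows of
# P are processed in rowname order so the result is invariant to input
# permutation. Returns an integer label per row of P.
.avgLinkage <- function(P, threshold) {
    n <- nrow(P)
    if (n == 0L) return(integer())
    if (n == 1L) return(1L)
    D <- .cosineDistMatrix(P)
    diag(D) <- Inf
    size <- rep(1L, n)
    label <- seq_len(n)
    active <- rep(TRUE, n)
    W <- D
    repeat {
        k <- which.min(W)  # first minimum in column-major order: deterministic
        if (!length(k) || W[k] > threshold) break
        j <- ((k - 1L) %/% n) + 1L
        i <- ((k - 1L) %% n) + 1L
        if (i > j) { tmp <- i; i <- j; j <- tmp }
        act <- which(active); act <- act[act != i & act != j]
        if (length(act)) {
            dij <- (size[i] * D[i, act] + size[j] * D[j, act]) /
                (size[i] + size[j])
            D[i, act] <- dij; D[act, i] <- dij
            W[i, act] <- dij; W[act, i] <- dij
        }
        size[i] <- size[i] + size[j]
        active[j] <- FALSE
        label[label == j] <- i
        W[j, ] <- Inf; W[, j] <- Inf
        W[i, i] <- Inf
    }
    match(label, sort(unique(label)))
}

# Same agglomeration restricted to candidate pairs: only pairs marked in
# `allowed` may merge; on a merge the new cluster inherits the union of
# both candidate sets. Exact distances are always used, so the restriction
# can only withhold merges, never create wrong ones.
.avgLinkageRestricted <- function(P, threshold, allowed) {
    n <- nrow(P)
    if (n <= 1L) return(rep(1L, n))
    D <- .cosineDistMatrix(P)
    diag(D) <- Inf
    size <- rep(1L, n)
    label <- seq_len(n)
    active <- rep(TRUE, n)
    W <- D
    W[!allowed] <- Inf
    diag(W) <- Inf
    repeat {
        k <- which.min(W)
        if (!length(k) || W[k] > threshold) break
        j <- ((k - 1L) %/% n) + 1L
        i <- ((k - 1L) %% n) + 1L
        if (i > j) { tmp <- i; i <- j; j <- tmp }
        act <- which(active); act <- act[act != i & act != j]
        if (length(act)) {
            dij <- (size[i] * D[i, act] + size[j] * D[j, act]) /
                (size[i] + size[j])
            D[i, act] <- dij; D[act, i] <- dij
            cand <- allowed[i, act] | allowed[j, act]
            allowed[i, act] <- cand; allowed[act, i] <- cand
            W[i, act] <- ifelse(cand, dij, Inf)
            W[act, i] <- W[i, act]
        }
        size[i] <- size[i] + size[j]
        active[j] <- FALSE
        label[label == j] <- i
        W[j, ] <- Inf; W[, j] <- Inf
        W[i, i] <- Inf
    }
    match(label, sort(unique(label)))
}

# rank CAGs by descending member count, ties by smallest member gene_id;
# returns a CAGPartition with ids "CAG<zero-padded rank>"
.namePartition <- function(genes, label) {
    groups <- split(genes, label)
    sizes <- lengths(groups)
    minid <- vapply(groups, min, character(1))
    ord <- order(-sizes, minid)
    groups <- groups[ord]
    width <- max(nchar(as.character(length(groups))), 5L)
    ids <- sprintf("CAG%0*d", width, seq_along(groups))
    mem <- rep(ids, lengths(groups))
    names(mem) <- unlist(groups, use.names = FALSE)
    CAGPartition(mem[sort(names(mem))])
}

#' Exact average-linkage clustering of gene abundance profiles
#'
#' Non-sharded agglomerative clustering under the cosine distance:
#' repeatedly merge the pair of clusters with the smallest average pairwise
#' distance while that minimum is at or below \code{threshold}. This is the
#' exact (brute-force) routine the sharded scheme approximates; it is
#' quadratic in the number of genes.
#'
#' @param profiles numeric gene-by-specimen matrix of sequencing depth with
#'   gene identifiers as rownames; every gene must be detected (positive in
#'   at least one specimen).
#' @param threshold cosine-distance merge threshold (inclusive).
#' @return A \linkS4class{CAGPartition}.
#' @seealso [shardedCluster()] for the scalable multi-round scheme.
#' @export
averageLinkageCluster <- function(profiles, threshold) {
    stopifnot(is.matrix(profiles), threshold >= 0)
    if (nrow(profiles) == 0L) return(CAGPartition(character()))
    if (is.null(rownames(profiles)))
        stop("profiles must carry gene identifiers as rownames")
    profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
    label <- .avgLinkage(profiles, threshold)
    .namePartition(rownames(profiles), label)
}

# deterministic id-based shard assignment: polynomial string hash of
# (id, round, seed), centroids sorted by (hash, id) and cut into
# consecutive shards
.shardAssign <- function(ids, round, seed, shard_size) {
    h <- vapply(ids, function(s) {
        v <- utf8ToInt(paste0(s, "|", round, "|", seed))
        acc <- 0
        for (x in v) acc <- (acc * 131 + x) %% 2147483647
        acc
    }, numeric(1))
    ord <- order(h, ids)
    n_shards <- max(1L, ceiling(length(ids) / shard_size))
    shard <- integer(length(ids))
    shard[ord] <- rep(seq_len(n_shards), each = shard_size,
                      length.out = length(ids))
    shard
}

# symmetric candidate pairs from exact top-k cosine neighbours
.neighborCandidates <- function(P, k) {
    n <- nrow(P)
    S <- 1 - .cosineDistMatrix(P)  # similarity
    diag(S) <- -Inf
    allowed <- matrix(FALSE, n, n)
    k <- min(k, n - 1L)
    for (i in seq_len(n)) {
        nb <- order(S[i, ], decreasing = TRUE)[seq_len(k)]
        allowed[i, nb] <- TRUE
    }
    allowed | t(allowed)
}

#' Sharded multi-round clustering into co-abundant gene groups
#'
#' Scales average-linkage clustering to large gene catalogs. In each of the
#' first \code{n_rounds - 1} pre-clustering rounds, genes (or the cluster
#' centroids from the previous round) are assigned to shards of at most
#' \code{shard_size} members and clustered exactly within each shard at the
#' stringent threshold \code{tau / 2}; each resulting cluster is replaced
#' by the unweighted mean profile of its member genes, and shard membership
#' is reshuffled between rounds. The final round applies the user-specified
#' threshold \code{tau} globally, restricting the merge search to exact
#' top-\code{ann_neighbors} cosine neighbours of each centroid (candidate
#' generation only: all merge decisions recompute exact average-linkage
#' distances, so the pre-filter can miss merges but never create wrong
#' ones). With a single shard and \code{exact_final = TRUE} the result
#' equals [averageLinkageCluster()] on the pre-cluster centroids.
#'
#' The stringent pre-clustering threshold means the final CAGs are a
#' superset of the tighter groups formed in early rounds.
#'
#' @param profiles numeric gene-by-specimen depth matrix (rownames = gene
#'   ids); genes never detected in any specimen are excluded before
#'   clustering.
#' @param tau final-round cosine-distance threshold in (0, 1]; required.
#' @param shard_size maximum genes per shard (>= 2).
#' @param n_rounds total rounds including the final global round
#'   (default 5).
#' @param ann_neighbors candidate neighbours retrieved per centroid for the
#'   final round (default 20).
#' @param seed integer seed controlling shard assignment.
#' @param exact_final if TRUE the final round searches all centroid pairs
#'   (no neighbour restriction).
#' @return A \linkS4class{CAGPartition} over the detected genes.
#' @export
shardedCluster <- function(profiles, tau, shard_size, n_rounds = 5L,
                           ann_neighbors = 20L, seed = 0L,
                           exact_final = FALSE) {
    stopifnot(is.matrix(profiles))
    if (missing(tau) || !is.numeric(tau) || tau <= 0 || tau > 1)
        stop("tau (final cosine-distance threshold in (0,1]) is required")
    if (shard_size < 2L) stop("shard_size must be >= 2")
    if (ann_neighbors < 1L) stop("ann_neighbors must be >= 1")
    if (n_rounds < 1L) stop("n_rounds must be >= 1")
    detected <- rowSums(profiles) > 0
    profiles <- profiles[detected, , drop = FALSE]
    if (nrow(profiles) == 0L) return(CAGPartition(character()))
    profiles <- profiles[order(rownames(profiles)), , drop = FALSE]

    # state: one centroid per current cluster, named by smallest member id
    centroids <- profiles
    memb <- as.list(rownames(profiles))
    names(memb) <- rownames(profiles)

    pre_thresh <- tau / 2
    for (round in seq_len(n_rounds - 1L)) {
        ids <- rownames(centroids)
        shard <- .shardAssign(ids, round, seed, shard_size)
        new_memb <- list()
        new_centroids <- NULL
        for (s in sort(unique(shard))) {
            sel <- which(shard == s)
            sub <- centroids[sel, , drop = FALSE]
            lab <- .avgLinkage(sub, pre_thresh)
            for (cl in sort(unique(lab))) {
                ids_cl <- rownames(sub)[lab == cl]
                genes_cl <- sort(unlist(memb[ids_cl], use.names = FALSE))
                cen <- colMeans(profiles[genes_cl, , drop = FALSE])
                new_memb[[genes_cl[1L]]] <- genes_cl
                new_centroids <- rbind(new_centroids, cen)
                rownames(new_centroids)[nrow(new_centroids)] <- genes_cl[1L]
            }
        }
        ord <- order(rownames(new_centroids))
        centroids <- new_centroids[ord, , drop = FALSE]
        memb <- new_memb[rownames(centroids)]
    }

    # final global round at tau
    if (nrow(centroids) > 1L) {
        if (exact_final) {
            lab <- .avgLinkage(centroids, tau)
        } else {
            allowed <- .neighborCandidates(centroids, ann_neighbors)
            lab <- .avgLinkageRestricted(centroids, tau, allowed)
        }
    } else lab <- rep(1L, nrow(centroids))

    gene_label <- integer(0)
    gene_names <- character(0)
    for (i in seq_along(memb)) {
        gene_names <- c(gene_names, memb[[i]])
        gene_label <- c(gene_label, rep(lab[i], length(memb[[i]])))
    }
    .namePartition(gene_names, gene_label)
}

#' CAG-level relative abundance
#'
#' The abundance of each CAG in each specimen is the sum of sequencing
#' depth over the CAG's member genes divided by the total depth over all
#' detected genes in that specimen, so CAG abundances of one specimen sum
#' to 1.
#'
#' @param partition a \linkS4class{CAGPartition} covering the detected
#'   genes.
#' @param x a \linkS4class{GeneAbundance}.
#' @return Numeric CAG-by-specimen matrix.
#' @export
cagAbundance <- function(partition, x) {
    stopifnot(is(partition, "CAGPartition"), is(x, "GeneAbundance"))
    d <- depthMatrix(x)
    totals <- colSums(d)
    if (any(totals == 0))
        stop("cannot normalize specimen(s) with zero total depth: ",
             paste(colnames(d)[totals == 0], collapse = ", "))
    m <- membership(partition)
    missing_genes <- names(m)[!names(m) %in% rownames(d)]
    if (length(missing_genes))
        stop("partition genes absent from abundance matrix: ",
             paste(utils::head(missing_genes, 5), collapse = ", "))
    sub <- d[names(m), , drop = FALSE]
    agg <- rowsum(sub, group = m[rownames(sub)])
    sweep(agg, 2, totals, "/")
}

#' Distribution of genes across CAG size classes
#'
#' Counts genes falling in CAGs of each size range (1, 2, 3-4, 5-8, ...,
#' doubling bins). The counts sum to the number of genes in the partition.
#'
#' @param partition a \linkS4class{CAGPartition}.
#' @return data.frame with columns \code{size_range}, \code{n_cags} and
#'   \code{n_genes}.
#' @export
cagSizeSpectrum <- function(partition) {
    stopifnot(is(partition, "CAGPartition"))
    sizes <- as.integer(table(membership(partition)))
    if (!length(sizes))
        return(data.frame(size_range = character(), n_cags = integer(),
                          n_genes = integer()))
    # doubling bins [2^k, 2^(k+1) - 1]: 1, 2-3, 4-7, 8-15, ...
    lo <- 2^(0:max(0, floor(log2(max(sizes)))))
    bin <- findInterval(sizes, lo)
    lab <- vapply(lo, function(a) {
        if (a == 1) "1" else paste0(a, "-", 2 * a - 1)
    }, character(1))
    out <- data.frame(size_range = lab[sort(unique(bin))],
                      n_cags = as.integer(table(bin)),
                      n_genes = as.integer(tapply(sizes, bin, sum)))
    rownames(out) <- NULL
    out
}
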