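#' Per-CAG read count table
#'
#' Tallies the resolved reads of each specimen by the CAG of their assigned
#' gene, giving the counts \code{W[specimen, cag]} and per-specimen totals
#' \code{M[specimen]} used by the beta-binomial model.
#'
#' @param assignments data.frame of resolved assignments
#'   ([resolveMultimappers()] output).
#' @param partition a \linkS4class{CAGPartition}; every assigned gene must
#'   belong to it.
#' @return List with \code{W} (integer specimen-by-CAG matrix) and \code{M}
#'   (named integer vector of per-specimen totals).
#' @export
buildCountTable <- function(assignments, partition) {
    stopifnot(is.data.frame(assignments), is(partition, "CAGPartition"))
    if (!nrow(assignments))
        stop("no resolved reads: every specimen must have positive total")
    m <- membership(partition)
    unassigned <- setdiff(unique(assignments$gene_id), names(m))
    if (length(unassigned))
        stop("gene(s) not covered by the partition: ",
             paste(utils::head(unassigned, 5), collapse = ", "))
    cag <- m[assignments$gene_id]
    cags <- sort(unique(unname(m)))
    specs <- sort(unique(assignments$specimen))
    W <- table(factor(assignments$specimen, levels = specs),
               factor(cag, levels = cags))
    W <- matrix(as.integer(W), nrow = length(specs),
                dimnames = list(specs, cags))
    M <- rowSums(W)
    if (any(M == 0))
        stop("specimen(s) with zero resolved reads: ",
             paste(specs[M == 0], collapse = ", "))
    list(W = W, M = M)
}

# beta-binomial log density in the mean/correlation parameterization:
# a = mu(1-phi)/phi, b = (1-mu)(1-phi)/phi
.dbetabinomLog <- function(w, m, mu, phi) {
    a <- mu * (1 - phi) / phi
    b <- (1 - mu) * (1 - phi) / phi
    lchoose(m, w) + lbeta(w + a, m - w + b) - lbeta(a, b)
}

#' Fit a beta-binomial regression for one CAG
#'
#' Models the reads assigned to a CAG out of each specimen's total,
#' \code{W_s ~ BetaBinomial(M_s, mu_s, phi)}, with covariates on the logit
#' of the expected relative abundance, \code{logit(mu_s) = X_s beta}, and a
#' single overdispersion parameter \code{phi} in (0, 1) shared across
#' specimens (optimized on a logit-transformed internal scale). Maximum
#' likelihood by quasi-Newton (BFGS) from a logistic-regression warm start
#' with \code{phi} initialized at 0.01; standard errors from the observed
#' information; two-sided Wald p-values per coefficient against a
#' Student-t reference with \code{n - #parameters} degrees of freedom.
#'
#' Degenerate counts (all zero or all equal to the totals) are flagged as
#' separation and not fitted.
#'
#' @param W integer vector of per-specimen CAG read counts.
#' @param M integer vector of per-specimen total read counts (same length).
#' @param X design matrix, one row per specimen, including the intercept.
#' @return List with elements \code{beta}, \code{se}, \code{wald},
#'   \code{p} (named per column of X), \code{phi}, \code{logLik},
#'   \code{converged} and \code{flag} ("ok", "separation" or
#'   "no_convergence").
#' @export
fitBetaBinomial <- function(W, M, X) {
    X <- as.matrix(X)
    stopifnot(length(W) == length(M), nrow(X) == length(W))
    if (nrow(X) < ncol(X) + 1L)
        stop("need more specimens than model coefficients")
    if (any(W < 0) || any(W > M))
        stop("counts must satisfy 0 <= W <= M")
    p_names <- colnames(X)
    if (is.null(p_names)) p_names <- paste0("x", seq_len(ncol(X)))
    nap <- stats::setNames(rep(NA_real_, ncol(X)), p_names)
    if (all(W == 0) || all(W == M))
        return(list(beta = nap, se = nap, wald = nap, p = nap,
                    phi = NA_real_, logLik = NA_real_,
                    converged = FALSE, flag = "separation"))

    negll <- function(theta) {
        beta <- theta[seq_len(ncol(X))]
        phi <- stats::plogis(theta[ncol(X) + 1L])
        mu <- stats::plogis(drop(X %*% beta))
        mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
        phi <- pmin(pmax(phi, 1e-10), 1 - 1e-10)
        -sum(.dbetabinomLog(W, M, mu, phi))
    }
    warm <- suppressWarnings(
        stats::glm.fit(X, cbind(W, M - W), family = stats::binomial()))
    start <- c(warm$coefficients, stats::qlogis(0.01))
    start[!is.finite(start)] <- 0
    opt <- try(stats::optim(start, negll, method = "BFGS",
                            hessian = TRUE,
                            control = list(maxit = 500, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(opt, "try-error") || opt$convergence != 0)
        return(list(beta = nap, se = nap, wald = nap, p = nap,
                    phi = NA_real_, logLik = NA_real_,
                    converged = FALSE, flag = "no_convergence"))
    beta <- stats::setNames(opt$par[seq_len(ncol(X))], p_names)
    phi <- stats::plogis(opt$par[ncol(X) + 1L])
    vc <- try(solve(opt$hessian), silent = TRUE)
    if (inherits(vc, "try-error") || any(diag(vc)[seq_len(ncol(X))] <= 0))
        return(list(beta = beta, se = nap, wald = nap, p = nap,
                    phi = phi, logLik = -opt$value,
                    converged = FALSE, flag = "no_convergence"))
    se <- stats::setNames(sqrt(diag(vc)[seq_len(ncol(X))]), p_names)
    wald <- beta / se
    # Student-t reference with df = n - #parameters: the usual small-sample
    # correction for ML Wald tests with an estimated dispersion
    df <- length(W) - ncol(X) - 1L
    p <- if (df > 0) 2 * stats::pt(-abs(wald), df) else
        2 * stats::pnorm(-abs(wald))
    list(beta = beta, se = se, wald = wald, p = p, phi = phi,
         df = df, logLik = -opt$value, converged = TRUE, flag = "ok")
}

#' Fit the beta-binomial model for every CAG
#'
#' Builds the design matrix from a Wilkinson-style formula over the
#' manifest covariates and fits [fitBetaBinomial()] per CAG, then adjusts
#' the p-values of the coefficient of interest by Benjamini-Hochberg
#' across the converged fits.
#'
#' @param counts list with \code{W} and \code{M} from [buildCountTable()].
#' @param covariates data.frame of per-specimen covariates (rownames =
#'   specimen).
#' @param formula right-hand-side formula string over covariate columns,
#'   e.g. \code{"outcome"} or \code{"outcome + cohort"}.
#' @param coef name of the coefficient of interest for FDR adjustment;
#'   defaults to the first non-intercept column.
#' @return data.frame with one row per CAG: estimate, se, wald, p, q for
#'   the chosen coefficient, plus phi, converged and flag.
#' @export
fitAllCags <- function(counts, covariates, formula, coef = NULL) {
    specs <- rownames(counts$W)
    missing_cov <- setdiff(specs, rownames(covariates))
    if (length(missing_cov))
        stop("covariates missing for specimen(s): ",
             paste(utils::head(missing_cov, 5), collapse = ", "))
    covariates <- covariates[specs, , drop = FALSE]
    X <- stats::model.matrix(stats::as.formula(paste("~", formula)),
                             data = covariates)
    if (qr(X)$rank < ncol(X))
        stop("design matrix is rank deficient")
    if (is.null(coef)) {
        non_int <- setdiff(colnames(X), "(Intercept)")
        if (!length(non_int)) stop("no non-intercept coefficient to test")
        coef <- non_int[1L]
    }
    if (!coef %in% colnames(X))
        stop("coefficient not in design matrix: ", coef)
    cags <- colnames(counts$W)
    rows <- lapply(cags, function(cg) {
        f <- fitBetaBinomial(counts$W[, cg], counts$M, X)
        data.frame(cag_id = cg,
                   estimate = unname(f$beta[coef]),
                   se = unname(f$se[coef]),
                   wald = unname(f$wald[coef]),
                   p = unname(f$p[coef]),
                   phi = f$phi,
                   converged = f$converged,
                   flag = f$flag,
                   stringsAsFactors = FALSE)
    })
    fits <- do.call(rbind, rows)
    fits$q <- NA_real_
    ok <- fits$converged & !is.na(fits$p)
    fits$q[ok] <- bhAdjust(fits$p[ok])
    fits
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: \code{q_(i) = min_{j >= i} p_(j) m / j},
#' capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Split significant CAGs by coefficient sign
#'
#' @param fits data.frame from [fitAllCags()] with columns cag_id,
#'   estimate, q.
#' @param q_threshold FDR threshold (CAGs with \code{q <= q_threshold} are
#'   significant).
#' @return List with character vectors \code{positive} and \code{negative}
#'   and integer counts \code{n_positive}, \code{n_negative}.
#' @export
significantCags <- function(fits, q_threshold) {
    stopifnot(all(c("cag_id", "estimate", "q") %in% colnames(fits)))
    sig <- !is.na(fits$q) & fits$q <= q_threshold
    pos <- fits$cag_id[sig & fits$estimate > 0]
    neg <- fits$cag_id[sig & fits$estimate < 0]
    list(positive = pos, negative = neg,
         n_positive = length(pos), n_negative = length(neg))
}
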