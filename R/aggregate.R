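# ML errors-in-response fit for one label: y_c = beta0 + eps_c + u_c with
# u_c ~ N(0, se_c^2) known and eps_c ~ N(0, sigma2) estimated. Profile
# likelihood: for fixed sigma2 the MLE of beta0 is the inverse-variance
# weighted mean with weights 1/(sigma2 + se^2).
.fitErrorsInResponse <- function(y, se) {
    v <- se^2
    prof <- function(s2) {
        w <- 1 / (s2 + v)
        b0 <- sum(w * y) / sum(w)
        -0.5 * sum(log(s2 + v) + (y - b0)^2 / (s2 + v))
    }
    if (length(y) == 1L) {
        s2 <- 0
    } else {
        upper <- max(stats::var(y) * 4, max(v), 1e-6)
        op <- stats::optimize(prof, c(0, upper), maximum = TRUE,
                              tol = 1e-10)
        # compare against the boundary: variance estimate clamps at 0
        s2 <- if (prof(0) >= op$objective) 0 else op$maximum
    }
    w <- 1 / (s2 + v)
    b0 <- sum(w * y) / sum(w)
    se0 <- sqrt(1 / sum(w))
    k <- length(y)
    if (k > 1L) {
        # Knapp-Hartung: scaled variance estimator with a t(k-1) reference;
        # the plug-in normal Wald test is anti-conservative at small k
        se_kh <- sqrt(sum(w * (y - b0)^2) / ((k - 1) * sum(w)))
        p0 <- 2 * stats::pt(-abs(b0 / se_kh), k - 1)
    } else {
        p0 <- 2 * stats::pnorm(-abs(b0 / se0))
    }
    list(beta0_hat = b0, se0 = se0, sigma2_hat = s2, p0 = p0,
         clamped = k > 1L && s2 == 0)
}

#' Aggregate CAG coefficients to taxon or function level
#'
#' For each taxonomic or functional label, collects the fitted coefficient
#' and standard error of every converged CAG containing at least one gene
#' carrying that label, and fits an intercept-only errors-in-response
#' random-effects model: the CAG coefficients are treated as noisy
#' observations (known variances \code{se^2}) of a shared label-level
#' effect with additional between-CAG heterogeneity \code{sigma^2}
#' estimated by maximum likelihood. The hypothesis that the label-level
#' intercept is zero is tested with the Knapp-Hartung adjusted statistic
#' (t reference with k - 1 degrees of freedom), which keeps the test close
#' to nominal at small CAG counts where the plug-in normal Wald test is
#' anti-conservative; \code{se0} reports the conventional inverse-variance
#' standard error. A CAG whose genes carry several labels contributes to
#' each label's aggregate.
#'
#' @param fits data.frame from [fitAllCags()] (columns cag_id, estimate,
#'   se, converged).
#' @param partition a \linkS4class{CAGPartition}.
#' @param catalog a \linkS4class{GeneCatalog} carrying the annotation
#'   column.
#' @param label_kind \code{"taxon"} or \code{"function"}: which annotation
#'   column supplies the labels.
#' @return data.frame with one row per label: beta0_hat, se0, sigma2_hat,
#'   p0, n_cags, clamped (TRUE when the heterogeneity estimate hit the
#'   zero boundary). Labels with no contributing converged CAG are omitted.
#' @export
aggregateByAnnotation <- function(fits, partition, catalog,
                                  label_kind = c("taxon", "function")) {
    label_kind <- match.arg(label_kind)
    tbl <- catalogTable(catalog)
    if (!label_kind %in% colnames(tbl))
        stop("catalog carries no '", label_kind, "' annotation")
    ann <- stats::setNames(as.character(tbl[[label_kind]]), tbl$gene_id)
    ann <- ann[!is.na(ann) & nzchar(ann)]
    if (!length(ann))
        stop("no gene is annotated with a ", label_kind)
    m <- membership(partition)
    ok <- fits$converged & !is.na(fits$se) & fits$se > 0
    fits <- fits[ok, , drop = FALSE]

    # label -> set of contributing CAGs (any constituent annotated gene)
    genes_ann <- intersect(names(ann), names(m))
    pair <- unique(data.frame(label = unname(ann[genes_ann]),
                              cag = unname(m[genes_ann]),
                              stringsAsFactors = FALSE))
    pair <- pair[pair$cag %in% fits$cag_id, , drop = FALSE]
    if (!nrow(pair))
        return(data.frame(label = character(), beta0_hat = numeric(),
                          se0 = numeric(), sigma2_hat = numeric(),
                          p0 = numeric(), n_cags = integer(),
                          clamped = logical()))
    est <- stats::setNames(fits$estimate, fits$cag_id)
    sev <- stats::setNames(fits$se, fits$cag_id)
    rows <- lapply(split(pair$cag, pair$label), function(cags) {
        f <- .fitErrorsInResponse(unname(est[cags]), unname(sev[cags]))
        data.frame(beta0_hat = f$beta0_hat, se0 = f$se0,
                   sigma2_hat = f$sigma2_hat, p0 = f$p0,
                   n_cags = length(cags), clamped = f$clamped)
    })
    out <- do.call(rbind, rows)
    out <- cbind(data.frame(label = names(rows), stringsAsFactors = FALSE),
                 out)
    rownames(out) <- NULL
    out[order(out$label), , drop = FALSE]
}
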