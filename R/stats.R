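## Shapiro-Wilk normality gate at alpha = 0.05; groups too small for the
## test count as non-normal (the non-parametric route is taken)
.isNormal <- function(x, alpha = 0.05) {
    x <- x[!is.na(x)]
    if (length(x) < 3L || length(unique(x)) < 3L) return(FALSE)
    stats::shapiro.test(x)$p.value > alpha
}

#' Percent change of a group mean against a reference
#'
#' \code{100 * (value - reference) / reference}. Report display rounds to
#' whole percent; the exact value is returned here.
#'
#' @param value group mean.
#' @param reference reference (e.g. healthy-control) mean; must be nonzero.
#' @return percent change (numeric).
#' @examples
#' percentChange(23, 50)   # -54
#' percentChange(0.12, 0.18)  # -33.3
#' @export
percentChange <- function(value, reference) {
    if (any(reference == 0)) stop("percent change undefined for zero reference")
    100 * (value - reference) / reference
}

#' Compare a parameter between cohorts
#'
#' Two groups: Shapiro-Wilk (alpha 0.05) per group decides between Student's
#' t-test (both normal) and the Mann-Whitney rank-sum test; groups with
#' fewer than 3 subjects skip the gate and use the non-parametric route
#' with a warning. More than two groups: one-way ANOVA followed by Tukey's
#' HSD post-hoc contrasts.
#'
#' @param table subject-level data.frame (e.g. from [synthCohort()]).
#' @param parameter column to compare.
#' @param grouping grouping column (default \code{"cohort"}).
#' @param reference for the two-group percent change: the reference group
#'   label (default the first level encountered).
#' @return data.frame, one row per comparison: parameter, groups, group
#'   means and sds, percentChange (display-rounded to integer), test, p.
#' @export
compareGroups <- function(table, parameter, grouping = "cohort",
                          reference = NULL) {
    g <- factor(table[[grouping]])
    x <- table[[parameter]]
    ok <- !is.na(x) & !is.na(g)
    x <- x[ok]; g <- droplevels(g[ok])
    lev <- levels(g)
    if (length(lev) < 2L) stop("need at least 2 groups")
    if (any(table(g) < 2L)) stop("need at least 2 subjects per group")
    if (is.null(reference)) reference <- lev[1]
    if (length(lev) == 2L) {
        a <- x[g == lev[1]]; b <- x[g == lev[2]]
        small <- length(a) < 3L || length(b) < 3L
        if (small)
            warning("group with fewer than 3 subjects; normality gate skipped, non-parametric test used")
        normal <- !small && .isNormal(a) && .isNormal(b)
        if (normal) {
            ht <- stats::t.test(a, b)
            test <- "t-test"
        } else {
            ht <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
            test <- "mann-whitney"
        }
        other <- setdiff(lev, reference)
        pc <- if (mean(x[g == reference]) != 0)
            round(percentChange(mean(x[g == other]), mean(x[g == reference])))
        else NA_real_
        data.frame(parameter = parameter, group1 = lev[1], group2 = lev[2],
                   mean1 = mean(a), sd1 = stats::sd(a),
                   mean2 = mean(b), sd2 = stats::sd(b),
                   percentChange = pc, test = test, p = ht$p.value,
                   stringsAsFactors = FALSE)
    } else {
        fit <- stats::aov(x ~ g)
        pAnova <- summary(fit)[[1]][["Pr(>F)"]][1]
        tk <- stats::TukeyHSD(fit)$g
        ## enumerate level pairs directly: level names may contain hyphens,
        ## so the Tukey rownames cannot be parsed reliably
        cmb <- utils::combn(lev, 2)
        out <- lapply(seq_len(ncol(cmb)), function(j) {
            gg <- c(cmb[2, j], cmb[1, j])
            i <- match(paste(gg[1], gg[2], sep = "-"), rownames(tk))
            a <- x[g == gg[2]]; b <- x[g == gg[1]]
            data.frame(parameter = parameter, group1 = gg[2], group2 = gg[1],
                       mean1 = mean(a), sd1 = stats::sd(a),
                       mean2 = mean(b), sd2 = stats::sd(b),
                       percentChange = if (mean(a) != 0)
                           round(percentChange(mean(b), mean(a))) else NA_real_,
                       test = "anova+tukey", p = tk[i, "p adj"],
                       stringsAsFactors = FALSE)
        })
        out <- do.call(rbind, out)
        attr(out, "anovaP") <- pAnova
        out
    }
}

#' Correlate two parameters with the joint significance rule
#'
#' Pearson correlation when both variables pass the Shapiro-Wilk gate,
#' Spearman otherwise. A correlation is flagged significant only under the
#' joint rule: p at or below 0.05 AND |R| above 0.25.
#'
#' @param table subject-level data.frame.
#' @param x,y column names.
#' @return one-row data.frame: x, y, method, R, p, significant. R is also
#'   carried display-rounded to 3 decimals in \code{Rdisplay}.
#' @export
correlate <- function(table, x, y) {
    xv <- table[[x]]; yv <- table[[y]]
    ok <- !is.na(xv) & !is.na(yv)
    xv <- xv[ok]; yv <- yv[ok]
    if (length(xv) < 4L) stop("need at least 4 paired observations")
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
        warning("constant variable; correlation undefined")
        return(data.frame(x = x, y = y, method = NA_character_, R = NA_real_,
                          Rdisplay = NA_real_, p = NA_real_,
                          significant = FALSE, stringsAsFactors = FALSE))
    }
    method <- if (.isNormal(xv) && .isNormal(yv)) "pearson" else "spearman"
    ct <- suppressWarnings(stats::cor.test(xv, yv, method = method))
    R <- unname(ct$estimate)
    data.frame(x = x, y = y, method = method, R = R, Rdisplay = round(R, 3),
               p = ct$p.value,
               significant = ct$p.value <= 0.05 && abs(R) > 0.25,
               stringsAsFactors = FALSE)
}

#' Multivariable model of indexed diameter on hemodynamics
#'
#' Builds the standardized multiple linear regression: candidate predictors
#' enter only if their univariate association with the dependent variable
#' passes the joint rule (p at or below 0.05 and |R| above 0.25) and they
#' survive a pairwise collinearity screen (when two retained candidates
#' correlate with |r| above the threshold, the one with the weaker
#' univariate |R| is dropped). Age is always retained. All variables are
#' z-scored, so coefficients are standardized betas.
#'
#' @param table subject-level data.frame.
#' @param dependent dependent column (e.g. BSA-indexed AAo diameter).
#' @param candidates character vector of candidate predictor columns.
#' @param age name of the always-retained age column (default "age"; set
#'   NULL to disable).
#' @param collinearityR pairwise |r| threshold of the screen (default 0.7).
#' @return list: \code{coefficients} data.frame (predictor, beta, p,
#'   retained rule), \code{overallR} multiple correlation coefficient,
#'   \code{dropped} named character of excluded candidates and why, and
#'   \code{fit} the underlying \code{lm}.
#' @export
multivariateModel <- function(table, dependent, candidates, age = "age",
                              collinearityR = 0.7) {
    keep <- stats::complete.cases(table[, c(dependent, candidates,
                                            if (!is.null(age)) age)])
    df <- table[keep, , drop = FALSE]
    if (nrow(df) < 10L) stop("need at least 10 complete subjects")
    dropped <- character(0)
    uni <- vapply(candidates, function(p) {
        r <- correlate(df, p, dependent)
        c(R = r$R, sig = as.numeric(r$significant))
    }, numeric(2))
    retained <- candidates[!is.na(uni["sig", ]) & uni["sig", ] == 1]
    for (p in setdiff(candidates, retained))
        dropped[p] <- "no significant univariate association"
    ## pairwise collinearity screen among retained candidates
    if (length(retained) > 1L) {
        ord <- retained[order(-abs(uni["R", retained]))]
        kept <- character(0)
        for (p in ord) {
            if (length(kept) &&
                any(abs(stats::cor(df[[p]], df[, kept])) > collinearityR)) {
                dropped[p] <- "collinear with a stronger predictor"
            } else kept <- c(kept, p)
        }
        retained <- retained[retained %in% kept]
    }
    preds <- c(if (!is.null(age)) age, retained)
    if (!length(preds)) stop("no predictors retained")
    Z <- as.data.frame(lapply(df[, c(dependent, preds), drop = FALSE],
                              function(v) if (stats::sd(v) == 0)
                                  rep(0, length(v)) else as.numeric(scale(v))))
    names(Z) <- c(".y", preds)
    ## guard against residual exact singularity
    fit <- stats::lm(.y ~ ., data = Z)
    while (anyNA(stats::coef(fit))) {
        bad <- names(which(is.na(stats::coef(fit))))[1]
        warning(sprintf("dropping '%s': singular design", bad))
        dropped[bad] <- "singular design"
        preds <- setdiff(preds, bad)
        fit <- stats::lm(.y ~ ., data = Z[, c(".y", preds), drop = FALSE])
    }
    sm <- summary(fit)
    cf <- stats::coef(sm)
    rows <- rownames(cf) != "(Intercept)"
    list(coefficients = data.frame(
             predictor = rownames(cf)[rows],
             beta = unname(cf[rows, "Estimate"]),
             p = unname(cf[rows, "Pr(>|t|)"]),
             stringsAsFactors = FALSE),
         overallR = if (is.finite(sm$r.squared)) sqrt(sm$r.squared) else 0,
         dropped = dropped,
         fit = fit)
}
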