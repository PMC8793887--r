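#' Published regional reference statistics
#'
#' Literature-reported per-region summary statistics (mean, sd, group size)
#' of voxel-wise aortic 4D-flow parameters and diameters for healthy
#' controls, BAV patients and BAV subgroups (dilation severity, Sievers
#' valve type). Used as the default effect structure of [synthCohort()] and
#' as inputs to percent-change worked examples.
#'
#' @param comparison optional filter: keep only rows whose \code{group} is in
#'   this character vector.
#' @return data.frame with columns region, parameter, group, mean, sd, n.
#' @examples
#' head(referenceRegionalStats())
#' @export
referenceRegionalStats <- function(comparison = NULL) {
    path <- system.file("extdata", "reference_regional_stats.csv",
                        package = "VoxelFlow", mustWork = TRUE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!is.null(comparison)) df <- df[df$group %in% comparison, ]
    df
}

## log-normal parameters matched to a target mean and sd
.lnormPars <- function(m, s) {
    s2 <- log(1 + (s / m)^2)
    list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a subject-level cohort table
#'
#' Draws per-subject regional hemodynamic parameters for two (or more)
#' groups with a stated mean/sd structure, emulating the statistical shape
#' the cohort analysis assumes. Strictly positive parameters (FF, RF, KE,
#' peak velocity, diameters) are drawn log-normal with moment-matched
#' mean/sd so no negative values occur; stasis is drawn normal and clipped
#' to [0, 100]. Ages and BSA are drawn normal (age truncated at 18). Output
#' is deterministic under a fixed seed.
#'
#' @param nPerGroup named integer vector: subjects per group, names are the
#'   cohort labels (default the reference control/BAV sizes 23 and 73).
#' @param stats data.frame with columns region, parameter, group, mean, sd
#'   (default [referenceRegionalStats()] restricted to the groups named in
#'   \code{nPerGroup}).
#' @param seed integer seed.
#' @return data.frame: one row per subject with columns subject, cohort,
#'   valveType, age, sex, height, weight, bsa, surgery and one
#'   \code{<region>_<parameter>} column per regional parameter.
#' @examples
#' tab <- synthCohort(c(control = 5, bav = 5), seed = 1)
#' dim(tab)
#' @export
synthCohort <- function(nPerGroup = c(control = 23, bav = 73),
                        stats = NULL, seed = 1L) {
    if (is.null(names(nPerGroup)) || any(!nzchar(names(nPerGroup))))
        stop("nPerGroup must be a named vector of group sizes")
    if (any(nPerGroup < 2)) stop("need at least 2 subjects per group")
    if (is.null(stats)) stats <- referenceRegionalStats(names(nPerGroup))
    if (any(stats$sd < 0)) stop("sds must be non-negative")
    positive <- c("ff", "rf", "ke", "peakVelocity", "diameter",
                  "indexedDiameter")
    .withSeed(seed, {
        rows <- lapply(names(nPerGroup), function(g) {
            n <- nPerGroup[[g]]
            st <- stats[stats$group == g, ]
            df <- data.frame(
                subject = paste0(g, "_", seq_len(n)),
                cohort = g, stringsAsFactors = FALSE)
            agest <- st[st$parameter == "age", ]
            bsast <- st[st$parameter == "bsa", ]
            df$age <- if (nrow(agest)) pmax(18, stats::rnorm(n, agest$mean[1],
                                                             agest$sd[1]))
                      else pmax(18, stats::rnorm(n, 45, 15))
            df$sex <- sample(c("F", "M"), n, replace = TRUE,
                             prob = c(0.3, 0.7))
            df$height <- stats::rnorm(n, 172, 9)
            df$bsa <- if (nrow(bsast)) pmax(1.2, stats::rnorm(n, bsast$mean[1],
                                                              bsast$sd[1]))
                      else pmax(1.2, stats::rnorm(n, 1.9, 0.25))
            ## weight consistent with the drawn BSA under the Mosteller rule
            df$weight <- 3600 * df$bsa^2 / df$height
            df$valveType <- if (g == "control") "tricuspid" else
                sample(c("0", "1-RL", "1-RN", "2", "unknown"), n,
                       replace = TRUE, prob = c(19, 36, 11, 4, 3) / 73)
            df$surgery <- if (g == "control") FALSE else
                stats::runif(n) < 24 / 73
            reg <- st[!st$parameter %in% c("age", "bsa"), ]
            for (i in seq_len(nrow(reg))) {
                col <- paste0(reg$region[i], "_", reg$parameter[i])
                m <- reg$mean[i]; s <- reg$sd[i]
                v <- if (reg$parameter[i] %in% positive && m > 0 && s > 0) {
                    lp <- .lnormPars(m, s)
                    stats::rlnorm(n, lp$meanlog, lp$sdlog)
                } else if (s > 0) stats::rnorm(n, m, s) else rep(m, n)
                if (reg$parameter[i] == "stasis") v <- pmin(100, pmax(0, v))
                df[[col]] <- v
            }
            df
        })
        cols <- Reduce(union, lapply(rows, names))
        rows <- lapply(rows, function(df) {
            df[setdiff(cols, names(df))] <- NA
            df[cols]
        })
        out <- do.call(rbind, rows)
        if ("AAo_diameter" %in% names(out))
            out$dilation <- vapply(out$AAo_diameter, classifyDilation,
                                   character(1))
        rownames(out) <- NULL
        out
    })
}
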