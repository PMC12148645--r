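## Batch regression over every (pathway, tier, feature) bundle and the
## effect-matrix / relative-percent-change summaries.

TERMS <- c(age = "Age", sex = "Sex", interaction = "Age:Sex", ticv = "zTICV")

#' Fit the developmental model to every bundle feature
#'
#' Runs the robust regression
#' `feature ~ Age + Sex + Age:Sex + zTICV` (bisquare IRLS) on each
#' (pathway, tier, feature) row of the experiment. Features are
#' z-transformed per bundle-feature column by default so coefficients are
#' in SD units (SD/year for age); set `standardize = FALSE` when the values
#' are already on the standardized scale. Benjamini-Hochberg FDR is applied
#' per term within each tier's pathway-by-feature matrix (one family per
#' coefficient panel).
#'
#' A cell whose fit fails is reported with NA estimates and `failed = TRUE`
#' without aborting the batch.
#'
#' @param se an [SAFExperiment-class].
#' @param standardize z-transform each bundle-feature column first.
#' @param alpha FDR level.
#' @param tuningC bisquare tuning constant.
#' @return data.frame with one row per (pathway, tier, feature, term):
#'   estimate, se, t, p, q, significant, converged, failed.
#' @export
fitAllBundles <- function(se, standardize = TRUE, alpha = 0.05,
                          tuningC = 4.685) {
  X <- buildDesign(cohortTable(se))
  rd <- as.data.frame(rowData(se))
  m <- assay(se, "features")
  rows <- list()
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    fit <- try(suppressMessages({
      if (standardize) y <- zTransform(y, rownames(m)[i])
      fitRobustLM(X, y, tuningC = tuningC)
    }), silent = TRUE)
    for (term in names(TERMS)) {
      cn <- TERMS[[term]]
      if (inherits(fit, "try-error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = rd$pathway[i], tier = rd$tier[i], feature = rd$feature[i],
          term = term, estimate = NA_real_, se = NA_real_, t = NA_real_,
          p = NA_real_, converged = NA, failed = TRUE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = rd$pathway[i], tier = rd$tier[i], feature = rd$feature[i],
          term = term, estimate = unname(fit@beta[cn]),
          se = unname(fit@se[cn]), t = unname(fit@tStat[cn]),
          p = unname(fit@pValue[cn]), converged = fit@converged,
          failed = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  res$significant <- NA
  for (term in names(TERMS)) {
    for (tier in TIERS) {
      fam <- which(res$term == term & res$tier == tier & !res$failed)
      if (length(fam)) {
        adj <- bhFdr(res$p[fam], alpha)
        res$q[fam] <- adj$q
        res$significant[fam] <- adj$reject
      }
    }
  }
  res
}

#' Pivot batch results into a pathway-by-feature effect matrix
#'
#' @param results output of [fitAllBundles()].
#' @param term one of `"age"`, `"sex"`, `"interaction"`, `"ticv"`.
#' @param tier `"SAF"` or `"LR"`.
#' @param value which column to tabulate (default `"estimate"`).
#' @return pathway x feature numeric matrix.
#' @export
effectMatrix <- function(results, term = "age", tier = "SAF",
                         value = "estimate") {
  sub <- results[results$term == term & results$tier == tier, ]
  pw <- unique(sub$pathway)
  m <- matrix(NA_real_, length(pw), length(FEATURES),
              dimnames = list(pw, FEATURES))
  m[cbind(match(sub$pathway, pw), match(sub$feature, FEATURES))] <- sub[[value]]
  m
}

#' Relative percent change per year for every bundle
#'
#' Refits the developmental model on the raw (untransformed) feature values
#' and expresses the female-model age slope as a percent of the cohort-mean
#' feature value per year.
#'
#' @param se an [SAFExperiment-class].
#' @param tuningC bisquare tuning constant.
#' @return data.frame: pathway, tier, feature, beta1Raw, meanFeature,
#'   percentPerYear.
#' @export
relPercentChangeTable <- function(se, tuningC = 4.685) {
  X <- buildDesign(cohortTable(se))
  rd <- as.data.frame(rowData(se))
  m <- assay(se, "features")
  out <- data.frame(pathway = rd$pathway, tier = rd$tier,
                    feature = rd$feature, beta1Raw = NA_real_,
                    meanFeature = NA_real_, percentPerYear = NA_real_)
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    fit <- try(fitRobustLM(X, y, tuningC = tuningC), silent = TRUE)
    if (inherits(fit, "try-error")) next
    out$beta1Raw[i] <- unname(fit@beta["Age"])
    out$meanFeature[i] <- mean(y)
    out$percentPerYear[i] <- relativePercentChange(out$beta1Raw[i],
                                                   out$meanFeature[i])
  }
  out
}

#' Compare SAF vs LR effect sizes per pathway and feature
#'
#' For each pathway and feature, tests whether the chosen coefficient
#' differs between the SAF fit and the LR fit using
#' [compareEffectSizes()], with BH FDR across the pathway-by-feature
#' family.
#'
#' @param results output of [fitAllBundles()].
#' @param term coefficient to compare (default `"age"`).
#' @param alpha FDR level.
#' @return data.frame: pathway, feature, betaSAF, betaLR, t, p, q,
#'   significant.
#' @export
compareTiers <- function(results, term = "age", alpha = 0.05) {
  sub <- results[results$term == term & !results$failed, ]
  saf <- sub[sub$tier == "SAF", ]
  lr <- sub[sub$tier == "LR", ]
  key <- function(d) paste(d$pathway, d$feature)
  common <- intersect(key(saf), key(lr))
  saf <- saf[match(common, key(saf)), ]
  lr <- lr[match(common, key(lr)), ]
  tp <- mapply(function(ba, sa, bb, sb) compareEffectSizes(ba, sa, bb, sb),
               saf$estimate, saf$se, lr$estimate, lr$se)
  out <- data.frame(pathway = saf$pathway, feature = saf$feature,
                    betaSAF = saf$estimate, betaLR = lr$estimate,
                    t = tp[1, ], p = tp[2, ])
  adj <- bhFdr(out$p, alpha)
  out$q <- adj$q
  out$significant <- adj$reject
  out
}
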