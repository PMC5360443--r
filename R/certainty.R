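#' Certainty binning and linear mixed-effects analysis
#'
#' Trials are binned by the proportion of cycles showing the more frequent
#' image (ten 5-percentage-point bins from 50-55% up to 95-100%), and the
#' effect of certainty on log2(SNR) over the posterior ROI is tested with
#' likelihood-ratio tests between nested linear mixed models fitted by
#' maximum likelihood (lme4).
#'
#' @name certainty-stats
NULL

#' Certainty bin of a dominant-image proportion
#'
#' Left-closed 5%-wide bins: `[50, 55) -> 1`, ..., `[95, 100] -> 10`
#' (p = 1 belongs to bin 10).
#'
#' @param p proportion(s) in `[0.5, 1]`.
#' @return data.frame with columns `p`, `index` (1-10), `lower`, `upper`
#'   (bin limits in percent).
#' @examples
#' certainty_bin(c(0.52, 0.55, 1))$index # 1, 2, 10
#' @export
certainty_bin <- function(p) {
  if (any(p < 0.5 | p > 1)) stop("`p` must lie in [0.5, 1]")
  idx <- pmin(1L + as.integer(floor((p - 0.5) / 0.05 + 1e-9)), 10L)
  data.frame(p = p, index = idx,
             lower = 50 + 5 * (idx - 1), upper = 55 + 5 * (idx - 1))
}

restrict_roi <- function(tab, roi) {
  out <- tab[tab$channel %in% roi, , drop = FALSE]
  if (nrow(out) == 0) stop("no rows left after ROI restriction")
  out
}

# Build an lmer formula string; diag = TRUE requests diagonal (uncorrelated
# intercept/slope) random effects for every grouping in the nesting.
lme_formula <- function(fixed, nesting, diag = FALSE) {
  groups <- vapply(seq_along(nesting), function(i)
    paste(nesting[1:i], collapse = ":"), character(1))
  re <- if (diag)
    paste(sprintf("(1 | %s) + (0 + certainty | %s)", groups, groups),
          collapse = " + ")
  else paste(sprintf("(1 + certainty | %s)", groups), collapse = " + ")
  stats::as.formula(paste("log2snr ~", fixed, "+", re))
}

fit_ml <- function(formula, data) {
  ctrl <- lme4::lmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  lme4::lmer(formula, data = data, REML = FALSE, control = ctrl)
}

lrt <- function(full, reduced) {
  chi2 <- max(2 * (as.numeric(stats::logLik(full)) -
                     as.numeric(stats::logLik(reduced))), 0)
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Likelihood-ratio test of the certainty effect on log2(SNR)
#'
#' Fits full and reduced mixed models by maximum likelihood and compares
#' them with a likelihood-ratio test. Three levels of analysis:
#' * level 1 (one frequency): `log2snr ~ certainty` with random intercepts
#'   and certainty slopes for channel nested within participant;
#' * level 2 (one frequency category): random effects additionally nest
#'   frequency within channel within participant;
#' * level 3 (between categories): fixed effects
#'   `certainty * category`, random effects nest frequency within category
#'   within channel within participant; the tested term is the
#'   certainty-by-category interaction.
#'
#' Singular fits are refitted with diagonal random-effect covariances
#' (with a warning); non-convergence is an error.
#'
#' @param snr_tab tidy SNR table ([snr_table()] rows, with
#'   `certainty_bin`); only channels in `roi` are used.
#' @param level 1, 2 or 3.
#' @param frequency frequency in Hz selecting the rows (level 1).
#' @param category role selecting the rows (level 2): `"ssvep"`,
#'   `"swift"` or `"im"`.
#' @param categories roles entering a level-3 model (first is the
#'   reference).
#' @param predictor `"bin"` (certainty bin index 1-10, default) or
#'   `"proportion"` (`p_dominant`, requires a `p_dominant` column).
#' @param roi channels to keep (default: the 30-electrode posterior ROI).
#' @param re_cov `"full"` (correlated random intercepts/slopes, falling
#'   back to diagonal on singularity) or `"diag"` (diagonal covariance from
#'   the start; useful for small simulated sessions where the full
#'   structure is invariably singular).
#' @return an object of class `"lme_result"`: list with `level`, `term`,
#'   `estimate` (fixed certainty slope, per bin), `direction`
#'   (`"+"`, `"-"` or `"0"`), `chi2`, `df`, `p_raw`, `singular`, and the
#'   fitted `full` model.
#' @export
fit_certainty_effect <- function(snr_tab, level = 1L, frequency = NULL,
                                 category = NULL,
                                 categories = c("ssvep", "swift", "im"),
                                 predictor = c("bin", "proportion"),
                                 roi = posterior_roi(),
                                 re_cov = c("full", "diag")) {
  predictor <- match.arg(predictor)
  re_cov <- match.arg(re_cov)
  level <- as.integer(level)
  stopifnot(level %in% 1:3)
  if (any(snr_tab$snr <= 0)) stop("SNR values must be positive for log2")
  d <- restrict_roi(snr_tab, roi)
  if (level == 1L) {
    if (is.null(frequency)) stop("level 1 needs `frequency`")
    d <- d[abs(d$freq - frequency) < 1e-9, ]
    nesting <- c("participant", "channel")
    fixed_full <- "certainty"; fixed_red <- "1"; term <- "certainty"
  } else if (level == 2L) {
    if (is.null(category)) stop("level 2 needs `category`")
    d <- d[d$role == category, ]
    nesting <- c("participant", "channel", "freq_f")
    fixed_full <- "certainty"; fixed_red <- "1"; term <- "certainty"
  } else {
    d <- d[d$role %in% categories, ]
    d$category <- factor(d$role, levels = categories)
    nesting <- c("participant", "channel", "category", "freq_f")
    fixed_full <- "certainty * category"
    fixed_red <- "certainty + category"
    term <- "certainty:category"
  }
  if (nrow(d) == 0) stop("no data selected")
  d$certainty <- if (predictor == "bin") d$certainty_bin else d$p_dominant
  d$freq_f <- factor(d$freq)
  d$participant <- factor(d$participant)
  d$channel <- factor(d$channel)
  fit_pair <- function(diag) {
    full <- fit_ml(lme_formula(fixed_full, nesting, diag), d)
    red <- fit_ml(lme_formula(fixed_red, nesting, diag), d)
    list(full = full, red = red)
  }
  fits <- fit_pair(diag = re_cov == "diag")
  singular <- lme4::isSingular(fits$full)
  if (singular && re_cov == "full") {
    warning("singular random-effect fit; refitting with diagonal covariance")
    fits <- fit_pair(diag = TRUE)
  }
  fe <- lme4::fixef(fits$full)
  est <- if (level == 3L) {
    ix <- grep("^certainty:category", names(fe))
    fe[ix]
  } else unname(fe["certainty"])
  test <- lrt(fits$full, fits$red)
  dir_of <- function(e) if (abs(e) < 1e-12) "0" else if (e > 0) "+" else "-"
  structure(list(level = level, term = term,
                 frequency = frequency, category = category,
                 estimate = est,
                 direction = if (level == 3L)
                   vapply(est, dir_of, "", USE.NAMES = FALSE)
                 else dir_of(est),
                 chi2 = test$chi2, df = test$df, p_raw = test$p,
                 singular = singular, full = fits$full),
            class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat("<lme_result> level ", x$level, ", term ", x$term,
      if (!is.null(x$frequency)) paste0(" @ ", x$frequency, " Hz"),
      if (!is.null(x$category)) paste0(" [", x$category, "]"),
      ": direction ", paste(x$direction, collapse = "/"),
      ", chi2(", x$df, ") = ", sprintf("%.2f", x$chi2),
      ", p = ", format.pval(x$p_raw, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Per-frequency certainty-effect table with FDR adjustment
#'
#' Runs the level-1 likelihood-ratio test at each frequency of a tidy SNR
#' table and adjusts p-values across the tested family with
#' Benjamini-Hochberg.
#'
#' @inheritParams fit_certainty_effect
#' @param frequencies frequencies to test (default: all in `snr_tab`).
#' @return data.frame: freq, role, direction, estimate, chi2, df, p_raw,
#'   p_fdr.
#' @export
certainty_effect_table <- function(snr_tab, frequencies = NULL,
                                   predictor = c("bin", "proportion"),
                                   roi = posterior_roi(),
                                   re_cov = c("full", "diag")) {
  predictor <- match.arg(predictor)
  re_cov <- match.arg(re_cov)
  frequencies <- frequencies %||% sort(unique(snr_tab$freq))
  rows <- lapply(frequencies, function(f) {
    r <- fit_certainty_effect(snr_tab, level = 1L, frequency = f,
                              predictor = predictor, roi = roi,
                              re_cov = re_cov)
    data.frame(freq = f,
               role = snr_tab$role[match(TRUE, abs(snr_tab$freq - f) < 1e-9)],
               direction = r$direction, estimate = r$estimate,
               chi2 = r$chi2, df = r$df, p_raw = r$p_raw)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

#' Certainty-by-category interaction contrast
#'
#' Level-3 likelihood-ratio test of the certainty-by-category interaction
#' for one category against a reference (the canonical comparisons are IM
#' vs SSVEP and SWIFT vs SSVEP).
#'
#' @inheritParams fit_certainty_effect
#' @param category category whose certainty slope is contrasted.
#' @param reference reference category (default `"ssvep"`).
#' @return an `"lme_result"` (its `estimate`/`direction` refer to the slope
#'   difference `category - reference`).
#' @export
interaction_contrast <- function(snr_tab, category, reference = "ssvep",
                                 predictor = c("bin", "proportion"),
                                 roi = posterior_roi(),
                                 re_cov = c("full", "diag")) {
  fit_certainty_effect(snr_tab, level = 3L,
                       categories = c(reference, category),
                       predictor = match.arg(predictor), roi = roi,
                       re_cov = match.arg(re_cov))
}

#' Compare IM scalp-map correlations with SSVEP versus SWIFT
#'
#' For each IM component, the Pearson correlation across channels between
#' its mean-SNR scalp map and the SSVEP map is compared with the
#' correlation to the SWIFT map via Fisher's r-to-z transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))`, two-tailed p, FDR
#' across the IM components.
#'
#' @param snr_maps numeric matrix, channels x frequencies: mean SNR per
#'   channel, with column names.
#' @param ssvep_col,swift_col column names of the SSVEP and SWIFT maps.
#' @param im_cols column names of the IM maps (default: all remaining).
#' @return data.frame: im, r_im_ssvep, r_im_swift, z, p_raw, p_fdr.
#' @export
topo_correlation_compare <- function(snr_maps, ssvep_col = "ssvep",
                                     swift_col = "swift", im_cols = NULL) {
  stopifnot(is.matrix(snr_maps), !is.null(colnames(snr_maps)))
  n <- nrow(snr_maps)
  if (n < 4) stop("need at least 4 channels")
  im_cols <- im_cols %||% setdiff(colnames(snr_maps), c(ssvep_col, swift_col))
  if (any(apply(snr_maps[, c(ssvep_col, swift_col, im_cols)], 2,
                stats::sd) == 0))
    stop("zero-variance scalp map: correlation undefined")
  rows <- lapply(im_cols, function(cn) {
    r1 <- stats::cor(snr_maps[, cn], snr_maps[, ssvep_col])
    r2 <- stats::cor(snr_maps[, cn], snr_maps[, swift_col])
    z <- (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))
    data.frame(im = cn, r_im_ssvep = r1, r_im_swift = r2, z = z,
               p_raw = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out
}
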