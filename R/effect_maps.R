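#' Residualize regional measures on age and sex
#'
#' Per region, ordinary least squares of the measure on
#' \[1, age, sex\], fitted either on the pooled sample
#' (diagnosis-blind, the default) or on controls only; the adjusted
#' value is the residual plus the fit evaluated at the pooled mean age
#' and sex, which preserves the measure's scale. Group statistics on the
#' adjusted values are therefore free of additive age/sex effects.
#'
#' A covariate that is constant (e.g. a single-sex cohort) is dropped
#' from the design; if age and sex are both constant the design is
#' singular and an error is raised.
#'
#' @param table A [regional_table] with `age` and `sex` covariates.
#' @param adjustment `"pooled"` (fit on everyone) or `"controls_only"`
#'   (coefficients from controls, applied to everyone).
#' @return A list with `table` (the adjusted [regional_table]) and
#'   `model` (class `covariate_model`: per-region coefficients and the
#'   covariate means used for re-centering).
#' @export
residualize <- function(table, adjustment = c("pooled", "controls_only")) {
  stopifnot(inherits(table, "regional_table"))
  adjustment <- match.arg(adjustment)
  s <- table$subjects
  fit_rows <- if (adjustment == "pooled") seq_len(nrow(s)) else which(s$dx == 0)
  if (length(fit_rows) < 3L)
    stop("need at least 3 subjects to fit the covariate model")
  X <- cbind(intercept = 1, age = s$age, sex = s$sex)
  if (qr(X[fit_rows, , drop = FALSE])$rank < 2L)
    stop("singular covariate design: age and sex are both constant")
  fit <- stats::lm.fit(X[fit_rows, , drop = FALSE],
                       table$measures[fit_rows, , drop = FALSE])
  coefs <- fit$coefficients
  if (is.null(dim(coefs)))              # single-region table
    coefs <- matrix(coefs, ncol = 1L, dimnames = list(names(coefs), NULL))
  coefs[is.na(coefs)] <- 0              # aliased (constant) covariate
  mu <- c(1, mean(s$age), mean(s$sex))
  # adjusted = x - b_age (age - mean_age) - b_sex (sex - mean_sex)
  adj <- table$measures -
    outer(s$age - mu[2L], coefs["age", ]) -
    outer(s$sex - mu[3L], coefs["sex", ])
  model <- structure(list(
    coefficients = data.frame(region = table$region_ids,
                              intercept = coefs["intercept", ],
                              b_age = coefs["age", ],
                              b_sex = coefs["sex", ],
                              row.names = NULL),
    covariate_means = c(age = mu[2L], sex = mu[3L]),
    adjustment = adjustment), class = "covariate_model")
  list(table = regional_table(s, adj, measure_name = table$measure_name),
       model = model)
}

#' Per-region case-control Cohen's d map
#'
#' For every region, the standardized mean difference
#' \deqn{d_j = \frac{\bar x_{case} - \bar x_{control}}{s_{pooled}},
#'   \quad s_{pooled} = \sqrt{\frac{(n_1 - 1) s_1^2 + (n_2 - 1) s_2^2}
#'   {n_1 + n_2 - 2}},}
#' with the pooled two-sample t statistic and its two-sided p-value on
#' \eqn{n_1 + n_2 - 2} degrees of freedom. Negative d means a case
#' deficit (case - control convention). Regions where either group has
#' fewer than 2 values, or where the pooled SD is 0, yield NA/NaN with a
#' warning. Apply after [residualize] to obtain age/sex-adjusted maps.
#'
#' @param table A [regional_table] (normally the adjusted table).
#' @param hedges If `TRUE`, apply the small-sample (Hedges' g)
#'   correction factor; off by default.
#' @param measure_name,cohort_label Labels carried on the output.
#' @return An `effect_size_map`: a data frame with columns `region`,
#'   `d`, `t`, `p`, `n_case`, `n_control`.
#' @export
cohens_d_map <- function(table, hedges = FALSE,
                         measure_name = table$measure_name,
                         cohort_label = "") {
  stopifnot(inherits(table, "regional_table"))
  dx <- table$subjects$dx
  rows <- lapply(seq_along(table$region_ids), function(j) {
    x1 <- table$measures[dx == 1, j]; x1 <- x1[is.finite(x1)]
    x0 <- table$measures[dx == 0, j]; x0 <- x0[is.finite(x0)]
    n1 <- length(x1); n0 <- length(x0)
    out <- data.frame(region = table$region_ids[j],
                      d = NA_real_, t = NA_real_, p = NA_real_,
                      n_case = n1, n_control = n0,
                      stringsAsFactors = FALSE)
    if (n1 < 2L || n0 < 2L) {
      warning("region ", table$region_ids[j],
              " skipped: fewer than 2 subjects in a group")
      return(out)
    }
    sp <- sqrt(((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) /
                 (n1 + n0 - 2))
    if (sp == 0) {
      warning("region ", table$region_ids[j], ": pooled SD is 0")
      out$d <- NaN
      return(out)
    }
    d <- (mean(x1) - mean(x0)) / sp
    if (hedges) d <- d * (1 - 3 / (4 * (n1 + n0) - 9))
    tt <- (mean(x1) - mean(x0)) / (sp * sqrt(1 / n1 + 1 / n0))
    out$d <- d
    out$t <- tt
    out$p <- 2 * stats::pt(-abs(tt), df = n1 + n0 - 2)
    out
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("effect_size_map", "data.frame"),
            measure_name = measure_name, cohort_label = cohort_label)
}

#' Summarize an effect-size map
#'
#' Mean and sample SD of d across regions, plus regions ranked by |d|.
#'
#' @param map An `effect_size_map` (or a data frame with `region`, `d`).
#' @param top How many extreme regions to list.
#' @return List with `mean_d`, `sd_d`, `n_regions` and `extremes` (a
#'   data frame ranked by descending |d|).
#' @export
summarize_map <- function(map, top = 5L) {
  ok <- is.finite(map$d)
  if (!any(ok)) stop("no finite effect sizes in map")
  if (sum(ok) < 2L) stop("need at least 2 regions with finite d to form an SD")
  d <- map$d[ok]
  ord <- order(-abs(d))
  list(mean_d = mean(d), sd_d = stats::sd(d), n_regions = sum(ok),
       extremes = data.frame(region = map$region[ok][ord],
                             d = d[ord])[seq_len(min(top, sum(ok))), ])
}

#' Flag regions significant after multiple-comparison correction
#'
#' Bonferroni by default: significant iff `p < alpha / R`, where R is
#' the number of regions with a p-value in the map (never hard-coded).
#' Benjamini-Hochberg FDR is available as an alternative.
#'
#' @param map An `effect_size_map`.
#' @param alpha Family-wise (or FDR) level.
#' @param method `"bonferroni"` or `"fdr"`.
#' @return The map with a logical `significant_bonferroni` column
#'   (named `significant_fdr` for the FDR method).
#' @export
flag_significant <- function(map, alpha = 0.05,
                             method = c("bonferroni", "fdr")) {
  method <- match.arg(method)
  ok <- is.finite(map$p)
  R <- sum(ok)
  if (R < 1L) stop("map has no usable p-values")
  if (method == "bonferroni") {
    map$significant_bonferroni <- ok & map$p < alpha / R
  } else {
    padj <- rep(NA_real_, nrow(map))
    padj[ok] <- stats::p.adjust(map$p[ok], method = "BH")
    map$significant_fdr <- ok & padj < alpha
  }
  map
}

#' Write / read an effect-size map as TSV
#'
#' @param map An `effect_size_map`.
#' @param path File path.
#' @return `read_effect_map_tsv` returns an `effect_size_map`.
#' @export
write_effect_map_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_effect_map_tsv
#' @export
read_effect_map_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df, class = c("effect_size_map", "data.frame"))
}
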