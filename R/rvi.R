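#' Control reference for z-scoring regional measures
#'
#' Per-region mean and sample SD computed from controls only (the
#' healthy norm against which individual deviations are measured).
#' Regions with zero control SD cannot be z-scored and are excluded
#' with a warning.
#'
#' @param table A [regional_table], normally age/sex-adjusted via
#'   [residualize].
#' @return A `control_reference`: list with `region`, `mu`, `sigma`.
#' @export
build_control_reference <- function(table) {
  stopifnot(inherits(table, "regional_table"))
  ctrl <- table$measures[table$subjects$dx == 0, , drop = FALSE]
  if (nrow(ctrl) < 2L) stop("need at least 2 controls")
  mu <- colMeans(ctrl)
  sigma <- apply(ctrl, 2L, stats::sd)
  bad <- which(sigma == 0 | !is.finite(sigma))
  if (length(bad)) {
    warning("excluding region(s) with degenerate control SD: ",
            paste(table$region_ids[bad], collapse = ", "))
    mu <- mu[-bad]; sigma <- sigma[-bad]
  }
  if (!length(mu)) stop("no scorable regions")
  structure(list(region = names(mu), mu = unname(mu), sigma = unname(sigma)),
            class = "control_reference")
}

#' Z-score subjects against a control reference
#'
#' \eqn{z_{ij} = (x_{ij} - \mu_j) / \sigma_j} using the control-derived
#' reference; when the reference is built from the same controls, their
#' column means are 0 and column SDs 1 by construction.
#'
#' @param table A [regional_table].
#' @param reference A `control_reference`.
#' @return Numeric subjects x regions matrix of z-scores, with
#'   `subject_id` row names.
#' @export
zscore_subjects <- function(table, reference) {
  stopifnot(inherits(table, "regional_table"),
            inherits(reference, "control_reference"))
  miss <- setdiff(reference$region, table$region_ids)
  if (length(miss))
    stop("reference region(s) absent from table: ",
         paste(miss, collapse = ", "))
  x <- table$measures[, reference$region, drop = FALSE]
  z <- sweep(sweep(x, 2L, reference$mu), 2L, reference$sigma, "/")
  rownames(z) <- table$subjects$subject_id
  z
}

#' Regional Vulnerability Index scores
#'
#' Per subject, the Pearson correlation across regions between the
#' subject's control-referenced z-deviation profile and a template
#' effect-size pattern (case - control d, deficits negative). A subject
#' expressing the deficit pattern has negative deviations where the
#' template is negative and therefore a positive RVI. RVI is invariant
#' to positive affine rescaling of the template and flips sign when the
#' template is negated. Region matching is by name after canonical
#' lowercase/underscore normalization.
#'
#' @param z Subjects x regions z-score matrix from [zscore_subjects].
#' @param template Named numeric vector of per-region template effect
#'   sizes (>= 3 regions, nonzero variance).
#' @param method Similarity kernel: `"pearson"` (default),
#'   `"spearman"`, or `"cosine"`.
#' @return Data frame with `subject_id` and `rvi`; subjects with zero
#'   z-variance get `NaN` with a warning.
#' @export
rvi_scores <- function(z, template, method = c("pearson", "spearman", "cosine")) {
  method <- match.arg(method)
  if (is.null(names(template))) stop("template must be a named vector")
  if (length(template) < 3L) stop("template needs at least 3 regions")
  if (!all(is.finite(template))) stop("template must be finite")
  if (stats::sd(template) == 0) stop("template has zero variance")
  tcanon <- canonical_region_name(names(template))
  zcanon <- canonical_region_name(colnames(z))
  miss <- setdiff(tcanon, zcanon)
  if (length(miss))
    stop("template region(s) not present in the z matrix: ",
         paste(miss, collapse = ", "))
  zt <- z[, match(tcanon, zcanon), drop = FALSE]
  d <- as.numeric(template)
  scores <- vapply(seq_len(nrow(zt)), function(i) {
    zi <- zt[i, ]
    if (any(!is.finite(zi))) return(NaN)
    switch(method,
           pearson = if (stats::sd(zi) == 0) NaN else stats::cor(zi, d),
           spearman = if (stats::sd(zi) == 0) NaN
                      else stats::cor(zi, d, method = "spearman"),
           cosine = {
             nz <- sqrt(sum(zi^2))
             if (nz == 0) NaN else sum(zi * d) / (nz * sqrt(sum(d^2)))
           })
  }, numeric(1L))
  if (anyNA(scores))
    warning(sum(is.na(scores)), " subject(s) with degenerate profiles scored NaN")
  data.frame(subject_id = rownames(zt) %||% seq_len(nrow(zt)),
             rvi = scores, stringsAsFactors = FALSE)
}

#' RVI case-control contrast
#'
#' Pooled-SD Cohen's d (case - control) of RVI scores, with the pooled
#' two-sample t statistic and two-sided p-value.
#'
#' @param rvi Numeric RVI scores (or the data frame from [rvi_scores]).
#' @param dx 0/1 diagnosis labels aligned with the scores.
#' @return List with `cohen_d`, `t`, `p`, `n_case`, `n_control`.
#' @export
rvi_group_contrast <- function(rvi, dx) {
  if (is.data.frame(rvi)) rvi <- rvi$rvi
  x1 <- rvi[dx == 1]; x1 <- x1[is.finite(x1)]
  x0 <- rvi[dx == 0]; x0 <- x0[is.finite(x0)]
  n1 <- length(x1); n0 <- length(x0)
  if (n1 < 2L || n0 < 2L)
    stop("need at least 2 usable scores per group (", n1, " cases, ",
         n0, " controls)")
  sp <- sqrt(((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) /
               (n1 + n0 - 2))
  if (sp == 0) stop("degenerate groups: pooled SD is 0")
  tt <- (mean(x1) - mean(x0)) / (sp * sqrt(1 / n1 + 1 / n0))
  list(cohen_d = (mean(x1) - mean(x0)) / sp, t = tt,
       p = 2 * stats::pt(-abs(tt), df = n1 + n0 - 2),
       n_case = n1, n_control = n0)
}

#' RVI-symptom severity association
#'
#' Pearson correlation between RVI scores and a symptom-severity rating
#' over subjects with both values (controls without ratings are
#' excluded); p-value from the standard t transform of r.
#'
#' @param rvi Numeric RVI scores (or the data frame from [rvi_scores]).
#' @param severity Severity ratings aligned with the scores (NA where
#'   not rated).
#' @return List with `pearson_r`, `p`, `n`.
#' @export
rvi_symptom_association <- function(rvi, severity) {
  if (is.data.frame(rvi)) rvi <- rvi$rvi
  ok <- is.finite(rvi) & is.finite(severity)
  if (sum(ok) < 4L)
    stop("need at least 4 subjects with both RVI and severity (got ",
         sum(ok), ")")
  ct <- stats::cor.test(rvi[ok], severity[ok], method = "pearson")
  list(pearson_r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
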