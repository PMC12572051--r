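# Effect-heterogeneity screening: squared semi-partial correlations of
# individual-level effect estimates with each covariate, and stratified
# subgroup ATEs.

# R^2 of a least-squares fit (intercept added), via QR with aliased
# columns dropped
ols_r2 <- function(X, y) {
  X <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(X)
  keep <- qr_x$pivot[seq_len(qr_x$rank)]
  fit <- stats::lm.fit(X[, keep, drop = FALSE], y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  1 - sum(fit$residuals^2) / tss
}

#' Squared semi-partial correlations of individual effects
#'
#' For each covariate j, SPC^2_j = R^2(effects ~ all covariates) -
#' R^2(effects ~ all covariates except j): the share of independent
#' variation in the individual-level effects attributable to j given the
#' others. Aliased (perfectly collinear) columns are dropped from the
#' full fit (logged) and report SPC^2 = 0.
#'
#' @param effects numeric vector of individual-level effects (as from
#'   \code{\link{individual_effects}}).
#' @param X numeric matrix or data.table of covariates (n rows).
#' @return data.table (covariate, spc2), sorted by descending SPC^2,
#'   ties broken by covariate name.
#' @export
spc2 <- function(effects, X) {
  X <- as.matrix(X)
  if (nrow(X) != length(effects)) {
    abort_fmt("effects and X disagree on n (%d vs %d)",
              length(effects), nrow(X))
  }
  if (nrow(X) <= ncol(X) + 1L) {
    abort_fmt("need n > p + 1 for the linear screens")
  }
  qr_full <- qr(cbind(1, X))
  aliased <- integer(0)
  if (qr_full$rank < ncol(X) + 1L) {
    keep <- sort(qr_full$pivot[seq_len(qr_full$rank)])
    aliased <- setdiff(seq_len(ncol(X) + 1L), keep) - 1L
    aliased <- aliased[aliased > 0L]
    message(sprintf("spc2: dropping %d aliased column(s): %s",
                    length(aliased),
                    paste(colnames(X)[aliased], collapse = ", ")))
  }
  use <- setdiff(seq_len(ncol(X)), aliased)
  r2_full <- ols_r2(X[, use, drop = FALSE], effects)
  vals <- vapply(seq_len(ncol(X)), function(j) {
    if (j %in% aliased) return(0)
    rest <- setdiff(use, j)
    r2_red <- ols_r2(X[, rest, drop = FALSE], effects)
    max(0, min(1, r2_full - r2_red))
  }, numeric(1))
  out <- data.table::data.table(covariate = colnames(X), spc2 = vals)
  data.table::setorderv(out, c("spc2", "covariate"), order = c(-1L, 1L))
  out[]
}

#' Stratified subgroup ATEs
#'
#' Computes subgroup estimates per stratum of pre-treatment variables:
#' by default gender (female vs male), being single, and education above
#' vs at-or-below the sample median years of education.
#'
#' @param ate a \code{shockdml_ate} from \code{\link{ddml_ate}}.
#' @param sample the \code{shockdml_sample} the estimate was computed on.
#' @param strata named list mapping a stratification name to a function
#'   of the sample returning a logical mask for the "high"/"yes" level;
#'   both the mask and its complement are reported.
#' @param education_cut years-of-education cut for the default education
#'   split (default: sample median).
#' @return data.table (stratification, stratum, n, estimate, se,
#'   ci_lower, ci_upper).
#' @export
stratified_effects <- function(ate, sample, strata = NULL,
                               education_cut = NULL) {
  if (is.null(strata)) {
    if (is.null(education_cut)) {
      education_cut <- median(sample$education_years)
    }
    strata <- list(
      gender = list(yes = "female", mask = sample$female == 1,
                    labels = c("female", "male")),
      single = list(mask = sample$single == 1,
                    labels = c("single", "not single")),
      education = list(mask = sample$education_years > education_cut,
                       labels = c("high education", "low education"))
    )
  }
  rows <- list()
  for (nm in names(strata)) {
    st <- strata[[nm]]
    mask <- if (is.list(st)) st$mask else st
    labels <- if (is.list(st) && !is.null(st$labels)) {
      st$labels
    } else {
      c(paste0(nm, ": yes"), paste0(nm, ": no"))
    }
    for (i in 1:2) {
      m <- if (i == 1) mask else !mask
      if (!any(m)) abort_fmt("stratum '%s' is empty", labels[i])
      est <- subgroup_ate(ate, m)
      rows[[paste(nm, i)]] <- data.table::data.table(
        stratification = nm, stratum = labels[i], n = sum(m),
        estimate = est$estimate, se = est$se,
        ci_lower = est$ci_lower, ci_upper = est$ci_upper)
    }
  }
  data.table::rbindlist(rows)
}
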