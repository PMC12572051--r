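# Health-shock definition: an indicator that a component summary score
# fell by more than `threshold` (default 25%) relative to its level two
# years earlier. Indicators are only defined where both scores are
# observed and the baseline score is positive; missingness propagates to
# "undefined", never to 0.

score_column <- function(domain) {
  switch(domain, physical = "pcs", mental = "mcs",
         abort_fmt("unknown domain '%s' (use 'physical' or 'mental')", domain))
}

as_panel_dt <- function(panel) {
  if (inherits(panel, "shockdml_panel")) return(panel$panel)
  data.table::as.data.table(panel)
}

#' Flag a health shock from a score pair
#'
#' Returns 1 when the current score lies more than \code{threshold} below
#' the score two years earlier, i.e. \code{(curr - prev)/prev < -threshold}
#' (strict: a drop of exactly 25% is not a shock). Pairs with missing
#' values or a non-positive baseline are non-computable and yield
#' \code{NA}.
#'
#' @param prev score two years before the reference year (must be > 0 for
#'   the indicator to be defined).
#' @param curr score at the reference year.
#' @param threshold relative-drop threshold in (0, 1); default 0.25.
#' @return integer vector of 0/1/NA, vectorized over inputs.
#' @export
flag_shock <- function(prev, curr, threshold = 0.25) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (threshold <= 0 || threshold >= 1) {
    abort_fmt("threshold must lie in (0, 1), got %g", threshold)
  }
  out <- ifelse(!is.na(prev) & !is.na(curr) & prev > 0,
                as.integer((curr - prev) / prev < -threshold),
                NA_integer_)
  as.integer(out)
}

#' Shock indicators for every consecutive score-wave pair of a panel
#'
#' @param panel a \code{shockdml_panel} or its long panel data.table.
#' @param domain "physical" (PCS) or "mental" (MCS).
#' @param threshold relative-drop threshold; default 0.25.
#' @return data.table (id, year, domain, shock) with one row per
#'   computable (id, reference year) pair; non-computable pairs (missing
#'   score, non-positive baseline) are absent, not 0.
#' @export
flag_panel_shocks <- function(panel, domain, threshold = 0.25) {
  dt <- as_panel_dt(panel)
  col <- score_column(domain)
  sc <- dt[, c("id", "year", col), with = FALSE]
  data.table::setnames(sc, col, "score")
  waves <- sort(unique(sc$year[!is.na(sc$score)]))
  pairs <- waves[c(FALSE, diff(waves) == 2)]
  if (!length(pairs)) {
    warning("panel contains no consecutive score-wave pairs")
    return(data.table::data.table(id = integer(), year = integer(),
                                  domain = character(), shock = integer()))
  }
  sc <- sc[sc$year %in% waves, ]
  data.table::setorderv(sc, c("id", "year"))
  sc[, `:=`(score_prev = data.table::shift(score),
            year_prev = data.table::shift(year)), by = id]
  out <- sc[sc$year %in% pairs & !is.na(sc$year_prev) &
              sc$year_prev == sc$year - 2L, ]
  out[, shock := flag_shock(score_prev, score, threshold)]
  out <- out[!is.na(out$shock), c("id", "year", "shock"), with = FALSE]
  out$domain <- domain
  data.table::setcolorder(out, c("id", "year", "domain", "shock"))
  out[]
}

#' Distribution of per-individual shock counts
#'
#' Counts, for each individual with at least one computable indicator,
#' how many shocks they experienced over the observed score waves, and
#' tabulates the distribution (repeated-shock descriptive).
#'
#' @inheritParams flag_panel_shocks
#' @return data.table (shocks, n_individuals); the n column sums to the
#'   number of individuals with >= 1 computable pair.
#' @export
repeated_shock_counts <- function(panel, domain, threshold = 0.25) {
  ind <- flag_panel_shocks(panel, domain, threshold)
  if (!nrow(ind)) {
    return(data.table::data.table(shocks = integer(),
                                  n_individuals = integer()))
  }
  per_id <- ind[, list(count = sum(shock)), by = id]
  tab <- per_id[, list(n_individuals = .N), by = list(shocks = count)]
  data.table::setorderv(tab, "shocks")
  tab[]
}

#' Correlation between physical and mental shock indicators
#'
#' Pearson correlation of the two binary indicators over the (id, year)
#' cells where both are computable.
#'
#' @inheritParams flag_panel_shocks
#' @return a single number, or \code{NA} (with a warning) when either
#'   indicator has zero variance on the common cells.
#' @export
shock_correlation <- function(panel, threshold = 0.25) {
  phys <- flag_panel_shocks(panel, "physical", threshold)
  ment <- flag_panel_shocks(panel, "mental", threshold)
  joint <- merge(phys[, c("id", "year", "shock"), with = FALSE],
                 ment[, c("id", "year", "shock"), with = FALSE],
                 by = c("id", "year"), suffixes = c("_phys", "_ment"))
  if (!nrow(joint)) {
    warning("no common computable cells between the two domains")
    return(NA_real_)
  }
  x <- joint$shock_phys
  y <- joint$shock_ment
  if (var(x) == 0 || var(y) == 0) {
    warning("an indicator has zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}
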