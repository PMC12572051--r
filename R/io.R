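# Plain-text persistence: panels, truth tables and samples as CSV
# (header row, UTF-8, "." decimal), configurations as JSON, manifests as
# key-value text. Every artifact records the seed and a config hash.

#' Write a synthetic panel (and its ground truth) to a directory
#'
#' Writes \code{panel.csv}, \code{truth.csv}, \code{config.json} and a
#' \code{manifest.txt} with the seed, row counts and a config hash.
#'
#' @param sim a \code{shockdml_panel}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_panel <- function(sim, dir) {
  stopifnot(inherits(sim, "shockdml_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(sim$panel, file.path(dir, "panel.csv"))
  data.table::fwrite(sim$truth, file.path(dir, "truth.csv"))
  cfg_file <- file.path(dir, "config.json")
  write_config(sim$config, cfg_file)
  manifest <- c(
    sprintf("config_hash: %s", unname(tools::md5sum(cfg_file))),
    sprintf("seed: %d", sim$seed),
    sprintf("panel_rows: %d", nrow(sim$panel)),
    sprintf("truth_rows: %d", nrow(sim$truth)),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("shockdml"))))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a panel written by \code{\link{write_panel}}
#' @param dir directory containing panel.csv / truth.csv / config.json.
#' @return a \code{shockdml_panel}.
#' @export
read_panel <- function(dir) {
  panel <- data.table::fread(file.path(dir, "panel.csv"))
  truth <- data.table::fread(file.path(dir, "truth.csv"))
  cfg <- read_config(file.path(dir, "config.json"))
  manifest <- readLines(file.path(dir, "manifest.txt"))
  seed_line <- grep("^seed:", manifest, value = TRUE)
  out <- list(panel = panel, truth = truth, config = cfg,
              seed = as.integer(sub("^seed: ", "", seed_line)))
  class(out) <- "shockdml_panel"
  out
}

write_config <- function(cfg, path) {
  ser <- unclass(cfg)
  ser$effect_profile <- as.data.frame(ser$effect_profile)
  # named atomic vectors must become objects, not nameless arrays
  for (nm in c("latent_persistence", "drop_hazard_intercept",
               "baseline_prevalence", "outcome_intercepts",
               "state_dependence", "confounding_weights")) {
    ser[[nm]] <- as.list(ser[[nm]])
  }
  ser$outcome_coefficients <- lapply(ser$outcome_coefficients, as.list)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$effect_profile <- data.table::as.data.table(raw$effect_profile)
  if (!nrow(raw$effect_profile)) {
    raw$effect_profile <- default_effect_profile()[0]
  }
  for (nm in c("latent_persistence", "drop_hazard_intercept",
               "baseline_prevalence", "outcome_intercepts",
               "state_dependence", "confounding_weights")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  raw$outcome_coefficients <- lapply(raw$outcome_coefficients, unlist)
  cfg <- raw[names(raw) != ""]
  class(cfg) <- "shockdml_config"
  validate_config(cfg)
  cfg
}

#' Write an estimation sample with a manifest
#'
#' @param sample a \code{shockdml_sample}.
#' @param path CSV file path; a "<path>.manifest.txt" is written next to
#'   it recording timing, threshold and counts.
#' @return \code{path}, invisibly.
#' @export
write_sample <- function(sample, path) {
  data.table::fwrite(sample, path)
  tm <- attr(sample, "timing")
  manifest <- c(
    sprintf("outcome: %s", tm$outcome),
    sprintf("domain: %s", tm$domain),
    sprintf("reference_year: %d", tm$reference_year),
    sprintf("lag: %d", tm$lag),
    sprintf("covariate_mode: %s", tm$covariate_mode),
    sprintf("placebo: %s", tm$placebo),
    sprintf("threshold: %g", attr(sample, "threshold")),
    sprintf("rows: %d", nrow(sample)),
    sprintf("treated: %d", sum(sample$treated)))
  writeLines(manifest, paste0(path, ".manifest.txt"))
  invisible(path)
}

# flat results row for one ATE estimate
ate_row <- function(est, extra = list()) {
  tm <- est$timing
  base <- data.table::data.table(
    outcome = tm$outcome %||% NA_character_,
    domain = tm$domain %||% NA_character_,
    lag = tm$lag %||% NA_integer_,
    estimate = est$estimate, se = est$se,
    ci_lower = est$ci_lower, ci_upper = est$ci_upper,
    n = est$n, n_treated = est$n_treated,
    learner = est$learner, K = est$K, R = est$R, seed = est$seed)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}
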