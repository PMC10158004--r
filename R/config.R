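#' Pipeline run configuration
#'
#' Thresholds and policies shared by every stage.  Defaults follow the
#' published cutoffs of the workflow this package implements:
#' VIP > 1, fold change > 2 or < 0.5, adjusted P < 0.05 for differential
#' calling; |r| > 0.2 with adjusted P < 0.05 for correlation edges.
#'
#' @param vip_min minimum VIP retained in differential calls (default 1).
#' @param fc_up,fc_down fold-change cutoffs, linear scale: up-regulated
#'   above `fc_up` (default 2), down-regulated below `fc_down`
#'   (default 0.5); must satisfy `fc_up > 1 > fc_down > 0`.
#' @param q_max maximum Benjamini-Hochberg adjusted p (default 0.05).
#' @param r_min minimum |Spearman r| for a retained correlation edge
#'   (default 0.2).
#' @param enrich_q_max adjusted-p cutoff declaring a pathway enriched
#'   (default 0.05).
#' @param string_conf_min minimum interaction confidence on the 0-1000
#'   combined-score scale (default 400, "medium confidence").
#' @param key_target_rule `"median_all"` (all three centralities at or
#'   above their medians), `"median_any"`, or `"top_frac:x"`.
#' @param median_multiplier multiplier applied to the median thresholds of
#'   the key-target rule (default 1).
#' @param seed non-negative integer seeding all randomness downstream.
#' @return A validated list of class `sf_config`.
#' @export
sf_config <- function(vip_min = 1, fc_up = 2, fc_down = 0.5, q_max = 0.05,
                      r_min = 0.2, enrich_q_max = 0.05, string_conf_min = 400,
                      key_target_rule = "median_all", median_multiplier = 1,
                      seed = 0) {
  cfg <- list(vip_min = vip_min, fc_up = fc_up, fc_down = fc_down,
              q_max = q_max, r_min = r_min, enrich_q_max = enrich_q_max,
              string_conf_min = string_conf_min,
              key_target_rule = key_target_rule,
              median_multiplier = median_multiplier, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "sf_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, key, why) if (!ok) stop("invalid config key `", key, "`: ", why)
  num1 <- function(key) {
    v <- cfg[[key]]
    chk(is.numeric(v) && length(v) == 1 && is.finite(v), key, "must be a finite number")
    v
  }
  chk(num1("fc_up") > 1, "fc_up", "must exceed 1")
  chk(num1("fc_down") > 0 && cfg$fc_down < 1, "fc_down", "must lie in (0, 1)")
  chk(num1("q_max") > 0 && cfg$q_max < 1, "q_max", "must lie in (0, 1)")
  chk(num1("enrich_q_max") > 0 && cfg$enrich_q_max < 1, "enrich_q_max", "must lie in (0, 1)")
  chk(num1("r_min") >= 0 && cfg$r_min < 1, "r_min", "must lie in [0, 1)")
  chk(num1("vip_min") >= 0, "vip_min", "must be non-negative")
  chk(num1("string_conf_min") >= 0, "string_conf_min", "must be non-negative")
  chk(num1("median_multiplier") > 0, "median_multiplier", "must be positive")
  chk(num1("seed") >= 0 && cfg$seed == round(cfg$seed), "seed",
      "must be a non-negative integer")
  rule <- cfg$key_target_rule
  chk(is.character(rule) && length(rule) == 1 &&
        (rule %in% c("median_all", "median_any") || grepl("^top_frac:", rule)),
      "key_target_rule", "must be 'median_all', 'median_any' or 'top_frac:x'")
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Absent keys take their [sf_config()] defaults; unknown keys are an
#' error, as are violated invariants (the offending key is named).
#'
#' @param path YAML file of `key: value` pairs; an empty file yields the
#'   full default configuration.
#' @return An `sf_config`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(sf_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(sf_config, vals)
}

#' Write the effective configuration next to an output directory
#'
#' @param cfg an `sf_config`.
#' @param path output YAML file.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sf_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.sf_config <- function(x, ...) {
  cat("sf_config:\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable small-integer sub-seeds derived from a master seed (< 2^31).
sub_seed <- function(seed, offset) (as.numeric(seed) * 1000 + offset) %% 2147483647
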