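#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive their mean
#' rank). Thin, validating wrapper around `stats::cor`.
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return rho in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input vector")
  }
  stats::cor(x, y, method = "spearman")
}

#' Read a lifetime table
#'
#' @param path CSV with columns `protein_id`, `tau_ns` and optionally
#'   `source` (e.g. `"in_vitro"` or `"in_cell"`).
#' @return Validated data.frame.
#' @export
read_lifetime_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_lifetime_table(df)
}

validate_lifetime_table <- function(df) {
  stopifnot(all(c("protein_id", "tau_ns") %in% names(df)))
  if (is.null(df$source)) df$source <- "unknown"
  if (anyDuplicated(df$protein_id)) stop("duplicate protein ids in lifetime table")
  if (any(!is.finite(df$tau_ns)) || any(df$tau_ns <= 0)) {
    stop("lifetimes must be finite and > 0")
  }
  df
}

descriptor_columns <- function() {
  c("volume_A3", "area_A2", "hydropathy", "sasa_A2", "dipole_eA")
}

# properties table -> list(D = array[protein, model] per descriptor,
# tau, proteins); shared by correlation and bootstrap
align_properties <- function(properties, lifetimes, descriptors) {
  lifetimes <- validate_lifetime_table(lifetimes)
  common <- intersect(unique(properties$protein_id), lifetimes$protein_id)
  missing <- setdiff(unique(properties$protein_id), lifetimes$protein_id)
  if (length(missing)) {
    warning("dropping protein(s) without lifetimes: ",
            paste(missing, collapse = ", "))
  }
  if (length(common) < 3) {
    stop("need >= 3 proteins present in both tables, got ", length(common))
  }
  props <- properties[properties$protein_id %in% common, , drop = FALSE]
  counts <- table(props$protein_id)
  if (length(unique(counts)) != 1) {
    stop("all proteins must have the same model count; got ",
         paste(sort(unique(counts)), collapse = ", "))
  }
  n_mod <- unique(props$model)
  mats <- lapply(descriptors, function(d) {
    m <- matrix(NA_real_, length(common), length(n_mod),
                dimnames = list(common, n_mod))
    m[cbind(match(props$protein_id, common), match(props$model, n_mod))] <-
      props[[d]]
    m
  })
  names(mats) <- descriptors
  tau <- lifetimes$tau_ns[match(common, lifetimes$protein_id)]
  list(D = mats, tau = tau, proteins = common, n_models = length(n_mod))
}

#' Correlate pocket descriptors with lifetimes across predicted models
#'
#' For each descriptor and each model index m, computes Spearman's rho
#' between the descriptor values of all proteins at model m and the
#' measured lifetimes, then summarises rho over models (mean and sd).
#' Structure predictors emit several models per protein; correlating per
#' model index and averaging captures the spread those replicate
#' predictions induce in the correlation estimate.
#'
#' @param properties data.frame with columns `protein_id`, `model` and the
#'   descriptor columns (see [compute_all_properties()]).
#' @param lifetimes data.frame `protein_id`, `tau_ns` (see
#'   [read_lifetime_table()]).
#' @param descriptors which descriptor columns to analyse.
#' @return data.frame: `descriptor`, `rho_mean`, `rho_sd`, `n_proteins`,
#'   `n_models`, plus a `rho_per_model` list column.
#' @export
correlate_over_models <- function(properties, lifetimes,
                                  descriptors = descriptor_columns()) {
  al <- align_properties(properties, lifetimes, descriptors)
  rows <- lapply(descriptors, function(d) {
    rhos <- apply(al$D[[d]], 2, function(v) spearman(v, al$tau))
    data.frame(descriptor = d, rho_mean = mean(rhos),
               rho_sd = if (length(rhos) > 1) stats::sd(rhos) else 0,
               n_proteins = length(al$proteins), n_models = al$n_models,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rho_per_model <- lapply(descriptors, function(d) {
    unname(apply(al$D[[d]], 2, function(v) spearman(v, al$tau)))
  })
  rownames(out) <- NULL
  out
}

#' Bootstrap significance of a descriptor-lifetime correlation
#'
#' Case-resampling bootstrap with the protein as the exchangeable unit:
#' each replicate resamples proteins with replacement and draws one model
#' index uniformly per resampled protein, then computes Spearman's rho.
#' The 95% percentile interval of the replicate distribution gives the
#' confidence interval; the correlation is flagged significant when the
#' interval excludes zero. Replicates with a constant descriptor or
#' lifetime vector are discarded and counted; more than 50% discarded is
#' an error.
#'
#' @param properties,lifetimes as in [correlate_over_models()].
#' @param descriptor single descriptor column name.
#' @param n_boot number of bootstrap replicates (>= 1000).
#' @param seed RNG seed (required, for reproducibility).
#' @param conf confidence level.
#' @return list with `ci_lo`, `ci_hi`, `significant`, `n_discarded`,
#'   `n_boot`, `seed`, `replicates`.
#' @export
bootstrap_significance <- function(properties, lifetimes, descriptor,
                                   n_boot = 10000, seed, conf = 0.95) {
  if (n_boot < 1000) stop("n_boot must be >= 1000")
  al <- align_properties(properties, lifetimes, descriptor)
  D <- al$D[[descriptor]]
  n <- length(al$proteins)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  mod <- matrix(sample.int(al$n_models, n * n_boot, replace = TRUE), n_boot, n)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    x <- D[cbind(idx[b, ], mod[b, ])]
    y <- al$tau[idx[b, ]]
    reps[b] <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y, method = "spearman")
  }
  n_disc <- sum(is.na(reps))
  if (n_disc > n_boot / 2) {
    stop("more than 50% of bootstrap replicates degenerate (", n_disc, "/",
         n_boot, ")")
  }
  ci <- unname(stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                               na.rm = TRUE, type = 7))
  list(ci_lo = ci[1], ci_hi = ci[2],
       significant = ci[1] > 0 || ci[2] < 0,
       n_discarded = n_disc, n_boot = n_boot, seed = seed,
       replicates = reps)
}

#' Full correlation report: per-model Spearman summary plus bootstrap CI
#'
#' @inheritParams bootstrap_significance
#' @param descriptors descriptor columns to report.
#' @return data.frame: `descriptor`, `rho_mean`, `rho_sd`, `ci_lo`, `ci_hi`,
#'   `significant`, `n_proteins`, `n_models`, `n_boot`, `seed`.
#' @export
correlation_report <- function(properties, lifetimes,
                               descriptors = descriptor_columns(),
                               n_boot = 10000, seed = 1) {
  base <- correlate_over_models(properties, lifetimes, descriptors)
  base$rho_per_model <- NULL
  boots <- lapply(seq_along(descriptors), function(i) {
    b <- bootstrap_significance(properties, lifetimes, descriptors[i],
                                n_boot = n_boot, seed = seed + i - 1)
    data.frame(ci_lo = b$ci_lo, ci_hi = b$ci_hi, significant = b$significant)
  })
  out <- cbind(base[, c("descriptor", "rho_mean", "rho_sd")],
               do.call(rbind, boots),
               base[, c("n_proteins", "n_models")],
               n_boot = n_boot, seed = seed)
  rownames(out) <- NULL
  out
}
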