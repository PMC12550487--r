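## Community-scale biocontrol indicator: the abundance-weighted sum of
## species-level daily predation rates on a prey,
##   lambda_com,p = sum_c lambda_c,p * A_c,
## propagated through the joint posterior, and the digestion-uncorrected
## "rough" comparator built from raw detection frequencies.

#' Community-scale biocontrol indicator
#'
#' For each posterior draw, sums the daily predation rates of all species
#' in the abundance table, weighted by their abundance (activity-density).
#' Draws are taken jointly — one full posterior vector per draw — so
#' cross-species posterior correlation is preserved. Predation rates are
#' held constant across communities; seasonal variation enters only
#' through the abundance table.
#'
#' @param fit a `predation_fit`.
#' @param abundance data frame with columns `community`, `species`,
#'   `abundance`. Every species must be registered in the fit.
#' @param prey prey label(s) to evaluate; defaults to all fitted prey.
#' @param n_draws number of posterior vectors used (100 by default).
#' @param seed optional seed for the draw subsample.
#' @return List with `draws` (data frame: `community`, `prey`, `draw`,
#'   `value` in prey per day) and `summary` (per community x prey: mean,
#'   sd, median and quantiles, lower-interpolation convention).
#' @export
biocontrol_indicator <- function(fit, abundance, prey = NULL, n_draws = 100,
                                 seed = NULL) {
  validate_abundance(abundance)
  if (is.null(prey)) prey <- fit$prey
  unknown_prey <- setdiff(prey, fit$prey)
  if (length(unknown_prey)) {
    stop("prey not in the fit: ", paste(unknown_prey, collapse = ", "),
         call. = FALSE)
  }
  unknown_sp <- setdiff(unique(abundance$species), fit$predators)
  if (length(unknown_sp)) {
    stop("species never registered in the fit: ",
         paste(unknown_sp, collapse = ", "), call. = FALSE)
  }
  rates <- posterior_daily_rates(fit)
  n_avail <- nrow(rates$draws)
  if (n_draws > n_avail) {
    stop("`n_draws` (", n_draws, ") exceeds available posterior draws (",
         n_avail, ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  take <- sample.int(n_avail, n_draws)
  communities <- unique(abundance$community)
  out <- vector("list", length(communities) * length(prey))
  k <- 0
  for (com in communities) {
    ab <- abundance[abundance$community == com, ]
    for (p in prey) {
      cols <- match(paste(p, ab$species, sep = "\r"),
                    paste(rates$prey, rates$predator, sep = "\r"))
      vals <- as.matrix(rates$draws[take, cols, drop = FALSE]) %*%
        ab$abundance
      k <- k + 1
      out[[k]] <- data.frame(community = com, prey = p,
                             draw = seq_len(n_draws), value = as.numeric(vals))
    }
  }
  draws <- do.call(rbind, out)
  agg <- function(f) {
    stats::aggregate(value ~ community + prey, data = draws, FUN = f)$value
  }
  smry <- stats::aggregate(value ~ community + prey, data = draws,
                           FUN = mean)
  names(smry)[names(smry) == "value"] <- "mean"
  smry$sd <- agg(stats::sd)
  smry$median <- agg(function(x) quantile_lower(x, 0.5))
  smry$q25 <- agg(function(x) quantile_lower(x, 0.25))
  smry$q75 <- agg(function(x) quantile_lower(x, 0.75))
  smry$q99 <- agg(function(x) quantile_lower(x, 0.99))
  list(draws = draws, summary = smry)
}

#' Rough frequency-based biocontrol comparator
#'
#' Replaces the model-based predation rate with the pooled proportion of
#' positive detection tests: `sum_c freq_c,p * A_c`, read as prey per day.
#' Because a detection only reflects meals within the detectability window
#' `I`, this comparator underestimates predation whenever `I` is shorter
#' than a day, and the more so the faster the prey is digested.
#'
#' @param field field-test data frame.
#' @param abundance data frame with `community`, `species`, `abundance`.
#' @param prey prey label(s); defaults to all prey in `field`.
#' @return data frame per (community, prey) with the rough indicator
#'   `value`. Species with abundance but no field test for a prey
#'   contribute zero, with a message.
#' @export
rough_indicator <- function(field, abundance, prey = NULL) {
  validate_field_data(field)
  validate_abundance(abundance)
  if (is.null(prey)) prey <- sort(unique(field$prey))
  obs <- aggregate_field(field)
  out <- vector("list", 0)
  for (com in unique(abundance$community)) {
    ab <- abundance[abundance$community == com & abundance$abundance > 0, ]
    for (p in prey) {
      sub <- obs[obs$prey == p, ]
      idx <- match(ab$species, sub$predator)
      if (anyNA(idx)) {
        message("community ", com, ", prey ", p, ": no field tests for ",
                paste(ab$species[is.na(idx)], collapse = ", "),
                " (contributing 0)")
      }
      freq <- ifelse(is.na(idx), 0, sub$y[idx] / sub$n[idx])
      out[[length(out) + 1]] <- data.frame(
        community = com, prey = p, value = sum(freq * ab$abundance))
    }
  }
  do.call(rbind, out)
}
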