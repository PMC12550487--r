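## Delimited-text readers and writers with row-level validation, plus the
## run-configuration file. Interchange format is plain CSV with a header:
##   feeding trial: predator, prey, hours_since_feeding, detected
##   field tests:   individual_id, predator, prey, detected [, session, region]
##   abundances:    community, species, abundance

validate_lab_data <- function(lab) {
  need <- c("predator", "prey", "hours_since_feeding", "detected")
  miss <- setdiff(need, names(lab))
  if (length(miss)) {
    stop("feeding-trial data missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  bad <- which(!is.finite(lab$hours_since_feeding) |
                 lab$hours_since_feeding < 0)
  if (length(bad)) {
    problems <- c(problems, paste0("negative or missing hours on row(s) ",
                                   paste(bad, collapse = ", ")))
  }
  bad <- which(!lab$detected %in% c(0L, 1L))
  if (length(bad)) {
    problems <- c(problems, paste0("non-binary `detected` on row(s) ",
                                   paste(bad, collapse = ", ")))
  }
  bad <- which(is.na(lab$predator) | lab$predator == "" |
                 is.na(lab$prey) | lab$prey == "")
  if (length(bad)) {
    problems <- c(problems, paste0("empty species/prey code on row(s) ",
                                   paste(bad, collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid feeding-trial data: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  invisible(TRUE)
}

validate_field_data <- function(field) {
  need <- c("predator", "prey", "detected")
  miss <- setdiff(need, names(field))
  if (length(miss)) {
    stop("field data missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  bad <- which(!field$detected %in% c(0L, 1L))
  if (length(bad)) {
    problems <- c(problems, paste0("non-binary `detected` on row(s) ",
                                   paste(bad, collapse = ", ")))
  }
  bad <- which(is.na(field$predator) | field$predator == "" |
                 is.na(field$prey) | field$prey == "")
  if (length(bad)) {
    problems <- c(problems, paste0("empty species/prey code on row(s) ",
                                   paste(bad, collapse = ", ")))
  }
  if ("individual_id" %in% names(field)) {
    key <- paste(field$individual_id, field$prey, sep = "\r")
    if (anyDuplicated(key)) {
      problems <- c(problems,
                    paste0("duplicated (individual_id, prey) on row(s) ",
                           paste(which(duplicated(key)), collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("invalid field data: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  invisible(TRUE)
}

read_table_checked <- function(path, validator, label) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    warning("empty ", label, " file: ", path, call. = FALSE)
    return(tab)
  }
  ## validators report data-row numbers; convert to file line numbers
  ## (header is line 1) in the error message
  res <- tryCatch(validator(tab), error = function(e) e)
  if (inherits(res, "error")) {
    msg <- gsub("row\\(s\\) ([0-9, ]+)", "row(s) \\1 ", conditionMessage(res))
    stop(msg, " [file line = data row + 1]", call. = FALSE)
  }
  tab
}

#' Read a feeding-trial CSV
#'
#' Columns `predator`, `prey`, `hours_since_feeding`, `detected` (0/1).
#' Validation failures are reported with the offending row numbers; no row
#' is ever silently dropped.
#'
#' @param path path to a CSV file with a header row.
#' @return Validated data frame; a summary is printed via `message()`.
#' @export
read_lab_data <- function(path) {
  tab <- read_table_checked(path, validate_lab_data, "feeding-trial")
  if (nrow(tab)) {
    message(sprintf(
      "feeding trial: %d tests, %d predator species, %d prey, %d positive",
      nrow(tab), length(unique(tab$predator)), length(unique(tab$prey)),
      sum(tab$detected)))
  }
  tab
}

#' Read a field-capture CSV
#'
#' Columns `individual_id`, `predator`, `prey`, `detected` (0/1), and
#' optional grouping labels `session` and `region` (carried through, never
#' used by the model; filter upstream to refit on subsets).
#'
#' @inheritParams read_lab_data
#' @return Validated data frame.
#' @export
read_field_data <- function(path) {
  tab <- read_table_checked(path, validate_field_data, "field")
  if (nrow(tab)) {
    pos <- stats::aggregate(detected ~ prey, data = tab, FUN = sum)
    message(sprintf(
      "field tests: %d rows, %d predator species, %d prey; positives: %s",
      nrow(tab), length(unique(tab$predator)), length(unique(tab$prey)),
      paste(pos$prey, pos$detected, sep = "=", collapse = ", ")))
  }
  tab
}

validate_abundance <- function(tab) {
  need <- c("community", "species", "abundance")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("abundance data missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(tab$abundance) | tab$abundance < 0)
  if (length(bad)) {
    stop("invalid abundance data: negative or missing abundance on row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a community-abundance CSV
#'
#' Columns `community` (e.g., a season label), `species`, `abundance`
#' (activity-density, non-negative).
#'
#' @inheritParams read_lab_data
#' @return Validated data frame.
#' @export
read_abundance <- function(path) {
  read_table_checked(path, validate_abundance, "abundance")
}

#' Write a data frame as interchange CSV
#'
#' @param tab data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Every hyperprior constant and sampler setting in one overridable list;
#' [write_config_template()] serialises it as YAML.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1,
    hyperpriors = list(
      prey_beta0 = c(0, 2),
      prey_lam = c(0, 2),
      log_beta1_location = c(0, 1),
      scale_halfnormal = 1
    ),
    sampler = list(
      chains = 3, adapt = 1500, warmup = 4000, iter = 30000, thin = 5,
      rhat_gate = 1.01, max_total_iter = 150000
    ),
    indicator = list(n_draws = 100)
  )
}

#' Write a YAML configuration template
#'
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config_template <- function(path) {
  yaml::write_yaml(default_config(), path)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Missing keys fall back to [default_config()] values.
#'
#' @param path path to a YAML file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_in <- function(base, over) {
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]])) {
        base[[k]] <- merge_in(base[[k]], over[[k]])
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  merge_in(cfg, user)
}

config_hyperpriors <- function(cfg) {
  hp <- cfg$hyperpriors
  default_hyperpriors(prey_beta0 = unlist(hp$prey_beta0),
                      prey_lam = unlist(hp$prey_lam),
                      log_beta1_location = unlist(hp$log_beta1_location),
                      scale_halfnormal = hp$scale_halfnormal)
}
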