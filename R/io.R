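#' Read multi-compound dose-toxicity data from delimited text
#'
#' Expects a CSV (header required) with columns `compound`, `population`
#' (values `source`/`target`, case-insensitive; `adult`/`caucasian` map to
#' source and `pediatric`/`japanese` to target), `dose`, `n`, `dlt`, one row
#' per compound x population x dose level. Reference doses are supplied
#' separately (they are configuration, not data): a named vector/list keyed
#' by compound, or a single value recycled to all compounds.
#'
#' @param path path to the CSV file.
#' @param reference_doses named numeric vector/list (names = compound ids),
#'   or a single unnamed value applied to every compound.
#' @return list of [compound_dataset()] objects (alphabetical by compound).
#' @export
read_compound_table <- function(path, reference_doses) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound", "population", "dose", "n", "dlt")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  df$population <- normalize_population(df$population)
  bad_pop <- which(is.na(df$population))
  if (length(bad_pop) > 0) {
    stop("unknown population label in row(s) ",
         paste(bad_pop, collapse = ", "),
         " (expected source/target)")
  }
  for (col in c("dose", "n", "dlt")) {
    bad <- which(!is.finite(as.numeric(df[[col]])))
    if (length(bad) > 0) {
      stop("non-numeric ", col, " in row(s) ", paste(bad, collapse = ", "))
    }
  }
  bad_dlt <- which(df$dlt > df$n | df$dlt < 0 | df$n < 0)
  if (length(bad_dlt) > 0) {
    stop("dlt exceeds n (or negative count) in row(s) ",
         paste(bad_dlt, collapse = ", "))
  }
  compounds <- sort(unique(df$compound))
  ref_map <- resolve_ref_map(reference_doses, compounds)
  lapply(compounds, function(id) {
    sub <- df[df$compound == id, ]
    pops <- lapply(c("source", "target"), function(p) {
      rows <- sub[sub$population == p, ]
      if (nrow(rows) == 0) {
        stop("compound ", id, " has no ", p, "-population rows")
      }
      rows <- rows[order(rows$dose), ]
      list(grid = dose_grid(rows$dose, ref_map[[id]]),
           outcome = trial_outcome(rows$n, rows$dlt))
    })
    compound_dataset(id, pops[[1]]$grid, pops[[1]]$outcome,
                     pops[[2]]$grid, pops[[2]]$outcome)
  })
}

normalize_population <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("source", "adult", "adults", "caucasian", "s")] <- "source"
  out[x %in% c("target", "pediatric", "paediatric", "japanese", "t")] <- "target"
  out
}

resolve_ref_map <- function(reference_doses, compounds) {
  if (is.null(reference_doses)) {
    stop("reference_doses must be supplied (one per compound, or a single ",
         "value for all)")
  }
  ref <- as.list(reference_doses)
  if (length(ref) == 1L && is.null(names(reference_doses))) {
    ref <- setNames(rep(ref, length(compounds)), compounds)
  }
  missing_ref <- setdiff(compounds, names(ref))
  if (length(missing_ref) > 0) {
    stop("missing reference dose for compound(s): ",
         paste(missing_ref, collapse = ", "))
  }
  ref
}

#' Write compound datasets as a delimited table
#'
#' Long-format CSV with columns `compound`, `population`, `dose`, `n`,
#' `dlt` — the format read back by [read_compound_table()]. Reference doses
#' are returned invisibly (and are not part of the table).
#'
#' @param datasets list of [compound_dataset()] objects.
#' @param path output CSV path.
#' @return invisibly, the named vector of reference doses per compound.
#' @export
write_compound_table <- function(datasets, path) {
  rows <- do.call(rbind, lapply(datasets, function(d) {
    do.call(rbind, lapply(c("source", "target"), function(p) {
      pop <- d[[p]]
      data.frame(compound = d$compound_id, population = p,
                 dose = pop$grid$doses, n = pop$outcome$n_per_dose,
                 dlt = pop$outcome$dlt_per_dose)
    }))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(vapply(datasets, function(d) d$source$grid$reference_dose,
                   numeric(1),
                   USE.NAMES = FALSE) |>
              setNames(vapply(datasets, `[[`, character(1), "compound_id")))
}

#' Resolve a compound's reference dose from identified MTDs
#'
#' Rule chain used when assembling historical cross-population data: an
#' explicit override always wins; if both populations identified the same
#' MTD, that dose is the reference; if only one MTD is known, it is used;
#' if the two MTDs differ, the source-population MTD is taken.
#'
#' @param mtd_source,mtd_target identified MTD dose *values* (positive
#'   reals) or `NULL` when no MTD was identified in that population.
#' @param override optional explicit reference dose.
#' @return positive reference dose.
#' @export
resolve_reference_dose <- function(mtd_source = NULL, mtd_target = NULL,
                                   override = NULL) {
  if (!is.null(override)) {
    stopifnot(override > 0)
    return(override)
  }
  if (is.null(mtd_source) && is.null(mtd_target)) {
    stop("no MTD available in either population and no override supplied")
  }
  if (is.null(mtd_source)) return(mtd_target)
  if (is.null(mtd_target)) return(mtd_source)
  if (isTRUE(all.equal(mtd_source, mtd_target))) return(mtd_source)
  mtd_source
}

#' Assemble a reproducible run configuration
#'
#' Captures seed, MCMC settings and design knobs; serialized into the
#' header of every results file written by the command-line interface so
#' any output can be traced back to its configuration.
#'
#' @param seed integer seed.
#' @param control an [mcmc_control()].
#' @param theta target DLT probability.
#' @param no_skip escalation constraint flag.
#' @param base transformation base for [similarity_to_omega()].
#' @param model similarity model, `"exnex"` or `"hierarchical"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, control = mcmc_control(), theta = 0.30,
                       no_skip = TRUE, base = 0.01,
                       model = c("exnex", "hierarchical")) {
  model <- match.arg(model)
  structure(list(seed = as.integer(seed), control = control, theta = theta,
                 no_skip = no_skip, base = base, model = model,
                 package_version = as.character(packageVersion("doseborrow"))),
            class = "run_config")
}

config_header <- function(config) {
  c(sprintf("# doseborrow %s", config$package_version),
    sprintf("# seed: %d", config$seed),
    sprintf("# mcmc: chains=%d warmup=%d iter=%d", config$control$chains,
            config$control$warmup, config$control$iter),
    sprintf("# theta: %g | no_skip: %s | omega_base: %g | model: %s",
            config$theta, config$no_skip, config$base, config$model))
}

# write a data.frame as CSV with a commented config header (audit trail)
write_result_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# read back a result table, skipping the config header
read_result_table <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE)
}
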