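# Configuration, file I/O and the end-to-end pipeline.

#' Default pipeline configuration
#'
#' @param seed Master seed fanned out to per-stage substreams.
#' @param n Cohort size.
#' @param psa_iter PSA iterations per risk group.
#' @param out_dir Output directory.
#' @return Named list of validated settings.
#' @export
default_run_config <- function(seed = 1L, n = 10000L, psa_iter = 1000L,
                               out_dir = tempfile("scad_run_")) {
  list(
    seed = seed,
    n = n,
    k_groups = 10L,
    families = FAMILIES,
    splice_time = 10,
    cycle_length = CYCLE_YEARS,
    discount_rate = 0.035,
    age_cap = 110,
    rhos = c(0.10, 0.20, 0.30, 0.40),
    lambdas = seq(10000, 40000, by = 10000),
    psa_iter = psa_iter,
    out_dir = out_dir
  )
}

validate_run_config <- function(config) {
  config <- utils::modifyList(default_run_config(), config)
  with(config, {
    stopifnot(n >= 1, k_groups >= 1, psa_iter >= 1)
    if (cycle_length <= 0) stop("cycle_length must be positive", call. = FALSE)
    if (discount_rate < 0) stop("discount_rate must be >= 0", call. = FALSE)
    if (splice_time <= 0) stop("splice_time must be positive", call. = FALSE)
    if (any(rhos < 0 | rhos >= 1)) stop("rhos must lie in [0, 1)", call. = FALSE)
    if (any(lambdas <= 0)) stop("lambdas must be positive", call. = FALSE)
  })
  config
}

#' Read a flat key: value configuration file
#'
#' Minimal YAML-like format: one \code{key: value} pair per line, \code{#}
#' comments, numeric values parsed as numbers and comma-separated values as
#' vectors.
#'
#' @param path File path.
#' @return Named list merged over \code{\link{default_run_config}}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln, call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  validate_run_config(out)
}

#' Write a flat key: value configuration file
#'
#' @param config Configuration list.
#' @param path Destination path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  keep <- vapply(config, function(v) is.numeric(v) || is.character(v), TRUE)
  lines <- vapply(names(config)[keep], function(k) {
    sprintf("%s: %s", k, paste(config[[k]], collapse = ", "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read cohort-generator settings from a key: value file
#'
#' Same flat format as \code{\link{read_run_config}}, with dotted keys for
#' nested fields: \code{binary_probs.hypertension: 0.76},
#' \code{subtype_probs.stable_angina: 0.47}, and so on. Named vector entries
#' inside a group keep their element names. Unspecified settings keep the
#' defaults of \code{\link{default_cohort_config}}.
#'
#' @param path File path.
#' @return A validated generator configuration list.
#' @export
read_cohort_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- default_cohort_config()
  for (ln in lines) {
    m <- regmatches(ln, regexec(
      "^([A-Za-z_][A-Za-z0-9_]*)(\\.([A-Za-z_][A-Za-z0-9_]*))?\\s*:\\s*(.*)$",
      ln))[[1]]
    if (length(m) != 5) stop("malformed config line: ", ln, call. = FALSE)
    key <- m[2]; sub_key <- m[4]; val <- trimws(m[5])
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    v <- if (!anyNA(num)) num else parts
    if (nzchar(sub_key)) {
      if (!key %in% names(cfg)) stop("unknown config group: ", key, call. = FALSE)
      cfg[[key]][[sub_key]] <- v
    } else {
      cfg[[key]] <- v
    }
  }
  validate_cohort_config(cfg)
}

#' Write cohort-generator settings to a key: value file
#'
#' @param config Generator configuration list.
#' @param path Destination path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  lines <- character(0)
  for (k in names(config)) {
    v <- config[[k]]
    if (is.matrix(v)) next  # correlation matrices are code-level settings
    if (!is.null(names(v)) && length(v) > 1) {
      lines <- c(lines, sprintf("%s.%s: %s", k, names(v), format(v)))
    } else {
      lines <- c(lines, sprintf("%s: %s", k, paste(format(v), collapse = ", ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a life table CSV (sex, age, qx)
#'
#' @param path CSV path.
#' @return Validated \code{scad_lifetable}.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sex", "age", "qx"), names(lt))
  if (length(missing)) {
    stop("life table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(lt$qx) | lt$qx < 0 | lt$qx > 1)
  if (length(bad)) {
    stop(sprintf("life table qx out of [0,1] at row %d", bad[1] + 1L),
         call. = FALSE)
  }
  validate_life_table(lt)
  class(lt) <- c("scad_lifetable", "data.frame")
  lt
}

#' Write a life table CSV
#'
#' @param lt \code{scad_lifetable}.
#' @param path Destination path.
#' @return \code{path}, invisibly.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE)
  invisible(path)
}

#' Read a utility catalogue (bands CSV + multipliers CSV)
#'
#' @param bands_path CSV with columns sex, age_lo, age_hi, base_utility.
#' @param multipliers_path CSV with columns name, value.
#' @return Validated \code{scad_utilities}.
#' @export
read_utility_catalogue <- function(bands_path, multipliers_path) {
  bands <- utils::read.csv(bands_path, stringsAsFactors = FALSE)
  need <- c("sex", "age_lo", "age_hi", "base_utility")
  missing <- setdiff(need, names(bands))
  if (length(missing)) {
    stop("utility bands missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mult <- utils::read.csv(multipliers_path, stringsAsFactors = FALSE)
  if (!all(c("name", "value") %in% names(mult))) {
    stop("multipliers file needs columns name, value", call. = FALSE)
  }
  cat <- structure(list(bands = bands,
                        multipliers = setNames(mult$value, mult$name)),
                   class = "scad_utilities")
  validate_utility_catalogue(cat)
  cat
}

#' Write a utility catalogue to a pair of CSVs
#'
#' @param catalogue \code{scad_utilities}.
#' @param bands_path,multipliers_path Destination paths.
#' @return Invisibly, the two paths.
#' @export
write_utility_catalogue <- function(catalogue, bands_path, multipliers_path) {
  utils::write.csv(catalogue$bands, bands_path, row.names = FALSE)
  utils::write.csv(data.frame(name = names(catalogue$multipliers),
                              value = unname(catalogue$multipliers)),
                   multipliers_path, row.names = FALSE)
  invisible(c(bands_path, multipliers_path))
}

#' Write model outputs as JSON and CSV
#'
#' @param outputs \code{scad_outputs} or a data frame of outputs.
#' @param path Base path; \code{.json} and \code{.csv} are appended.
#' @return The JSON path, invisibly.
#' @export
write_results <- function(outputs, path) {
  df <- if (inherits(outputs, "scad_outputs")) as.data.frame(outputs) else outputs
  jsonlite::write_json(df, paste0(path, ".json"), digits = NA, auto_unbox = FALSE)
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  invisible(paste0(path, ".json"))
}

#' Read model outputs written by \code{\link{write_results}}
#'
#' @param path Base path used at write time.
#' @return Data frame of outputs.
#' @export
read_results <- function(path) {
  jsonlite::fromJSON(paste0(path, ".json"))
}

#' Serialise a fitted equation set to JSON
#'
#' @param set \code{scad_eqset}.
#' @param path Destination JSON path.
#' @return \code{path}, invisibly.
#' @export
write_equation_set <- function(set, path) {
  ser_fit <- function(f) {
    list(endpoint = f$endpoint, family = f$family, coef = as.list(f$coef),
         sigma = f$sigma, Q = f$Q, loglik = f$loglik, AIC = f$AIC,
         n_events = f$n_events, vcov = f$vcov, par = as.list(f$par %||% list()),
         fingerprint = f$fingerprint)
  }
  obj <- list(primary = lapply(set$primary, ser_fit),
              post = lapply(set$post, function(x) lapply(x, ser_fit)),
              splice_time = set$splice_time,
              life_table = as.data.frame(set$life_table))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Run the full pipeline: simulate, fit, stratify, run, PSA, price
#'
#' Executes every stage with per-stage sub-seeds derived from the master
#' seed, writes versioned CSV/JSON outputs into \code{config$out_dir}, and
#' returns a manifest of output-file MD5 hashes (identical configs and seeds
#' give identical manifests).
#'
#' @param config See \code{\link{default_run_config}}.
#' @param truth Ground-truth parameters for the synthetic stages.
#' @param verbose Print stage progress.
#' @return List with the stage results and the \code{manifest}.
#' @export
run_pipeline <- function(config = default_run_config(),
                         truth = default_true_parameters(),
                         verbose = FALSE) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat(sprintf("run started seed=%d n=%d psa_iter=%d\n",
              config$seed, config$n, config$psa_iter), file = log_path)
  say <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  stage_seed <- function(k) substream_seed(config$seed, k)

  say("stage 1/6: simulate cohort (n = %d)", config$n)
  cohort <- generate_cohort(config$n, stage_seed(1))
  histories <- simulate_event_histories(cohort, truth, stage_seed(2))
  panel <- simulate_cost_panel(cohort, histories, truth, stage_seed(3))
  utils::write.csv(cohort, file.path(config$out_dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(histories, file.path(config$out_dir, "histories.csv"), row.names = FALSE)

  say("stage 2/6: fit 11 risk equations + cost model")
  life_table <- make_life_table()
  set <- fit_risk_equations(cohort, histories, families = config$families,
                            life_table = life_table,
                            splice_time = config$splice_time)
  cost_model <- fit_cost_model(panel, cohort)
  utilities <- truth$utility
  write_equation_set(set, file.path(config$out_dir, "equations.json"))
  utils::write.csv(set$aic_table, file.path(config$out_dir, "aic_table.csv"),
                   row.names = FALSE)
  sel <- set$aic_table[set$aic_table$selected, , drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    say("  selected %-40s %-12s AIC %.1f (%d events)",
        sel$endpoint[i], sel$family[i], sel$AIC[i], sel$n_events[i])
  }

  say("stage 3/6: stratify into %d risk groups", config$k_groups)
  groups <- assign_risk_groups(cohort, set, config$k_groups)
  gs <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g$index, n = length(g$member_ids),
               mean_risk = g$mean_risk, risk_at_mean = g$risk_at_mean,
               mean_age = g$mean_age, pct_female = 100 * g$mean_female)
  }))
  utils::write.csv(gs, file.path(config$out_dir, "risk_groups.csv"), row.names = FALSE)

  say("stage 4/6: lifetime model per group")
  results <- do.call(rbind, lapply(groups, function(g) {
    out <- run_cohort(g$mean_covariates, set, cost_model, utilities,
                      discount_rate = config$discount_rate,
                      age_cap = config$age_cap)$outputs
    cbind(data.frame(group = g$index), as.data.frame(out))
  }))
  utils::write.csv(results, file.path(config$out_dir, "group_results.csv"),
                   row.names = FALSE)

  say("stage 5/6: PSA (%d iterations per group)", config$psa_iter)
  psa <- do.call(rbind, lapply(groups, function(g) {
    p <- run_psa(g$mean_covariates, set, cost_model, utilities,
                 n_iter = config$psa_iter, seed = stage_seed(100 + g$index),
                 discount_rate = config$discount_rate)
    data.frame(group = g$index,
               field = colnames(p$ci),
               point = unlist(unclass(p$point)[colnames(p$ci)]),
               lower = p$ci["lower", ], upper = p$ci["upper", ],
               row.names = NULL)
  }))
  utils::write.csv(psa, file.path(config$out_dir, "psa_summary.csv"),
                   row.names = FALSE)

  say("stage 6/6: value-based pricing grid")
  prices <- price_grid(groups, set, cost_model, utilities,
                       rhos = config$rhos, lambdas = config$lambdas,
                       discount_rate = config$discount_rate)
  utils::write.csv(prices, file.path(config$out_dir, "pricing.csv"),
                   row.names = FALSE)

  say("writing manifest")
  files <- c("cohort.csv", "histories.csv", "equations.json", "aic_table.csv",
             "risk_groups.csv", "group_results.csv", "psa_summary.csv",
             "pricing.csv")
  manifest <- tools::md5sum(file.path(config$out_dir, files))
  names(manifest) <- files
  keep <- vapply(config, function(v) is.numeric(v) || is.character(v), TRUE)
  jsonlite::write_json(list(files = as.list(manifest), config = config[keep]),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(config = config, set = set, cost_model = cost_model,
       utilities = utilities, groups = groups, results = results,
       psa = psa, prices = prices, manifest = manifest)
}
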