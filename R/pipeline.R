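#' Run the full reorientation analysis pipeline on a synthetic study
#'
#' Orchestrates the stages in dependency order — simulate, maps, bmr
#' (rotation/coherency), context (FI/FS similarity + threshold model),
#' population (dot products + context prediction by location), decode
#' (heading/context SVMs), rate (rate remapping), behavior (dig
#' proportions + Bayes factors) — writing CSV/JSON outputs and a run
#' manifest (config echo, package version, file checksums) to `out_dir`.
#' Reruns with the same config are bit-identical. Disabling a stage whose
#' output a later stage needs fails fast with a dependency error.
#'
#' @param config A [sim_config()], or a path to a YAML/JSON file of
#'   `sim_config` arguments.
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "maps", "bmr", "context",
                                    "population", "decode", "rate",
                                    "behavior")) {
  if (is.character(config)) config <- read_run_config(config)
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  need <- function(stage, what) {
    if (is.null(what)) {
      stop(sprintf("stage '%s' requires a disabled upstream stage", stage),
           call. = FALSE)
    }
    what
  }

  study <- NULL
  maps_sq <- maps_rect <- NULL
  res <- list()

  if ("simulate" %in% stages) {
    study <- generate_study(config)
    all_trials <- do.call(rbind, unlist(lapply(
      seq_along(study$animals), function(a) {
        lapply(study$animals[[a]], function(b) {
          cbind(animal = a, b$trials)
        })
      }), recursive = FALSE))
    utils::write.csv(all_trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    res$trials <- all_trials
  }

  if (any(c("maps", "bmr", "context", "population", "decode", "rate")
          %in% stages)) {
    study <- need("maps", study)
    maps_rect <- lapply(study$animals, function(days) {
      lapply(days, session_rate_maps, square = FALSE)
    })
    maps_sq <- lapply(study$animals, function(days) {
      lapply(days, session_rate_maps, square = TRUE)
    })
  }

  per_session <- function(f) {
    unlist(lapply(seq_along(study$animals), function(a) {
      lapply(seq_along(study$animals[[a]]), function(d) f(a, d))
    }), recursive = FALSE)
  }

  if ("bmr" %in% stages) {
    need("bmr", maps_sq)
    bmr_rows <- per_session(function(a, d) {
      rec <- session_bmr(maps_sq[[a]][[d]])
      pr <- bmr_proportions(rec)$animal
      data.frame(animal = a, day = d, angle = as.numeric(names(pr)),
                 proportion = as.numeric(pr))
    })
    bmr_df <- do.call(rbind, bmr_rows)
    utils::write.csv(bmr_df, file.path(out_dir, "bmr_proportions.csv"),
                     row.names = FALSE)
    res$bmr <- bmr_df
  }

  if ("context" %in% stages) {
    need("context", maps_sq)
    score_rows <- per_session(function(a, d) {
      s <- session_context_similarity(maps_sq[[a]][[d]],
                                      study$animals[[a]][[d]]$trials)
      cbind(animal = a, day = d, s)
    })
    scores <- do.call(rbind, score_rows)
    utils::write.csv(scores, file.path(out_dir, "context_scores.csv"),
                     row.names = FALSE)
    fit_report <- tryCatch({
      dc <- within_across_decile_curve(scores)
      fit <- fit_asymptotic_regression(dc$curve$decile, dc$curve$r)
      sel <- if (fit$converged) select_threshold(fit, dc$boundaries)
             else NULL
      list(curve = dc$curve,
           fit = fit[c("a", "b", "c", "AIC", "RSE", "logLik",
                       "half_life", "root", "max_growth_x", "converged")],
           selection = sel)
    }, error = function(e) list(error = conditionMessage(e)))
    jsonlite::write_json(fit_report,
                         file.path(out_dir, "threshold_model.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    res$context <- list(scores = scores, fit_report = fit_report)
  }

  if ("population" %in% stages) {
    need("population", maps_rect)
    if (is.null(res$context)) {
      stop("stage 'population' requires stage 'context'", call. = FALSE)
    }
    pop_rows <- per_session(function(a, d) {
      sc <- res$context$scores
      sc <- sc[sc$animal == a & sc$day == d, ]
      out <- lapply(c("FI", "FS"), function(cls) {
        cells <- sc$cell_id[sc$class == cls]
        acc <- if (length(cells)) {
          predict_context_by_location(
            maps_rect[[a]][[d]], study$animals[[a]][[d]]$trials, cells,
            tie_seed = sub_seed(config$seed, a, d, 0L, 9L))$accuracy
        } else NA_real_
        data.frame(animal = a, day = d, class = cls,
                   n_cells = length(cells), accuracy = as.numeric(acc))
      })
      do.call(rbind, out)
    })
    pop_df <- do.call(rbind, pop_rows)
    utils::write.csv(pop_df,
                     file.path(out_dir, "context_prediction_location.csv"),
                     row.names = FALSE)
    res$population <- pop_df
  }

  if ("decode" %in% stages) {
    need("decode", maps_rect)
    dec_rows <- per_session(function(a, d) {
      b <- study$animals[[a]][[d]]
      ang <- session_center_out_angles(maps_rect[[a]][[d]])
      rates <- session_mean_rates(b)
      fp <- session_field_presence(maps_rect[[a]][[d]])
      data.frame(
        animal = a, day = d,
        heading_alignment = as.numeric(
          predict_heading_from_alignment(ang, b$trials)$accuracy),
        context_rate = as.numeric(
          predict_from_rates(rates, b$trials, "context", fp)$accuracy),
        heading_rate = as.numeric(
          predict_from_rates(rates, b$trials, "heading", fp)$accuracy))
    })
    dec_df <- do.call(rbind, dec_rows)
    utils::write.csv(dec_df, file.path(out_dir, "decoder_accuracy.csv"),
                     row.names = FALSE)
    res$decode <- dec_df
  }

  if ("rate" %in% stages) {
    need("rate", study)
    rr_rows <- per_session(function(a, d) {
      b <- study$animals[[a]][[d]]
      rr <- session_rate_remapping(session_mean_rates(b), b$trials)
      cbind(animal = a, day = d, rr$per_cell)
    })
    rr_df <- do.call(rbind, rr_rows)
    utils::write.csv(rr_df, file.path(out_dir, "rate_remapping.csv"),
                     row.names = FALSE)
    res$rate <- rr_df
  }

  if ("behavior" %in% stages) {
    trials <- need("behavior", res$trials)
    props <- dig_proportions(trials, group_by = "day")
    utils::write.csv(props, file.path(out_dir, "dig_proportions.csv"),
                     row.names = FALSE)
    bf <- lapply(c(cg = "cg", c = "c"), function(m) {
      per_day <- lapply(split(trials, trials$day), function(d) {
        behavior_bayes_factors(d, m)
      })
      per_day
    })
    jsonlite::write_json(bf, file.path(out_dir, "bayes_factors.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    res$behavior <- list(proportions = props, bayes_factors = bf)
  }

  manifest <- list(
    package = "reorientr",
    version = as.character(utils::packageVersion("reorientr")),
    stages = stages,
    config = config[setdiff(names(config), "dig_probs_by_day")],
    dig_probs_by_day = apply(config$dig_probs_by_day, 1, identity,
                             simplify = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "checksums.json"))
  sums <- as.list(tools::md5sum(files))
  names(sums) <- basename(files)
  jsonlite::write_json(sums, file.path(out_dir, "checksums.json"),
                       auto_unbox = TRUE)
  invisible(res)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File of [sim_config()] arguments.
#' @return A validated `sim_config`.
#' @export
read_run_config <- function(path) {
  args <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(args$dig_probs_by_day)) {
    args$dig_probs_by_day <- matrix(unlist(args$dig_probs_by_day),
                                    ncol = 4, byrow = TRUE)
  }
  do.call(sim_config, args)
}
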