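#' Assemble a pipeline configuration
#'
#' Collects everything one full analysis run needs: the raw survey records,
#' the raw-scale site covariate table, the prediction raster stack,
#' candidate covariate lists, and the screening / capping / selection /
#' goodness-of-fit settings. Either pass the data objects directly or give
#' file paths produced by the package's writers. A YAML file with the same
#' field names can be loaded with `yaml::read_yaml` and spliced in.
#'
#' @param records raw survey records data frame (or `records_path` CSV).
#' @param sites raw-scale site covariate table.
#' @param stack a [cov_stack()] for prediction (optional: no maps without
#'   it).
#' @param psi_candidates,p_candidates candidate covariates for the
#'   occupancy and detection parts; `p_candidates` defaults to the fire /
#'   ruggedness detection set intersected with the available columns.
#' @param screen_threshold,screen_priority Spearman screening settings.
#' @param ratio detections-per-covariate cap ratio (default 10).
#' @param daic_cutoff AIC-difference retention cutoff (default 6).
#' @param gof_B,gof_alpha parametric-bootstrap settings (`gof_B = 0`
#'   disables GoF screening).
#' @param n_starts,seed fitting settings.
#' @param weekly_methods methods collapsed weekly (default `"camera"`).
#' @param richness_groups optional named list mapping group name to a
#'   character vector of species for stacked richness maps.
#' @param restricted_ranges optional named list mapping species to a list
#'   with `region` (logical matrix on the stack grid) and `buffer`
#'   (distance); sites outside the buffered region are dropped before
#'   fitting and predictions are clipped to it.
#' @param domain_trim quantile trim for the environmental-domain mask.
#' @param output_dir run directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(records = NULL, sites = NULL, stack = NULL,
                            psi_candidates = NULL, p_candidates = NULL,
                            screen_threshold = 0.7,
                            screen_priority = NULL, ratio = 10,
                            daic_cutoff = 6, gof_B = 100,
                            gof_alpha = 0.05, n_starts = 3, seed = 1,
                            weekly_methods = "camera",
                            richness_groups = NULL,
                            restricted_ranges = NULL, domain_trim = 0,
                            output_dir = tempfile("occumap_run_")) {
  structure(list(records = records, sites = sites, stack = stack,
                 psi_candidates = psi_candidates,
                 p_candidates = p_candidates,
                 screen_threshold = screen_threshold,
                 screen_priority = screen_priority, ratio = ratio,
                 daic_cutoff = daic_cutoff, gof_B = gof_B,
                 gof_alpha = gof_alpha, n_starts = n_starts, seed = seed,
                 weekly_methods = weekly_methods,
                 richness_groups = richness_groups,
                 restricted_ranges = restricted_ranges,
                 domain_trim = domain_trim, output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full occupancy / model-selection / mapping pipeline
#'
#' For every species in the records: builds the multi-method detection
#' history, applies the detections-based covariate cap, enumerates and fits
#' all candidate models, ranks them by AIC, screens the retained set
#' (boundary estimates, parametric-bootstrap goodness-of-fit), falls back
#' to the constant-occupancy null model when necessary, writes the ranked
#' table, selected model, GoF result and mean occupancy/detectability
#' estimates, and (when a stack is supplied) predicts a domain-masked
#' occupancy surface. Finally stacks non-null species surfaces into a
#' relative richness map per group and writes a reproducibility manifest.
#' Species-level failures are logged and skipped.
#'
#' @param config a [pipeline_config()].
#' @return the run directory path, invisibly; per-species results are also
#'   returned in the `results` attribute.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "pipeline_config"),
            !is.null(cfg$records), !is.null(cfg$sites))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "pipeline.log")
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }

  all_cands <- unique(c(cfg$psi_candidates, cfg$p_candidates))
  if (is.null(all_cands) || length(all_cands) == 0L) {
    all_cands <- cov_columns(cfg$sites)
  }
  screen <- spearman_screen(
    cfg$sites[, c("site_id", "x", "y", all_cands)],
    threshold = cfg$screen_threshold, priority = cfg$screen_priority)
  jsonlite::write_json(
    list(kept = screen$kept, discarded = screen$discarded,
         threshold = cfg$screen_threshold),
    file.path(cfg$output_dir, "covariate_screening.json"),
    auto_unbox = TRUE, digits = NA)
  psi_cands <- intersect(cfg$psi_candidates %||% screen$kept, screen$kept)
  p_default <- intersect(c("time_since_fire", "fire_frequency",
                           "ruggedness"), screen$kept)
  p_cands <- intersect(cfg$p_candidates %||% p_default, screen$kept)

  std <- standardize_covariates(
    cfg$sites[, c("site_id", "x", "y", screen$kept)])
  species_list <- sort(unique(cfg$records$species))
  results <- list()

  for (sp in species_list) {
    res <- tryCatch(
      run_species(sp, cfg, std, psi_cands, p_cands, log_line),
      error = function(e) {
        log_line("%s: FAILED (%s)", sp, conditionMessage(e))
        NULL
      })
    if (!is.null(res)) results[[sp]] <- res
  }

  if (!is.null(cfg$stack)) {
    groups <- cfg$richness_groups %||% list(all = names(results))
    for (g in names(groups)) {
      members <- intersect(groups[[g]], names(results))
      surfaces <- list()
      for (sp in members) {
        r <- results[[sp]]
        if (!is.null(r$surface) && !r$is_null) {
          surfaces[[sp]] <- r$surface
        }
      }
      if (length(surfaces)) {
        rich <- stack_richness(surfaces)
        write_surface(rich$richness,
                      file.path(cfg$output_dir,
                                paste0("richness_", g, ".tsv")),
                      meta = list(group = g, species = names(surfaces),
                                  cellsize = rich$cellsize))
        log_line("richness group %s: %d species stacked", g,
                 length(surfaces))
      } else {
        log_line("richness group %s: no non-null species", g)
      }
    }
  }

  summary <- summarize_results(results)
  utils::write.csv(summary, file.path(cfg$output_dir, "summary.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = cfg$seed, n_species = length(results),
    settings = cfg[c("screen_threshold", "ratio", "daic_cutoff", "gof_B",
                     "gof_alpha", "n_starts", "weekly_methods",
                     "domain_trim")],
    psi_candidates = psi_cands, p_candidates = p_cands,
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  out <- cfg$output_dir
  attr(out, "results") <- results
  invisible(out)
}

run_species <- function(sp, cfg, std, psi_cands, p_cands, log_line) {
  sp_dir <- file.path(cfg$output_dir, "species", sp)
  dir.create(sp_dir, showWarnings = FALSE, recursive = TRUE)

  history <- build_history(cfg$records, sp,
                           weekly_methods = cfg$weekly_methods)
  sites_std <- std$table
  range <- NULL
  if (!is.null(cfg$restricted_ranges) &&
      sp %in% names(cfg$restricted_ranges)) {
    rr <- cfg$restricted_ranges[[sp]]
    range <- range_mask(rr$region, rr$buffer, cfg$stack)
    rc <- coord_to_cell(cfg$stack, sites_std$x, sites_std$y)
    inside <- !is.na(rc$row) & range[cbind(rc$row, rc$col)]
    keep_sites <- sites_std$site_id[inside]
    keep <- history$site_ids %in% keep_sites
    history$y <- history$y[keep, , drop = FALSE]
    history$site_ids <- history$site_ids[keep]
  }
  write_history(history, file.path(sp_dir, "history.csv"))

  n_det <- n_detection_sites(history)
  cap <- max_terms_for(n_det, cfg$ratio)
  specs <- enumerate_models(psi_cands, p_cands, max_terms = cap)
  fits <- fit_candidates(specs, history, sites_std,
                         n_starts = cfg$n_starts, seed = cfg$seed,
                         scaling = std$scaling)
  ranked <- rank_by_aic(fits, cutoff = cfg$daic_cutoff)
  write_model_table(ranked$records, sp, file.path(sp_dir, "models.csv"))

  gof_fun <- NULL
  if (cfg$gof_B > 0) {
    gof_fun <- function(fit) {
      parametric_bootstrap(fit, history, sites_std, B = cfg$gof_B,
                           seed = cfg$seed)
    }
  }
  sel <- select_best(ranked, history, sites_std, gof_fun = gof_fun,
                     alpha = cfg$gof_alpha, scaling = std$scaling,
                     seed = cfg$seed)
  # a selected model without environmental predictors is a null model
  # whether it arrived by fallback or by winning the ranking outright
  is_null <- sel$is_null || is.null(sel$fit$spec$psi_terms)
  write_fitted(sel$fit, file.path(sp_dir, "selected.json"))
  if (!is.null(sel$gof)) write_gof(sel$gof, file.path(sp_dir,
                                                      "gof.json"))

  est <- mean_estimates(sel$fit, history, sites_std)
  utils::write.csv(cbind(parameter = c("psi",
                                       paste0("rho:", est$rho$method)),
                         rbind(est$psi,
                               est$rho[, c("mean", "se", "sd_sites")])),
                   file.path(sp_dir, "mean_estimates.csv"),
                   row.names = FALSE)

  surface <- NULL
  if (!is.null(cfg$stack)) {
    surface <- predict_raster(sel$fit, cfg$stack, species = sp)
    if (!is_null) {
      dm <- domain_mask(cfg$stack, cfg$sites, trim = cfg$domain_trim)
      surface <- apply_mask(surface, dm, "environmental domain")
    }
    if (!is.null(range)) surface <- apply_mask(surface, range,
                                               "geographic range")
    write_surface(surface, file.path(sp_dir, "surface.tsv"))
  }

  log_line("%s: %d detection sites, cap %d, %d candidates, selected %s%s",
           sp, n_det, cap, length(specs), spec_string(sel$fit$spec),
           if (is_null) " (constant occupancy)" else "")
  list(species = sp, n_detection_sites = n_det, cap = cap,
       ranked = ranked$records, fit = sel$fit, is_null = is_null,
       gof = sel$gof, estimates = est, surface = surface)
}

summarize_results <- function(results) {
  if (length(results) == 0L) {
    return(data.frame(species = character(0),
                      n_detection_sites = integer(0), spec = character(0),
                      aic = numeric(0), is_null = logical(0),
                      mean_psi = numeric(0), se_psi = numeric(0),
                      status = character(0)))
  }
  do.call(rbind, lapply(results, function(r) {
    rho_cols <- stats::setNames(as.list(r$estimates$rho$mean),
                                paste0("rho_", r$estimates$rho$method))
    base <- data.frame(species = r$species,
                       n_detection_sites = r$n_detection_sites,
                       spec = spec_string(r$fit$spec), aic = r$fit$aic,
                       is_null = r$is_null,
                       mean_psi = r$estimates$psi$mean,
                       se_psi = r$estimates$psi$se,
                       status = "ok", stringsAsFactors = FALSE)
    for (nm in names(rho_cols)) base[[nm]] <- rho_cols[[nm]]
    if (!is.null(r$gof)) {
      base$gof_p_sse <- r$gof$p_value[["sse"]]
      base$gof_p_ft <- r$gof$p_value[["freeman_tukey"]]
      base$gof_p_pearson <- r$gof$p_value[["pearson"]]
    }
    rownames(base) <- NULL
    base
  }))
}

#' Summarise a completed run directory
#'
#' Reads the per-species outputs back into one table: detection sites,
#' selected specification, AIC, GoF p-values and mean estimates. Species
#' with incomplete outputs get a `status` other than `"ok"`.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return a data frame with one row per species.
#' @export
summarize_run <- function(run_dir) {
  sp_root <- file.path(run_dir, "species")
  species <- if (dir.exists(sp_root)) list.dirs(sp_root, recursive = FALSE,
                                                full.names = FALSE)
             else character(0)
  rows <- lapply(species, function(sp) {
    sp_dir <- file.path(sp_root, sp)
    sel_path <- file.path(sp_dir, "selected.json")
    if (!file.exists(sel_path)) {
      return(data.frame(species = sp, n_detection_sites = NA_integer_,
                        spec = NA_character_, aic = NA_real_,
                        is_null = NA, mean_psi = NA_real_,
                        se_psi = NA_real_, status = "incomplete",
                        stringsAsFactors = FALSE))
    }
    fit <- read_fitted(sel_path)
    hist <- read_history(file.path(sp_dir, "history.csv"))
    est <- utils::read.csv(file.path(sp_dir, "mean_estimates.csv"),
                           stringsAsFactors = FALSE)
    out <- data.frame(species = sp,
                      n_detection_sites = n_detection_sites(hist),
                      spec = spec_string(fit$spec), aic = fit$aic,
                      is_null = is.null(fit$spec$psi_terms),
                      mean_psi = est$mean[est$parameter == "psi"],
                      se_psi = est$se[est$parameter == "psi"],
                      status = "ok", stringsAsFactors = FALSE)
    rho <- est[grepl("^rho:", est$parameter), , drop = FALSE]
    for (i in seq_len(nrow(rho))) {
      out[[sub("^rho:", "rho_", rho$parameter[i])]] <- rho$mean[i]
    }
    gof_path <- file.path(sp_dir, "gof.json")
    if (file.exists(gof_path)) {
      g <- jsonlite::read_json(gof_path, simplifyVector = TRUE)
      out$gof_p_sse <- g$p_value$sse
      out$gof_p_ft <- g$p_value$freeman_tukey
      out$gof_p_pearson <- g$p_value$pearson
    }
    out
  })
  if (length(rows) == 0L) return(summarize_results(list()))
  base_cols <- c("species", "n_detection_sites", "spec", "aic", "is_null",
                 "mean_psi", "se_psi", "status")
  all_cols <- unique(c(base_cols, unlist(lapply(rows, names))))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_cols, names(r))) r[[nm]] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
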