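#' Run the full isolated-patch pipeline
#'
#' Orchestrates the six stages end to end: (1) pairwise F_ST from the
#' genotypes; (2) binned resistance surfaces for every retained
#' environmental variable and circuit-theory resistance matrices between the
#' sampling sites, plus a geographic-distance-only control; (3) the
#' IBD-residual MMRR scan selecting the variable(s) whose resistance model
#' predicts differentiation beyond isolation by distance (p <= alpha, the
#' marginal case included); (4) a univariate maximum-entropy connectivity
#' surface per selected variable from the presence records; (5) patch
#' extraction and gap-distance clustering on that surface; (6) a
#' multivariate suitability model (optionally merged with a prior map by
#' cellwise maximum) and the final isolated-patch selection.
#'
#' @param config a named list or the path of a flat `key = value` config
#'   file. Recognized keys (paths or in-memory objects): `genotypes`,
#'   `sites`, `presences`, `env` (named list of rasters), `prior`,
#'   `water_mask`; numbers: `seed` (default 1), `n_perm` (10000), `alpha`
#'   (0.05), `fst_perms` (0), `neighborhood` (8), `cutoff` (0.5), `min_size`
#'   (4), `range_km` (5), `suit_cutoff` (0.25), `edge_km` (5); strings:
#'   `resistance_mode` ("effective" or "straightpath_surface"), `geo_mode`
#'   ("uniform_effective", the default - an all-cost-1 circuit model, the
#'   distance-only control matching how the environmental matrices are
#'   built - or "greatcircle"), `out_dir` (write stage outputs when set).
#' @return a `pipeline_run` list: `fst`, `mantel`, `filter`, `scan`,
#'   `selected_variables`, `surfaces` (connectivity per selected variable),
#'   `patches` (per selected variable), `suitability`, `status`, `log`.
#'   When no surface is significant the run stops after stage 3 with
#'   `status = "no_significant_variable"` (a report, not an error).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  get <- function(key, default = NULL) config[[key]] %||% default
  seed <- as.integer(get("seed", 1))
  n_perm <- as.integer(get("n_perm", 10000))
  alpha <- get("alpha", 0.05)
  logs <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    logs <<- c(logs, msg)
    message("[isopatch] ", msg)
  }

  sites <- load_input(get("sites"), read_sites, "sites")
  genotypes <- load_input(get("genotypes"), read_genotypes, "genotypes")
  presences <- load_input(get("presences"), read_presences, "presences")
  stack <- load_stack(get("env"))
  prior <- get("prior")
  if (is.character(prior)) prior <- read_raster(prior)
  water <- get("water_mask")
  if (is.character(water)) water <- read_raster(water)
  say("inputs: %d sites, %d loci, %d env layers, %d presences; seed %d",
      nrow(sites), attr(genotypes, "n_loci"), length(stack), nrow(presences),
      seed)

  # M1: genetic differentiation
  fst <- fst_matrix(genotypes, sites, n_perm = as.integer(get("fst_perms", 0)),
                    seed = seed)
  geo_dist <- distance_matrix_km(sites)
  mant <- mantel_ibd(linearize_fst(fst), geo_dist, n_perm = n_perm, seed = seed)
  say("M1: F_ST matrix done; Mantel IBD r = %.3f, p = %.4g", mant$r, mant$p)

  # env covariation filter
  filt <- if (length(stack) > 1L)
    covariation_filter(stack, sites,
                       r_flag = get("r_flag", 0.80), r_drop = get("r_drop", 0.85))
  else list(selected = names(stack))
  say("env filter: %d of %d variables retained (%s)",
      length(filt$selected), length(stack), paste(filt$selected, collapse = ", "))

  # M2: resistance surfaces and circuit matrices
  neighborhood <- get("neighborhood", 8)
  rmode <- get("resistance_mode", "effective")
  env_mats <- list()
  for (tok in filt$selected) {
    for (surf in resistance_surfaces(stack[[tok]], token = tok)) {
      key <- paste(attr(surf, "provenance")$variable,
                   attr(surf, "provenance")$direction,
                   attr(surf, "provenance")$scheme, sep = "|")
      env_mats[[key]] <- resistance_matrix(build_graph(surf, neighborhood),
                                           sites, mode = rmode)
    }
  }
  geo_mode <- get("geo_mode", "uniform_effective")
  geo_ctrl <- geographic_control_matrix(sites, frame = stack[[1]],
                                        mode = geo_mode,
                                        neighborhood = neighborhood)
  say("M2: %d resistance matrices (%s mode), %s control",
      length(env_mats), rmode, geo_mode)

  # M3: IBD-residual scan
  scan <- ibd_residual_scan(fst, geo_ctrl, env_mats, n_perm = n_perm,
                            seed = seed, alpha = alpha)
  sel_surf <- scan$table[scan$table$selected, , drop = FALSE]
  selected_vars <- unique(sel_surf$variable)
  result <- list(fst = fst, mantel = mant, filter = filt, scan = scan,
                 selected_variables = selected_vars, config = config,
                 seed = seed)
  if (length(selected_vars) == 0L) {
    say("M3: no surface significant at alpha = %g; stopping with report", alpha)
    result$status <- "no_significant_variable"
    result$log <- logs
    class(result) <- "pipeline_run"
    return(write_outputs(result, get("out_dir")))
  }
  say("M3: selected variable(s): %s (best p = %.4g)",
      paste(selected_vars, collapse = ", "), min(sel_surf$p_mmrr))

  # M4/M5: univariate connectivity surface and patches per selected variable
  surfaces <- list(); patch_sets <- list()
  for (tok in selected_vars) {
    feats <- feature_expand(stack[tok])        # univariate by construction
    model <- fit_maxent(feats, presences)
    surf <- predict_logistic(model, stack[tok], water_mask = water,
                             role = "connectivity")
    surfaces[[tok]] <- surf
    ps <- extract_patches(surf, cutoff = get("cutoff", 0.5),
                          min_size = get("min_size", 4),
                          connectivity = neighborhood)
    ps <- cluster_patches(ps, range_km = get("range_km", 5))
    patch_sets[[tok]] <- ps
    say("M4/M5 [%s]: %d patches above %.2f after min size %d",
        tok, nrow(ps$table), get("cutoff", 0.5), get("min_size", 4))
  }

  # M6: suitability model, prior merge, isolated-patch selection
  feats_all <- feature_expand(stack[filt$selected])
  suit_model <- fit_maxent(feats_all, presences)
  suit <- predict_logistic(suit_model, stack[filt$selected],
                           water_mask = water, role = "suitability")
  if (!is.null(prior)) suit <- merge_max(suit, prior)
  for (tok in selected_vars) {
    patch_sets[[tok]] <- select_isolated(patch_sets[[tok]], suit,
                                         suit_cutoff = get("suit_cutoff", 0.25),
                                         edge_km = get("edge_km", 5))
    say("M6 [%s]: %d isolated patch(es) in %d cluster(s)",
        tok, sum(patch_sets[[tok]]$table$isolated),
        length(unique(patch_sets[[tok]]$table$cluster[
          patch_sets[[tok]]$table$isolated])))
  }
  result$surfaces <- surfaces
  result$patches <- patch_sets
  result$suitability <- suit
  result$suitability_model <- suit_model
  result$status <- "ok"
  result$log <- logs
  class(result) <- "pipeline_run"
  write_outputs(result, get("out_dir"))
}

load_input <- function(x, reader, what) {
  if (is.null(x)) stop("config is missing '", what, "'")
  if (is.character(x)) reader(x) else x
}

load_stack <- function(env) {
  if (is.null(env)) stop("config is missing 'env'")
  if (is.list(env) && all(vapply(env, inherits, TRUE, "raster_grid"))) return(env)
  if (is.character(env)) {
    paths <- strsplit(env, "[,;]")[[1]]
    paths <- trimws(paths)
    stack <- lapply(paths, read_raster)
    names(stack) <- tools::file_path_sans_ext(basename(paths))
    return(stack)
  }
  stop("'env' must be a named list of rasters or a comma-separated path list")
}

write_outputs <- function(result, out_dir) {
  if (is.null(out_dir)) return(result)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(result$fst, file.path(out_dir, "fst_matrix.csv"))
  write.csv(result$scan$table, file.path(out_dir, "scan_table.csv"),
            row.names = FALSE)
  if (!is.null(result$surfaces)) {
    for (tok in names(result$surfaces)) {
      write_raster(result$surfaces[[tok]],
                   file.path(out_dir, sprintf("connectivity_%s.asc", tok)))
      ps <- result$patches[[tok]]
      write_raster(ps$labels,
                   file.path(out_dir, sprintf("patches_%s.asc", tok)))
      write.csv(ps$table, file.path(out_dir, sprintf("patches_%s.csv", tok)),
                row.names = FALSE)
    }
    write_raster(result$suitability, file.path(out_dir, "suitability.asc"))
  }
  writeLines(c(sprintf("seed: %d", result$seed), result$log),
             file.path(out_dir, "run.log"))
  result
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> status:", x$status, "\n")
  cat(sprintf("  Mantel IBD: r = %.3f, p = %.4g\n", x$mantel$r, x$mantel$p))
  if (length(x$selected_variables))
    cat("  selected variable(s):", paste(x$selected_variables, collapse = ", "), "\n")
  if (!is.null(x$patches))
    for (tok in names(x$patches))
      cat(sprintf("  [%s] %d patches, %d isolated\n", tok,
                  nrow(x$patches[[tok]]$table),
                  sum(x$patches[[tok]]$table$isolated)))
  invisible(x)
}
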