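#' Read and write applied-mass tables
#'
#' CSV with the exact header `major_group, crop, country, mass_kg`,
#' deterministic row order (sorted keys), UTF-8.
#'
#' @param tab a `mass_table`.
#' @param path CSV path.
#' @param role role tag attached on read.
#' @return `write_mass_table` returns `path` invisibly; `read_mass_table`
#'   a `mass_table`.
#' @export
write_mass_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab)[c("major_group", "crop", "country",
                                        "mass_kg")],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_mass_table
#' @export
read_mass_table <- function(path, role = "first_guess") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("major_group", "crop", "country", "mass_kg")
  if (!all(need %in% names(tab)))
    stop("malformed mass table ", path, ": expected columns ",
         paste(need, collapse = ", "))
  mass_table(tab$major_group, tab$crop, tab$country, tab$mass_kg, role = role)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full estimation pipeline on a synthetic scenario
#'
#' Executes the seven stages in order — crop fusion, rate projection,
#' calibration-data preparation, maximum-likelihood calibration,
#' Monte-Carlo propagation, scenario map generation, quality indexing and
#' validation — writing every tabular product and scenario/QI raster to
#' `out_dir`, plus a JSON manifest recording seeds, per-stage record
#' counts and the calibrated parameters. Deterministic given the scenario
#' seed and `mc_seed`.
#'
#' @param s a [synthetic_scenario].
#' @param out_dir output directory.
#' @param tax `pesticide_taxonomy`.
#' @param banned optional data frame (`ai_name`, `country`) of bans.
#' @param mc_n Monte-Carlo sample size (default 1000).
#' @param mc_seed seed of the Monte-Carlo stage (default derived from the
#'   scenario seed).
#' @param threshold_kg minimum reference mass retained (default 100).
#' @return the manifest, invisibly; all products are on disk.
#' @export
run_pipeline <- function(s, out_dir, tax = load_taxonomy(), banned = NULL,
                         mc_n = 1000, mc_seed = stage_seed(s$seed, "mc"),
                         threshold_kg = 100) {
  if (!inherits(s, "synthetic_scenario")) stop("`s` must be a synthetic_scenario")
  if (!inherits(tax, "pesticide_taxonomy"))
    stop("`tax` must be a pesticide_taxonomy from load_taxonomy()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  regions <- load_regions()
  manifest <- list(seed = s$seed, mc_seed = mc_seed, stages = list())
  log_stage <- function(stage_name, info) {
    manifest$stages[[stage_name]] <<- info
  }

  ## 1. crop fusion
  bundle <- with_stage("fuse", {
    b <- gen_crop_raster(s)
    fused <- apply_corine_corrections(b$fine, b$corine)
    crops250 <- aggregate_labels(modal_upscale(fused, s$upscale_factor))
    countries250 <- modal_upscale(b$countries, s$upscale_factor)
    write_raster(crops250, file.path(out_dir, "crops.asc"))
    write_raster(countries250, file.path(out_dir, "countries.asc"))
    list(crops = crops250, countries = countries250,
         country_table = b$country_table,
         rule_counts = attr(fused, "rule_counts"))
  })
  log_stage("fuse", list(rule_counts = as.list(bundle$rule_counts),
                         cells = prod(dim(bundle$crops))))

  ## 2. projection + authorization + first-guess mass
  auth <- gen_authorizations(s, banned)
  fine_by_ai <- with_stage("project", {
    out <- lapply(s$ai_list, function(ai) {
      fine <- project_apr(gen_coarse_apr(s, ai), bundle$crops)
      apply_authorization(fine, ai, auth, bundle$countries, bundle$country_table)
    })
    stats::setNames(out, s$ai_list)
  })
  m_tilde <- with_stage("project",
    first_guess_mass(fine_by_ai, bundle$crops, bundle$countries,
                     bundle$country_table, tax))
  write_mass_table(m_tilde, file.path(out_dir, "first_guess_mass.csv"))
  log_stage("project", list(n_ai = length(fine_by_ai), n_keys = nrow(m_tilde)))

  ## 3. reference data assembly
  ref <- with_stage("prepare", {
    g <- gen_reference_masses(s, m_tilde, tax)
    m_star <- prepare_calibration(g$records, tax, window = s$years,
                                  threshold = threshold_kg)
    list(gen = g, m_star = m_star)
  })
  write_mass_table(ref$m_star, file.path(out_dir, "reference_mass.csv"))
  log_stage("prepare", list(n_records = nrow(ref$gen$records),
                           n_reference = nrow(ref$m_star),
                           n_dropped_sparsity = length(ref$gen$dropped)))

  ## 4. calibration per major group
  mgs <- intersect(unique(m_tilde$major_group), unique(ref$m_star$major_group))
  if (!length(mgs))
    stop("stage [calibrate] failed: no major group present in both the ",
         "first-guess and reference tables (reference table may be empty ",
         "after the ", threshold_kg, " kg filter)", call. = FALSE)
  fits <- with_stage("calibrate", {
    out <- lapply(mgs, function(mg) {
      fit <- suppressWarnings(calibrate(
        m_tilde[m_tilde$major_group == mg, ],
        ref$m_star[ref$m_star$major_group == mg, ], regions))
      jsonlite::write_json(
        list(major_group = mg, k_hat = as.list(unclass(fit$k_hat)),
             sigma = as.list(fit$sigma), J_min = fit$J_min, NLL = fit$NLL,
             n_obs = fit$n_obs),
        file.path(out_dir, paste0("calibration_", mg, ".json")),
        auto_unbox = TRUE, digits = NA)
      fit
    })
    stats::setNames(out, mgs)
  })
  m_hat <- do.call(rbind, lapply(fits, `[[`, "fitted"))
  m_hat <- mass_table(m_hat$major_group, m_hat$crop, m_hat$country,
                      m_hat$mass_kg, role = "fitted")
  write_mass_table(m_hat, file.path(out_dir, "fitted_mass.csv"))
  log_stage("calibrate", list(groups = mgs,
                             J_min = lapply(fits, `[[`, "J_min"),
                             NLL = lapply(fits, `[[`, "NLL")))

  ## 5. Monte-Carlo propagation
  no_sigma <- mgs[vapply(fits, function(f) anyNA(f$sigma), TRUE)]
  if (length(no_sigma)) {
    message("group(s) without posterior uncertainty (n_obs <= 7) skipped ",
            "beyond calibration: ", paste(no_sigma, collapse = ", "))
    mgs <- setdiff(mgs, no_sigma)
    if (!length(mgs))
      stop("stage [propagate] failed: no group has enough calibration keys ",
           "for uncertainty propagation", call. = FALSE)
  }
  scenarios <- with_stage("propagate", {
    per_mg <- lapply(mgs, function(mg) {
      draws <- sample_parameters(fits[[mg]], n = mc_n,
                                 seed = stage_seed(mc_seed, mg))
      scenario_quartiles(propagate(draws, m_tilde[m_tilde$major_group == mg, ],
                                   regions), seed = mc_seed)
    })
    tab <- do.call(rbind, per_mg)
    attr(tab, "n_realizations") <- mc_n
    attr(tab, "seed") <- mc_seed
    class(tab) <- c("scenario_mass_table", "data.frame")
    tab
  })
  sc_out <- as.data.frame(scenarios)
  sc_out$n <- mc_n
  sc_out$seed <- mc_seed
  utils::write.csv(sc_out, file.path(out_dir, "scenario_mass.csv"),
                   row.names = FALSE)
  log_stage("propagate", list(n = mc_n, n_keys = nrow(scenarios)))

  ## 6. scenario maps
  K <- with_stage("maps", correction_factors(scenarios,
                                             m_tilde[m_tilde$major_group %in% mgs, ]))
  utils::write.csv(K, file.path(out_dir, "correction_factors.csv"),
                   row.names = FALSE)
  maps <- with_stage("maps", {
    grids <- list()
    for (ai in s$ai_list) {
      if (!tax$major_group[tax$ai_name == ai] %in% mgs) next
      for (sc in c("Low", "Median", "High"))
        grids[[paste(ai, sc)]] <- suppressWarnings(apply_correction(
          fine_by_ai[[ai]], K, bundle$crops, bundle$countries,
          bundle$country_table, tax, ai, sc, regions))
    }
    write_scenario_maps(grids, file.path(out_dir, "maps"))
  })
  log_stage("maps", list(n_files = length(maps)))

  ## 7. quality index + validation ratio
  qi <- with_stage("qi", qi_with_fallback(m_hat, ref$m_star,
                                          m_tilde[m_tilde$major_group %in% mgs,
                                                  c("major_group", "crop", "country")],
                                          regions))
  utils::write.csv(qi, file.path(out_dir, "qi.csv"), row.names = FALSE)
  ai_mg <- tax$major_group[match(s$ai_list, tax$ai_name)]
  for (mg in mgs) {
    ai <- s$ai_list[match(mg, ai_mg)]
    if (is.na(ai)) next
    qr <- with_stage("qi", qi_raster(qi, bundle$crops, bundle$countries,
                                     bundle$country_table, tax, ai))
    write_raster(qr, file.path(out_dir, paste0("QI_", mg, ".asc")))
  }
  ratios <- with_stage("qi", validation_ratio(scenarios, ref$m_star))
  utils::write.csv(ratios, file.path(out_dir, "validation_ratio.csv"),
                   row.names = FALSE)
  log_stage("qi", list(n_qi = nrow(qi),
                      n_fallback = sum(qi$flag == "region_fallback"),
                      n_ratios = nrow(ratios)))

  manifest$completed <- names(manifest$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
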