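# end-to-end orchestration: simulate -> clean/fit -> phenotypes ->
# heritability/correlations -> adaptive differentiation -> GWAS

#' Validate pipeline input tables
#'
#' Schema and cross-consistency checks on the pipeline inputs: required
#' columns, positive areas, monotone within-plant times, and accession
#' coverage between tables. Checks never throw; findings are returned as a
#' machine-readable report with severity levels.
#'
#' @param phenotypes long phenotype tibble.
#' @param genotypes optional genotype matrix (accessions x SNPs).
#' @param climate optional climate tibble with `accession`.
#' @param seed_size optional seed-size tibble with `accession`.
#' @return a tibble with `severity` (`"error"`/`"warning"`/`"ok"`), `check`
#'   and `message`.
#' @export
validate_inputs <- function(phenotypes, genotypes = NULL, climate = NULL,
                            seed_size = NULL) {
  rep <- list()
  add <- function(severity, check, message) {
    rep[[length(rep) + 1]] <<- tibble::tibble(
      severity = severity, check = check, message = message)
  }
  need <- c("plant_id", "accession", "time_dap", "area")
  missing <- setdiff(need, names(phenotypes))
  if (length(missing)) {
    add("error", "phenotype_schema",
        paste("missing columns:", paste(missing, collapse = ", ")))
  } else {
    add("ok", "phenotype_schema", "all required columns present")
    if (any(phenotypes$area <= 0, na.rm = TRUE)) {
      add("error", "positive_areas", "non-positive rosette areas present")
    } else add("ok", "positive_areas", "all areas positive")
    nonmono <- phenotypes |>
      dplyr::group_by(.data$plant_id) |>
      dplyr::summarise(bad = is.unsorted(.data$time_dap, strictly = TRUE),
                       .groups = "drop") |>
      dplyr::filter(.data$bad)
    if (nrow(nonmono)) {
      add("warning", "monotone_times",
          sprintf("%d plant(s) with non-increasing times (e.g. %s)",
                  nrow(nonmono), nonmono$plant_id[1]))
    } else add("ok", "monotone_times", "times strictly increasing per plant")
    pheno_acc <- unique(phenotypes$accession)
    check_cover <- function(ids, what) {
      miss <- setdiff(pheno_acc, ids)
      if (length(miss)) {
        add("error", paste0(what, "_coverage"),
            sprintf("accession(s) in phenotypes but absent from %s: %s",
                    what, paste(utils::head(miss, 5), collapse = ", ")))
      } else {
        add("ok", paste0(what, "_coverage"),
            sprintf("all phenotype accessions present in %s", what))
      }
    }
    if (!is.null(genotypes)) check_cover(rownames(genotypes), "genotypes")
    if (!is.null(climate)) check_cover(climate$accession, "climate")
    if (!is.null(seed_size)) check_cover(seed_size$accession, "seed_size")
  }
  dplyr::bind_rows(rep)
}

pipeline_defaults <- function() {
  list(car1 = TRUE, method = "ML", n_tested_pcs = 10,
       maf_threshold = 0.10, alpha = 0.05, exact_lmm = FALSE,
       gwas_trait = "r16")
}

file_hash <- function(paths) {
  unname(tools::md5sum(paths[file.exists(paths)]))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: simulate (or load) the study
#' tables, validate, clean and fit the hierarchical growth model, derive
#' accession and plant phenotypes, estimate heritabilities and climate
#' correlations (kinship-corrected for winter temperature), test adaptive
#' differentiation along kinship PCs, and run the association scan. Each
#' stage writes plain-text tables under `out_dir`; a manifest JSON records
#' inputs, outputs, hashes, timing and the seed. Stages whose output files
#' already exist with matching input hashes are skipped.
#'
#' @param config a named list (or path to a YAML file) with elements
#'   `out_dir`, `seed`, either `sim` (arguments for [sim_config()]) or
#'   `inputs` (paths: `phenotypes`, `genotypes`, `climate`, `seed_size`),
#'   and an optional `options` block (`car1`, `method`, `n_tested_pcs`,
#'   `maf_threshold`, `alpha`, `exact_lmm`, `gwas_trait`).
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  opts <- utils::modifyList(pipeline_defaults(), config$options %||% list())
  manifest_path <- file.path(out, "manifest.json")
  old_manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  ## hash only the scientific configuration, not filesystem paths
  cfg_hash <- substr(digest_config(config[intersect(
    c("seed", "sim", "options"), names(config))]), 1, 8)

  manifest <- list(package = "thermogrowth",
                   version = as.character(utils::packageVersion("thermogrowth")),
                   seed = seed, config_hash = cfg_hash,
                   stages = list())
  stage <- function(name, inputs, outputs, fun) {
    t0 <- proc.time()[["elapsed"]]
    in_hash <- file_hash(inputs)
    prev <- NULL
    if (!is.null(old_manifest$stages)) {
      prev <- old_manifest$stages[[name]]
    }
    up_to_date <- all(file.exists(outputs)) && !is.null(prev) &&
      identical(unname(unlist(prev$input_md5)), unname(in_hash)) &&
      identical(unname(unlist(prev$output_md5)), unname(file_hash(outputs)))
    if (up_to_date) {
      manifest$stages[[name]] <<- prev
      message(sprintf("[%s] up to date, skipped", name))
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(
      inputs = inputs, outputs = outputs,
      input_md5 = as.list(in_hash),
      output_md5 = as.list(file_hash(outputs)),
      seconds = round(proc.time()[["elapsed"]] - t0, 2), seed = seed)
    res
  }
  paths <- list(
    phenotypes = file.path(out, "phenotypes.csv"),
    genotypes = file.path(out, "genotypes.tsv"),
    climate = file.path(out, "climate.csv"),
    seed_size = file.path(out, "seed_size.csv"),
    truth = file.path(out, "truth.json"),
    accession_phenotypes = file.path(out, "accession_phenotypes.tsv"),
    model_fit = file.path(out, "model_fit.json"),
    heritability = file.path(out, "heritability.tsv"),
    kinship = file.path(out, "kinship.tsv"),
    correlations = file.path(out, "correlations.tsv"),
    qpc = file.path(out, "qpc_results.tsv"),
    envelope = file.path(out, "qpc_envelope.tsv"),
    gwas = file.path(out, "gwas.tsv"),
    qq = file.path(out, "gwas_qq.tsv"))

  ## stage: simulate or load inputs --------------------------------------
  if (!is.null(config$sim)) {
    stage("simulate", character(0),
          unlist(paths[c("phenotypes", "genotypes", "climate", "seed_size",
                         "truth")]), function() {
      sim_args <- utils::modifyList(config$sim, list(seed = seed))
      ## YAML configs deliver vectors as lists
      for (nm in c("timepoints", "winter_temp_range")) {
        if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
      }
      for (nm in c("target_h2", "target_climate_r", "trait_means",
                   "trait_scales", "experiment_sd")) {
        if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
      }
      cfg <- do.call(sim_config, sim_args)
      study <- simulate_study(cfg)
      write_table_auto(study$phenotypes, paths$phenotypes, seed, cfg_hash)
      write_genotypes(study$truth$genotypes, paths$genotypes, seed, cfg_hash)
      acc <- study$truth$accessions
      write_table_auto(acc[, c("accession", "pop", "winter_temp")],
                       paths$climate, seed, cfg_hash)
      write_table_auto(acc[, c("accession", "seed_size")],
                       paths$seed_size, seed, cfg_hash)
      jsonlite::write_json(
        list(accessions = acc, plant_sd = as.list(study$truth$plant_sd)),
        paths$truth, auto_unbox = TRUE, digits = NA)
    })
    map_tbl <- NULL
  } else {
    stopifnot(!is.null(config$inputs))
    for (nm in names(config$inputs)) paths[[nm]] <- config$inputs[[nm]]
    map_tbl <- NULL
  }

  pheno <- read_phenotypes(paths$phenotypes)
  G <- read_genotypes(paths$genotypes)
  climate <- read_table_auto(paths$climate)
  seed_tbl <- if (file.exists(paths$seed_size))
    read_table_auto(paths$seed_size) else NULL

  ## stage: validate -------------------------------------------------------
  report <- validate_inputs(pheno, G, climate, seed_tbl)
  if (any(report$severity == "error")) {
    print(report[report$severity == "error", ])
    rlang::abort("input validation failed")
  }

  ## stage: growth model ----------------------------------------------------
  stage("fit_growth", unlist(paths["phenotypes"]),
        unlist(paths[c("accession_phenotypes", "model_fit",
                       "heritability")]), function() {
    cleaned <- clean_series(pheno)
    fit <- fit_stage2(cleaned, car1 = opts$car1, method = opts$method)
    accs <- accession_estimates(fit)
    write_table_auto(accs, paths$accession_phenotypes, seed, cfg_hash)
    jsonlite::write_json(
      list(glance = glance(fit), fixed_effects = tidy(fit)),
      paths$model_fit, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    pp <- plant_estimates(fit)
    h2 <- dplyr::bind_rows(
      heritability(pp, "M0"),
      heritability(pp, "r", temperature = 16),
      heritability(pp, "r", temperature = 6))
    write_table_auto(h2, paths$heritability, seed, cfg_hash)
  })
  accs <- read_table_auto(paths$accession_phenotypes)

  ## stage: kinship + correlations ------------------------------------------
  stage("quantgen", unlist(paths[c("genotypes", "accession_phenotypes",
                                   "climate")]),
        unlist(paths[c("kinship", "correlations")]), function() {
    kin <- kinship_centered(G)
    write_kinship(kin, paths$kinship)
    traits <- intersect(c("M0", "r16", "r6", "response"), names(accs))
    clim_vars <- setdiff(names(climate)[vapply(climate, is.numeric, TRUE)],
                         "accession")
    plain <- pearson_correlations(accs, climate, traits, clim_vars)
    corr <- purrr::map(traits, function(tr) {
      d <- dplyr::left_join(accs, climate, by = "accession")
      kinship_corrected_correlation(d, tr, clim_vars[1], kin)
    }) |> dplyr::bind_rows()
    out_tbl <- dplyr::left_join(
      plain, corr[, c("trait", "variable", "r_corrected", "p_corrected")],
      by = c("trait", "variable"))
    write_table_auto(out_tbl, paths$correlations, seed, cfg_hash)
  })
  kin <- read_kinship(paths$kinship)

  ## stage: adaptive differentiation -----------------------------------------
  stage("qpc", unlist(paths[c("kinship", "accession_phenotypes")]),
        unlist(paths[c("qpc", "envelope")]), function() {
    traits <- intersect(c("M0", "r16", "r6", "response"), names(accs))
    scr <- qpc_screen(accs, kin, traits = traits,
                      n_tested = opts$n_tested_pcs, alpha = opts$alpha)
    write_table_auto(scr$summary, paths$qpc, seed, cfg_hash)
    env <- purrr::map(names(scr$results), function(tr) {
      top <- scr$results[[tr]]$stats
      pc <- top$pc[which.max(top$F)]
      dplyr::mutate(neutral_envelope(scr$results[[tr]], pc = pc),
                    trait = tr, pc = pc, .before = 1)
    }) |> dplyr::bind_rows()
    write_table_auto(env, paths$envelope, seed, cfg_hash)
  })

  ## stage: association scan ---------------------------------------------------
  stage("gwas", unlist(paths[c("genotypes", "accession_phenotypes",
                               "kinship")]),
        unlist(paths[c("gwas", "qq")]), function() {
    tr <- opts$gwas_trait
    if (!tr %in% names(accs)) tr <- setdiff(names(accs), "accession")[1]
    y <- stats::setNames(accs[[tr]], accs$accession)
    map_tbl <- map_from_ids(colnames(G))
    scan <- lmm_scan(y, G, kin, map = map_tbl,
                     maf_threshold = opts$maf_threshold,
                     exact = opts$exact_lmm)
    write_table_auto(tibble::as_tibble(scan), paths$gwas, seed, cfg_hash)
    write_table_auto(qq_data(scan$p[is.finite(scan$p)]), paths$qq, seed,
                     cfg_hash)
  })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

# recover (chr, pos) from SNP ids of the form chr<k>_<pos>; NULL otherwise
map_from_ids <- function(ids) {
  m <- regmatches(ids, regexec("^chr([0-9]+)_([0-9]+)$", ids))
  if (!all(lengths(m) == 3)) return(NULL)
  tibble::tibble(id = ids,
                 chr = as.integer(vapply(m, `[`, "", 2)),
                 pos = as.integer(vapply(m, `[`, "", 3)))
}

digest_config <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), tf)
  unname(tools::md5sum(tf))
}
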