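# Orchestration: run the full analysis from one dataset/config and collect a
# reproducible results bundle; group contrasts by phenology.

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: phylogenetic signal tests, nested variance
#' decompositions, per-variable mixed-model environment screens, the PVR
#' partitions (plain and interaction variants), and the node-contribution
#' report. Stage failures are isolated: a failing stage is recorded in the
#' bundle's `errors` with its message while the remaining stages complete.
#'
#' @param dataset A `matched_dataset` (from [harmonize()] or
#'   [simulate_sla_dataset()]).
#' @param config A list of options: `n_perm` (default 999), `seed` (default
#'   1), `classes` (partition classes), `variants` (default both),
#'   `nestings` (named list of nesting column vectors; default spatial
#'   `site_id`/`species`), `screen_vars` (default the class variables),
#'   `eigvec_threshold` (default 1), `quad_screen` (default TRUE),
#'   `ci_floor` (default 0.005), `stages` (character subset to run).
#' @return An object of class `sla_analysis`: list with `signals`,
#'   `variance_components`, `env_screens`, `partitions`, `node_contributions`,
#'   `provenance`, and `errors`.
#' @export
run_full_analysis <- function(dataset, config = list()) {
  stopifnot(inherits(dataset, "matched_dataset"))
  cfg <- list(
    n_perm = config$n_perm %||% 999,
    seed = config$seed %||% 1,
    classes = config$classes %||% list(climate = default_climate_class(),
                                       soil = default_soil_class()),
    variants = config$variants %||% c("plain", "interactions"),
    nestings = config$nestings %||% list(spatial = c("site_id", "species")),
    screen_vars = config$screen_vars,
    eigvec_threshold = config$eigvec_threshold %||% 1,
    quad_screen = config$quad_screen %||% TRUE,
    ci_floor = config$ci_floor %||% 0.005,
    stages = config$stages %||% c("signals", "variance", "screens",
                                  "partition", "aot")
  )
  errors <- list()
  run_stage <- function(name, expr) {
    if (!name %in% cfg$stages) return(NULL)
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  signals <- run_stage("signals", phylo_signal(
    dataset, n_perm = cfg$n_perm, seed = stage_seed(cfg$seed, 11)))

  vcomp <- run_stage("variance", {
    out <- lapply(names(cfg$nestings), function(nm) {
      variance_decomposition(dataset, cfg$nestings[[nm]], label = nm)
    })
    names(out) <- names(cfg$nestings)
    out
  })

  screens <- run_stage("screens", {
    vars <- cfg$screen_vars %||% c(cfg$classes$climate, cfg$classes$soil)
    out <- lapply(vars, function(v) {
      tryCatch(env_screen(dataset, v), error = function(e) NULL)
    })
    names(out) <- vars
    Filter(Negate(is.null), out)
  })

  quad_flags <- if (!is.null(screens)) {
    names(Filter(function(s) s$degree == 2, screens))
  } else NULL

  partitions <- run_stage("partition", {
    classes <- cfg$classes
    if (cfg$quad_screen && is.null(classes$quadratic)) {
      classes$quadratic <- quad_flags %||% character(0)
    }
    out <- lapply(cfg$variants, function(v) {
      pvr_partition(dataset, classes = classes, variant = v,
                    eigvec_threshold = cfg$eigvec_threshold)
    })
    names(out) <- cfg$variants
    out
  })

  aot <- run_stage("aot", aot_report(
    dataset$tree, species_trait(dataset),
    n_perm = cfg$n_perm, seed = stage_seed(cfg$seed, 13),
    ci_floor = cfg$ci_floor))

  structure(
    list(signals = signals, variance_components = vcomp,
         env_screens = screens, partitions = partitions,
         node_contributions = aot,
         provenance = list(
           seed = cfg$seed, n_perm = cfg$n_perm,
           n_records = nrow(dataset$records),
           n_species = length(dataset$species_index),
           drop_report = dataset$drop_report,
           config = cfg,
           package_version = as.character(utils::packageVersion("pvrpart"))),
         errors = errors),
    class = "sla_analysis"
  )
}

#' @export
print.sla_analysis <- function(x, ...) {
  cat("Full trait-variance analysis\n")
  pv <- x$provenance
  cat(sprintf("  %d records, %d species (seed %d)\n",
              pv$n_records, pv$n_species, pv$seed))
  done <- c(signals = !is.null(x$signals),
            variance = !is.null(x$variance_components),
            screens = !is.null(x$env_screens),
            partition = !is.null(x$partitions),
            aot = !is.null(x$node_contributions))
  cat("  stages completed:", paste(names(done)[done], collapse = ", "), "\n")
  if (length(x$errors)) {
    cat("  stage errors:\n")
    for (nm in names(x$errors)) cat("    ", nm, ": ", x$errors[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Phenology contrast of the PVR partition
#'
#' Runs the interaction-variant partition separately for evergreen and
#' deciduous woody angiosperm records (tree re-pruned per group), mirroring
#' the leaf-longevity contrast. A group below `min_records` is skipped with
#' a warning rather than failing the other side.
#'
#' @param dataset A `matched_dataset` whose records carry `phenology`,
#'   `woody`, and `clade` columns.
#' @param min_records Minimum records per group (default 30).
#' @param min_species Minimum species per group (default 10).
#' @param ... Passed to [pvr_partition()].
#' @return A named list of `pvr_partition` objects (`evergreen`,
#'   `deciduous`), possibly with one side missing.
#' @export
phenology_contrast <- function(dataset, min_records = 30, min_species = 10, ...) {
  stopifnot(inherits(dataset, "matched_dataset"))
  rec <- dataset$records
  woody_angio <- (rec$woody %in% TRUE) &
    !is.na(rec$clade) & rec$clade != "gymnosperm" &
    rec$phenology %in% c("evergreen", "deciduous")
  out <- list()
  for (ph in c("deciduous", "evergreen")) {
    sub <- rec[woody_angio & rec$phenology == ph, , drop = FALSE]
    if (nrow(sub) < min_records || length(unique(sub$species)) < min_species) {
      warning("phenology group '", ph, "' below minimum size; skipped")
      next
    }
    ds <- harmonize(sub, dataset$tree)
    out[[ph]] <- pvr_partition(ds, variant = "interactions", ...)
  }
  out
}

#' Write a results bundle to disk
#'
#' Serializes the tables of an `sla_analysis` as TSV files plus one JSON
#' provenance/summary file in `dir`.
#'
#' @param bundle An `sla_analysis` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sla_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$signals)) wt(as.data.frame(bundle$signals), "signals")
  if (!is.null(bundle$variance_components)) {
    for (nm in names(bundle$variance_components)) {
      wt(as.data.frame(bundle$variance_components[[nm]]),
         paste0("variance_", nm))
    }
  }
  if (!is.null(bundle$env_screens)) {
    df <- do.call(rbind, lapply(bundle$env_screens, function(s) {
      data.frame(variable = s$variable, degree = s$degree,
                 aic_linear = s$aic["linear"], aic_quadratic = s$aic["quadratic"],
                 r2_marginal = s$r2_marginal, n = s$n)
    }))
    wt(df, "env_screens")
  }
  if (!is.null(bundle$partitions)) {
    df <- do.call(rbind, lapply(names(bundle$partitions), function(v) {
      p <- bundle$partitions[[v]]
      data.frame(variant = v,
                 component = c(names(p$components), "total_P", "total_C",
                               "total_S", "intraspecific", "unexplained"),
                 percent = 100 * c(unname(p$components), unname(p$totals),
                                   p$intraspecific, p$unexplained))
    }))
    wt(df, "partition")
  }
  if (!is.null(bundle$node_contributions)) {
    wt(as.data.frame(bundle$node_contributions), "node_contributions")
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    p <- file.path(dir, "provenance.json")
    jsonlite::write_json(bundle$provenance, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
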