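#' Read a trait record table
#'
#' Reads a CSV/TSV table of trait records (one row per measurement), maps
#' arbitrary source headers onto the package's standard column names, checks
#' domain invariants, and computes the log10-transformed response.
#'
#' Standard columns are `species`, `site_id`, `sla` (cm^2 g^-1, must be
#' positive), eight climate variables (`par`, `mat`, `mtcm`, `mthm`, `map`,
#' `mi`, `alpha`, `precip_seasonality`), eight soil variables (`sand_frac`,
#' `silt_frac`, `clay_frac`, `ph`, `org_c`, `cec`, `tn`, `tp`), and the
#' categorical labels `clade` (gymnosperm/magnoliid/monocot/eudicot),
#' `phenology` (evergreen/deciduous/unknown) and `woody` (logical). Only
#' `species`, `site_id` and `sla` are mandatory; missing numeric cells become
#' `NA` and are handled listwise by the downstream models.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector mapping standard names to
#'   source headers, e.g. `c(sla = "SLA.cm2.g", species = "Species_name")`.
#'   Standard names already present in the file need not be mapped.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` are read as tab-separated, anything else as comma).
#' @return A `data.frame` of trait records with standardized columns,
#'   including `log_sla = log10(sla)`.
#' @export
read_trait_table <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop_pvr("trait table not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", "", "NaN"))
  standardize_trait_records(raw, column_map = column_map)
}

#' Standardize an in-memory trait record table
#'
#' Applies the same column mapping, validation and response transform as
#' [read_trait_table()] to a data frame already in memory.
#'
#' @param raw A data frame of raw records.
#' @inheritParams read_trait_table
#' @return A standardized `data.frame` of trait records.
#' @export
standardize_trait_records <- function(raw, column_map = NULL) {
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src)) {
      stop_pvr("mapped source column(s) absent from table: ",
               paste(missing_src, collapse = ", "))
    }
    for (std in names(column_map)) names(raw)[names(raw) == column_map[[std]]] <- std
  }
  mandatory <- c("species", "site_id", "sla")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent)) {
    stop_pvr("mandatory column(s) missing: ", paste(absent, collapse = ", "))
  }

  numeric_cols <- c("sla", climate_vars(), soil_vars())
  for (v in intersect(numeric_cols, names(raw))) {
    raw[[v]] <- suppressWarnings(as.numeric(raw[[v]]))
  }

  bad_species <- which(is.na(raw$species) | !nzchar(trimws(raw$species)))
  if (length(bad_species)) {
    stop_pvr("empty species name in row(s): ", paste(bad_species, collapse = ", "))
  }
  bad_sla <- which(is.na(raw$sla) | raw$sla <= 0)
  if (length(bad_sla)) {
    stop_pvr("non-positive or missing SLA in row(s): ",
             paste(bad_sla, collapse = ", "))
  }

  out <- data.frame(
    species = normalize_species(raw$species),
    site_id = as.character(raw$site_id),
    sla = raw$sla,
    log_sla = log10(raw$sla),
    stringsAsFactors = FALSE
  )
  for (v in c(climate_vars(), soil_vars())) {
    out[[v]] <- if (v %in% names(raw)) raw[[v]] else NA_real_
  }
  out$clade <- if ("clade" %in% names(raw)) tolower(as.character(raw$clade)) else NA_character_
  known_clades <- c("gymnosperm", "magnoliid", "monocot", "eudicot", "angiosperm")
  odd <- setdiff(unique(out$clade[!is.na(out$clade)]), known_clades)
  if (length(odd)) warning("unrecognized clade label(s): ", paste(odd, collapse = ", "))
  out$phenology <- if ("phenology" %in% names(raw)) {
    tolower(as.character(raw$phenology))
  } else "unknown"
  out$phenology[is.na(out$phenology)] <- "unknown"
  out$woody <- if ("woody" %in% names(raw)) as.logical(raw$woody) else NA

  validate_env_ranges(out)
  out
}

## Soft range checks for the environment profiles; violations warn rather than
## stop because field databases carry occasional unit slips worth surfacing.
validate_env_ranges <- function(records) {
  warn_if <- function(cond, msg) {
    n <- sum(cond, na.rm = TRUE)
    if (n > 0) warning(sprintf("%d record(s) %s", n, msg), call. = FALSE)
  }
  for (v in c("sand_frac", "silt_frac", "clay_frac")) {
    warn_if(records[[v]] < 0 | records[[v]] > 1,
            paste("with", v, "outside [0, 1]"))
  }
  warn_if(records$ph <= 0 | records$ph >= 14, "with pH outside (0, 14)")
  warn_if(records$map < 0, "with negative MAP")
  warn_if(records$mi < 0, "with negative moisture index")
  both <- !is.na(records$mtcm) & !is.na(records$mthm)
  warn_if(both & records$mtcm > records$mthm, "with MTCM > MTHM")
  invisible(records)
}

#' Read and validate a rooted phylogeny
#'
#' Reads a Newick tree and checks the invariants the downstream matrix
#' derivations rely on: branch lengths present and non-negative, unique tip
#' labels, a single root. Polytomies are allowed.
#'
#' @param path Path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop_pvr("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop_pvr("could not parse Newick tree: ", path)
  validate_tree(tree)
}

#' Validate a phylo object
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly usable, after validation.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_pvr("not a phylo object")
  if (is.null(tree$edge.length)) stop_pvr("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop_pvr("tree has missing branch lengths")
  neg <- which(tree$edge.length < 0)
  if (length(neg)) {
    stop_pvr("negative branch length on edge(s) to node(s): ",
             paste(tree$edge[neg, 2], collapse = ", "))
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop_pvr("duplicate tip label(s): ", paste(dup, collapse = ", "))
  }
  ## exactly one parentless node; basal polytomies are legitimate roots
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1) stop_pvr("tree must have exactly one root")
  tree
}

#' Join trait records to a phylogeny
#'
#' Prunes the tree to the species present in the record table, drops records
#' whose species is not a tip, optionally filters by clade, and returns the
#' analysis-ready dataset every downstream stage consumes. Species are matched
#' exactly on underscore-normalized binomials; no fuzzy matching is attempted.
#'
#' @param records A standardized trait record table
#'   (see [read_trait_table()]).
#' @param tree A validated `phylo` object.
#' @param clade_filter Optional character vector of clade labels to retain.
#' @return An object of class `matched_dataset`: a list with `records`,
#'   the pruned `tree`, `species_index` (species -> tip number), and a
#'   `drop_report` accounting for every removed record and tip.
#' @export
harmonize <- function(records, tree, clade_filter = NULL) {
  validate_tree(tree)
  n_in <- nrow(records)
  records$species <- normalize_species(records$species)
  tree$tip.label <- normalize_species(tree$tip.label)

  dropped_clade <- 0L
  if (!is.null(clade_filter)) {
    keep <- !is.na(records$clade) & records$clade %in% tolower(clade_filter)
    dropped_clade <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }

  shared <- intersect(unique(records$species), tree$tip.label)
  if (length(shared) < 2) {
    stop_pvr("fewer than 2 species shared between records and tree")
  }
  dropped_records <- sum(!records$species %in% shared)
  records <- records[records$species %in% shared, , drop = FALSE]
  dropped_tips <- sum(!tree$tip.label %in% shared)
  tree <- ape::keep.tip(tree, shared)

  rownames(records) <- NULL
  species_index <- setNames(match(tree$tip.label, tree$tip.label), tree$tip.label)
  drop_report <- list(
    input_records = n_in,
    retained_records = nrow(records),
    dropped_clade_filter = dropped_clade,
    dropped_unmatched_records = dropped_records,
    dropped_tips = dropped_tips
  )
  structure(
    list(records = records, tree = tree, species_index = species_index,
         drop_report = drop_report),
    class = "matched_dataset"
  )
}

#' @export
print.matched_dataset <- function(x, ...) {
  dr <- x$drop_report
  cat("Matched trait/phylogeny dataset\n")
  cat(sprintf("  records: %d (of %d input; %d unmatched, %d clade-filtered)\n",
              dr$retained_records, dr$input_records,
              dr$dropped_unmatched_records, dr$dropped_clade_filter))
  cat(sprintf("  species (tips): %d (%d tips pruned)\n",
              length(x$species_index), dr$dropped_tips))
  invisible(x)
}

#' Species-level trait vector
#'
#' Aggregates record-level `log_sla` to one value per species, aligned to the
#' tip order of the dataset's tree. The default aggregation is the mean of the
#' log10-transformed values; the median is available as an alternative.
#'
#' @param dataset A `matched_dataset`.
#' @param fun Aggregation, `"mean"` or `"median"`.
#' @param var Record column to aggregate (default `"log_sla"`).
#' @return A named numeric vector, one entry per tip, in tree tip order.
#' @export
species_trait <- function(dataset, fun = c("mean", "median"), var = "log_sla") {
  stopifnot(inherits(dataset, "matched_dataset"))
  fun <- match.arg(fun)
  f <- if (fun == "mean") mean else median
  agg <- tapply(dataset$records[[var]], dataset$records$species, f, na.rm = TRUE)
  out <- as.numeric(agg[dataset$tree$tip.label])
  names(out) <- dataset$tree$tip.label
  if (anyNA(out)) stop_pvr("species without trait values after aggregation")
  out
}
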