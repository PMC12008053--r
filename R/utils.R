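# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## "Genus species" and "Genus_species" refer to the same taxon; tip labels and
## trait tables are reconciled on the underscore form.
normalize_species <- function(x) {
  x <- trimws(as.character(x))
  gsub("[ ]+", "_", x)
}

## Column roster shared by the reader, the simulator, and the partition.
climate_vars <- function() {
  c("par", "mat", "mtcm", "mthm", "map", "mi", "alpha", "precip_seasonality")
}

soil_vars <- function() {
  c("sand_frac", "silt_frac", "clay_frac", "ph", "org_c", "cec", "tn", "tp")
}

## Default predictor classes of the seven-model partition (a subset of the
## full roster: MAT and precipitation seasonality are screened but not
## entered, organic carbon and CEC likewise).
default_climate_class <- function() c("par", "mtcm", "mthm", "map", "mi", "alpha")
default_soil_class <- function() c("sand_frac", "silt_frac", "clay_frac", "ph", "tn", "tp")

stop_pvr <- function(...) stop(..., call. = FALSE)

## Deterministic per-stage seeds derived from one global seed, kept within
## 32-bit integer range.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647L)
}
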