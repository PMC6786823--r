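#' Read a BIDS-style events TSV
#'
#' Tab-separated with a header row; onsets are in seconds and trial
#' intervals are half-open `[onset, onset + duration)`.
#'
#' @param path file path.
#' @param required character vector of columns that must be present.
#' @return data.frame of trial records (empty file yields an empty
#'   data.frame with a warning).
#' @export
read_events_tsv <- function(path, required = character(0)) {
  if (!file.exists(path)) stop_ld("no such file: %s", path)
  if (file.size(path) == 0L) {
    warning(sprintf("events file is empty: %s", path))
    return(data.frame())
  }
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(fields)) > 1L)
    stop_ld("malformed row at line %d of %s: expected %d fields, found %d",
            which(fields != fields[1])[1], path, fields[1],
            fields[fields != fields[1]][1])
  dat <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           quote = "")
  miss <- setdiff(required, names(dat))
  if (length(miss))
    stop_ld("events file %s is missing column(s): %s", path,
            paste(miss, collapse = ", "))
  dat
}

#' Write trial records as a BIDS-style events TSV
#'
#' @param records data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read / write a 3-D or 4-D volume as NIfTI
#'
#' Thin wrappers over the RNifti package (optional dependency); the rest of
#' the package operates on plain arrays.
#'
#' @param path NIfTI file path.
#' @param volume numeric array.
#' @return `read_volume`: an array; `write_volume`: `path`, invisibly.
#' @export
read_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop_ld("reading NIfTI volumes requires the RNifti package")
  as.array(RNifti::readNifti(path))
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop_ld("writing NIfTI volumes requires the RNifti package")
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the design, generative model, scoring mode and thresholds; fully
#' serializable, round-tripping through YAML without loss.
#'
#' @param seed root seed; every stage derives a named child stream from it.
#' @param design a [design_config()].
#' @param generative a [generative_config()].
#' @param dependency_mode `"accuracy"`, `"confidence"` or `"both"`.
#' @param confidence_high high-confidence threshold.
#' @param roi_map named ROI -> category map.
#' @param cluster_p cluster-defining p threshold.
#' @param outlier_motion_mm,outlier_global_z,outlier_max_fraction scan
#'   outlier thresholds and participant-exclusion boundary.
#' @param run_glm include the small GLM recovery stage in [run_pipeline()].
#' @return list of class `loopdep_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            design = design_config(seed = seed),
                            generative = generative_config(seed = seed),
                            dependency_mode = "both",
                            confidence_high = 3L,
                            roi_map = default_roi_map(),
                            cluster_p = 0.005,
                            outlier_motion_mm = 2,
                            outlier_global_z = 9,
                            outlier_max_fraction = 0.10,
                            run_glm = FALSE) {
  cfg <- list(seed = as.integer(seed), design = design,
              generative = generative, dependency_mode = dependency_mode,
              confidence_high = as.integer(confidence_high),
              roi_map = roi_map, cluster_p = cluster_p,
              outlier_motion_mm = outlier_motion_mm,
              outlier_global_z = outlier_global_z,
              outlier_max_fraction = outlier_max_fraction,
              run_glm = isTRUE(run_glm))
  class(cfg) <- "loopdep_pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config`: `path`, invisibly;
#'   `read_pipeline_config`: the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "loopdep_pipeline_config"))
  plain <- rapply(unclass(config), unclass, how = "replace")
  plain$design <- unclass(plain$design)
  plain$generative <- unclass(plain$generative)
  plain$roi_map <- as.list(config$roi_map)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  design <- do.call(design_config,
                    raw$design[names(raw$design) != "pool_sizes"])
  gen_fields <- setdiff(names(raw$generative),
                        setdiff(names(raw$generative),
                                names(formals(generative_config))))
  generative <- do.call(generative_config, raw$generative[gen_fields])
  pipeline_config(seed = raw$seed, design = design, generative = generative,
                  dependency_mode = raw$dependency_mode,
                  confidence_high = raw$confidence_high,
                  roi_map = unlist(raw$roi_map),
                  cluster_p = raw$cluster_p,
                  outlier_motion_mm = raw$outlier_motion_mm,
                  outlier_global_z = raw$outlier_global_z,
                  outlier_max_fraction = raw$outlier_max_fraction,
                  run_glm = raw$run_glm)
}
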