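#' Pipeline configuration
#'
#' Bundles the tunables of the whole pipeline: the training
#' configuration, the quantification parameters (connected-components
#' merge radius, ROI tile size), the routing interval scheme, the model
#' variant and the master seed. Configurations round-trip losslessly
#' through YAML; unknown keys in a file are rejected.
#'
#' @param training a [training_config()].
#' @param merge_radius_px connected-components merge radius (default 4).
#' @param min_area_px intact-cell area gate for counting (default 0).
#' @param tile_px ROI tile size (default 256).
#' @param scheme an [interval_scheme()].
#' @param variant model variant, `"full"` or `"reduced"`.
#' @param seed master seed.
#' @param verbosity one of "quiet", "info", "debug".
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(training = training_config(),
                            merge_radius_px = 4L,
                            min_area_px = 0L,
                            tile_px = 256L,
                            scheme = default_scheme(),
                            variant = "full",
                            seed = 1L,
                            verbosity = "info") {
  stopifnot(inherits(training, "training_config"),
            inherits(scheme, "interval_scheme"),
            merge_radius_px >= 0, min_area_px >= 0, tile_px >= 1,
            variant %in% c("full", "reduced"),
            verbosity %in% c("quiet", "info", "debug"))
  structure(
    list(training = training,
         merge_radius_px = as.integer(merge_radius_px),
         min_area_px = as.integer(min_area_px),
         tile_px = as.integer(tile_px),
         scheme = scheme,
         variant = variant,
         seed = as.integer(seed),
         verbosity = verbosity),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(
    training = unclass(config$training),
    merge_radius_px = config$merge_radius_px,
    min_area_px = config$min_area_px,
    tile_px = config$tile_px,
    scheme = list(edges = config$scheme$edges,
                  labels = config$scheme$labels,
                  review = config$scheme$review),
    variant = config$variant,
    seed = config$seed,
    verbosity = config$verbosity
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("training", "merge_radius_px", "min_area_px", "tile_px",
               "scheme", "variant", "seed", "verbosity")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tr_allowed <- names(formals(training_config))
  tr_unknown <- setdiff(names(raw$training), tr_allowed)
  if (length(tr_unknown) > 0) {
    stop("unknown training config keys: ",
         paste(tr_unknown, collapse = ", "), call. = FALSE)
  }
  tr <- do.call(training_config, raw$training)
  sc <- if (is.null(raw$scheme)) default_scheme() else {
    interval_scheme(edges = unlist(raw$scheme$edges),
                    labels = unlist(raw$scheme$labels),
                    review = unlist(raw$scheme$review))
  }
  pipeline_config(
    training = tr,
    merge_radius_px = raw$merge_radius_px %||% 4L,
    min_area_px = raw$min_area_px %||% 0L,
    tile_px = raw$tile_px %||% 256L,
    scheme = sc,
    variant = raw$variant %||% "full",
    seed = raw$seed %||% 1L,
    verbosity = raw$verbosity %||% "info"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# timestamped, levelled logging to standard error
pd_log <- function(verbosity, level = c("info", "debug"), ...) {
  level <- match.arg(level)
  show <- switch(verbosity, quiet = FALSE,
                 info = level == "info", debug = TRUE)
  if (show) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "),
            toupper(level), " ", ...)
  }
  invisible(NULL)
}
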