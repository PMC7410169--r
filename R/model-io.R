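#' Read a demographic model from JSON or YAML
#'
#' The config lists `generation_time`, `grid_times` (years), `populations`
#' (name, parent, div_time, ghost), `sizes` (population, time, size; diploid
#' effective sizes), optional `bands` (source, dest, time, rate) and
#' `samples` (sample_id, population, age, ploidy, phased).
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A [demog_model()].
#' @export
read_demog_model <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- if (!is.null(cfg$grid_times))
    time_grid(unlist(cfg$grid_times),
              generation_time = cfg$generation_time %||% 29)
  else default_time_grid(cfg$generation_time %||% 29)
  as_df <- function(x) {
    if (is.data.frame(x)) return(x)
    dplyr::bind_rows(lapply(x, function(row)
      tibble::as_tibble(lapply(row, function(v) if (is.null(v)) NA else v))))
  }
  pops <- as_df(cfg$populations)
  if (!"parent" %in% names(pops)) pops$parent <- NA_character_
  if (!"div_time" %in% names(pops)) pops$div_time <- NA_real_
  demog_model(
    populations = pops,
    sizes = as_df(cfg$sizes),
    samples = as_df(cfg$samples),
    bands = if (!is.null(cfg$bands)) as_df(cfg$bands) else NULL,
    grid = grid
  )
}

#' Write a demographic model config as JSON
#'
#' @param model A [demog_model()].
#' @param path Output path.
#' @export
write_demog_model <- function(model, path) {
  cfg <- list(
    generation_time = model$generation_time,
    grid_times = model$grid$times,
    populations = model$pops[, c("name", "parent", "div_time", "ghost")],
    sizes = model$sizes[, c("population", "time", "size")],
    bands = if (nrow(model$bands))
      model$bands[, c("source", "dest", "time", "rate")] else NULL,
    samples = model$samples[, c("sample_id", "population", "age", "ploidy",
                                "phased")]
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
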