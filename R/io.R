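#' Read and write model input tables
#'
#' CSV dialects for the three external inputs: demography (`year, age,
#' population` with age 100 meaning 100+), incidence (`band_start,
#' band_end, rate_per_100k_year`) and macro (`year, inflation, gdp`).
#' Parameter sets round-trip through JSON in [flatten_params()] notation
#' (plus `epsilon` and `t_star`); scenarios through YAML with keys
#' `name, t_star, beta1, beta2, eta, overrides`.
#'
#' @param path File path.
#' @name oncopolicy_io
NULL

#' @rdname oncopolicy_io
#' @export
read_demography <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("year", "age", "population") %in% names(d)))
  d
}

#' @rdname oncopolicy_io
#' @param demography,incidence,macro Tables in the dialects above.
#' @export
write_demography <- function(demography, path) {
  utils::write.csv(demography, path, row.names = FALSE)
  invisible(path)
}

#' @rdname oncopolicy_io
#' @export
read_incidence <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("band_start", "band_end", "rate_per_100k_year")
                %in% names(d)))
  d
}

#' @rdname oncopolicy_io
#' @export
write_incidence <- function(incidence, path) {
  utils::write.csv(incidence, path, row.names = FALSE)
  invisible(path)
}

#' @rdname oncopolicy_io
#' @export
read_macro <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("year", "inflation", "gdp") %in% names(d)))
  d
}

#' @rdname oncopolicy_io
#' @export
write_macro <- function(macro, path) {
  utils::write.csv(macro, path, row.names = FALSE)
  invisible(path)
}

#' @rdname oncopolicy_io
#' @param params An `"oncopolicy_params"`.
#' @export
write_params <- function(params, path) {
  obj <- c(as.list(flatten_params(params)),
           list(epsilon = params$epsilon, t_star = params$t_star))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname oncopolicy_io
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- default_parameters()
  p$epsilon <- obj$epsilon %||% p$epsilon
  p$t_star <- as.integer(obj$t_star %||% p$t_star)
  obj$epsilon <- NULL
  obj$t_star <- NULL
  set_params(p, unlist(obj))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname oncopolicy_io
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  scenario_spec(name = obj$name %||% "custom",
                t_star = obj$t_star %||% 204L,
                overrides = unlist(obj$overrides),
                beta1 = obj$beta1 %||% 0.2,
                beta2 = obj$beta2 %||% 1,
                eta = obj$eta %||% 0)
}

#' @rdname oncopolicy_io
#' @param scenario An `"oncopolicy_scenario"`.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(list(name = scenario$name, t_star = scenario$t_star,
                        beta1 = scenario$beta1, beta2 = scenario$beta2,
                        eta = scenario$eta,
                        overrides = scenario$overrides), path)
  invisible(path)
}
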