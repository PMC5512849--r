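#' Load and validate a kinetic parameter set
#'
#' Accepts either a tidy CSV (columns `symbol`, `value`, and optionally
#' `units`, `provenance`, `description`) or a flat YAML mapping of
#' `symbol: value`.  Validation is exhaustive: all missing symbols and all
#' positivity violations are reported in a single error, not one at a time.
#'
#' Positivity is required for every saturation/affinity constant, maximal
#' rate, pool total and the growth yield `k_ATP`; the shared Hill
#' coefficient `n_hill` must be negative (high transcription-factor activity
#' at low ligand); `k_O2` must lie in (0, 1] because cytoplasmic oxygen is
#' assumed at most equal to the medium concentration.
#'
#' @param source path to a CSV/YAML file, or a named numeric vector / data
#'   frame already in memory.
#' @param network optional `metabolic_network`; when supplied, completeness
#'   is checked against every symbol the network's rate laws and regulation
#'   edges reference.
#' @return an object of class `parameter_set`: a named numeric vector with a
#'   `meta` attribute carrying the tidy table.
#' @export
load_parameters <- function(source, network = NULL) {
  if (is.character(source) && length(source) == 1L) {
    ext <- tolower(tools::file_ext(source))
    if (ext %in% c("yml", "yaml")) {
      vals <- unlist(yaml::read_yaml(source))
      tab <- data.frame(symbol = names(vals), value = as.numeric(vals),
                        units = NA_character_, provenance = NA_character_,
                        description = NA_character_)
    } else {
      tab <- utils::read.csv(source, stringsAsFactors = FALSE)
    }
  } else if (is.data.frame(source)) {
    tab <- source
  } else if (is.numeric(source) && !is.null(names(source))) {
    tab <- data.frame(symbol = names(source), value = as.numeric(source))
  } else {
    stop("unsupported parameter source")
  }
  if (!all(c("symbol", "value") %in% names(tab)))
    stop("parameter table must have columns 'symbol' and 'value'")
  for (col in c("units", "provenance", "description"))
    if (is.null(tab[[col]])) tab[[col]] <- NA_character_

  p <- as.numeric(tab$value)
  names(p) <- tab$symbol

  problems <- character(0)
  dup <- unique(tab$symbol[duplicated(tab$symbol)])
  if (length(dup) > 0L)
    problems <- c(problems, sprintf("duplicated symbol %s", dup))

  if (!is.null(network)) {
    missing <- setdiff(required_symbols(network), names(p))
    if (length(missing) > 0L)
      problems <- c(problems, sprintf("missing parameter %s", missing))
  }

  nonneg_exempt <- "n_hill"
  bad <- names(p)[!is.finite(p) | (p <= 0 & !(names(p) %in% nonneg_exempt))]
  if (length(bad) > 0L)
    problems <- c(problems, sprintf("non-positive or non-finite value for %s", bad))
  if ("n_hill" %in% names(p) && !(is.finite(p[["n_hill"]]) && p[["n_hill"]] < 0))
    problems <- c(problems, "n_hill must be negative")
  if ("k_O2" %in% names(p) && is.finite(p[["k_O2"]]) &&
      (p[["k_O2"]] <= 0 || p[["k_O2"]] > 1))
    problems <- c(problems, "k_O2 must lie in (0, 1]")

  if (length(problems) > 0L)
    stop("invalid parameter set:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  structure(p, meta = tab, class = c("parameter_set", "numeric"))
}

#' Every parameter symbol a network references
#'
#' Collects vmax/Km/effector symbols from all rate laws, regulation-edge
#' strengths, pool totals, the biomass carbon content, and the global redox
#' parameters used by the regulation layer.
#'
#' @param network a `metabolic_network`.
#' @return character vector of symbols.
#' @export
required_symbols <- function(network) {
  syms <- character(0)
  grab <- function(x) {
    if (is.null(x)) return(invisible())
    if (is.list(x)) { lapply(x, grab); return(invisible()) }
  }
  for (rx in network$reactions) {
    r <- rx$rate
    syms <- c(syms, r$vmax, r$keq)
    for (s in r$substrates) syms <- c(syms, s$km)
    if (!is.null(r$glucose)) syms <- c(syms, r$glucose$km, r$k_ratio)
    if (!is.null(r$substrate)) syms <- c(syms, r$substrate$km)
    if (!is.null(r$product))  syms <- c(syms, r$product$km)
    for (side in list(r$forward, r$reverse)) {
      if (is.null(side)) next
      syms <- c(syms, side$vmax)
      for (s in side$substrates) syms <- c(syms, s$km)
    }
    for (e in r$effectors)
      syms <- c(syms, e$ki, e$ka, e$beta, e$k, e$hill)
  }
  for (e in network$regulation) syms <- c(syms, e$strength)
  for (s in network$species)
    if (identical(s$compartment, "pool")) syms <- c(syms, s$total)
  if (!is.null(network$biomass)) syms <- c(syms, network$biomass$carbon_content)
  if (identical(network$name, "ecoli_core_redox"))
    syms <- c(syms, "K_Fnr", "K_ArcA", "n_hill", "k_O2", "DO2_star", "k_ATP")
  unique(unlist(syms))
}

#' The shipped refit parameter set
#'
#' Loads the parameter CSV distributed with the package.  Every row is
#' flagged `provenance: refit`: the values were calibrated against the
#' qualitative and quantitative behavior of the wild-type and knockout
#' strains across dissolved-oxygen levels (see the methods vignette).
#'
#' @return a `parameter_set` validated against [ecoli_network()].
#' @export
default_parameters <- function() {
  load_parameters(system.file("extdata", "ecoli_params_refit.csv",
                              package = "redoxferm", mustWork = TRUE),
                  network = ecoli_network())
}

#' Serialize a parameter set to tidy CSV
#'
#' Values are written with full double precision (17 significant digits) so
#' that a write/read round trip reproduces the set bit-for-bit.
#'
#' @param params a `parameter_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  tab <- attr(params, "meta")
  tab$value <- vapply(unname(params[tab$symbol]),
                      function(x) sprintf("%.17g", x), "")
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' A short digest of a parameter set
#'
#' Order-independent checksum over `symbol=value` pairs at full double
#' precision; used to stamp golden regression tables.
#'
#' @param params a `parameter_set`.
#' @return a character scalar.
#' @export
parameter_digest <- function(params) {
  keys <- sort(names(params), method = "radix")  # locale-independent
  txt <- paste(keys, sprintf("%.17g", unname(params[keys])),
               sep = "=", collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- c(17, 251, 433, 877)
  for (i in seq_along(bytes)) {
    h <- (h * c(31, 37, 41, 43) + bytes[i] * c(1, 7, 13, 19)) %% 2147480009
  }
  paste(sprintf("%08x", as.integer(h)), collapse = "")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d parameters, digest %s\n",
              length(x), parameter_digest(x)))
  invisible(x)
}
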