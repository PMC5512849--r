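#' Define a strain by its gene knockouts
#'
#' @param name strain label; the conventional shortcuts "WT", "fnr",
#'   "arcA" and "pfl" can be given alone and imply the knockout list.
#' @param knockouts character vector of knocked-out genes; any of
#'   `"fnr"`, `"arcA"`, `"pfl"`.
#' @return an object of class `strain_spec`.
#' @export
strain_spec <- function(name = "WT", knockouts = NULL) {
  if (is.null(knockouts))
    knockouts <- switch(name, WT = character(0), fnr = "fnr",
                        arcA = "arcA", pfl = "pfl",
                        stop("unknown strain shortcut: ", name))
  structure(list(name = name, knockouts = unique(knockouts)),
            class = "strain_spec")
}

#' Apply gene knockouts to the model
#'
#' Knockout semantics: `fnr` silences the Fnr activity identically (all Fnr
#' regulation edges become inert at every oxygen level); `arcA` silences the
#' ArcA activity identically; `pfl` zeroes the maximal rate of the Pfl
#' reaction.  The operation is idempotent and commutative across distinct
#' genes; the wild type is the identity.
#'
#' The network itself is returned unchanged; knockouts are carried as
#' attributes of the parameter set (`fnr_scale`, `arca_scale`, and a
#' possibly modified `vmax_Pfl`).
#'
#' @param network a `metabolic_network`.
#' @param params a `parameter_set`.
#' @param strain a `strain_spec` or a strain shortcut name.
#' @return list with elements `network` and `params`.
#' @export
apply_knockout <- function(network, params, strain) {
  if (is.character(strain)) strain <- strain_spec(strain)
  genes <- strain$knockouts
  known <- c("fnr", "arcA", "pfl")
  bad <- setdiff(genes, known)
  if (length(bad) > 0L)
    stop("unknown knockout gene(s): ", paste(bad, collapse = ", "))
  fnr_scale <- attr(params, "fnr_scale") %||% 1
  arca_scale <- attr(params, "arca_scale") %||% 1
  if ("fnr" %in% genes) fnr_scale <- 0
  if ("arcA" %in% genes) arca_scale <- 0
  if ("pfl" %in% genes) params[["vmax_Pfl"]] <- 0
  attr(params, "fnr_scale") <- fnr_scale
  attr(params, "arca_scale") <- arca_scale
  attr(params, "strain") <- strain$name
  list(network = network, params = params)
}

#' @export
print.strain_spec <- function(x, ...) {
  ko <- if (length(x$knockouts) == 0L) "none"
        else paste(x$knockouts, collapse = ", ")
  cat(sprintf("<strain_spec> %s (knockouts: %s)\n", x$name, ko))
  invisible(x)
}
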